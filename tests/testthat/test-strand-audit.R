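## independent exact two-proportion oracle: enumerate all 2x2 tables with
## the observed margins via hypergeometric probabilities from choose()
exact_test_oracle <- function(fm, fu, rm, ru) {
  m <- fm + fu; n <- rm + ru; k <- fm + rm
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, numeric(1))
  pobs <- probs[fm - lo + 1]
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

test_that("strand discordance flags the C>A/C>G heterozygote signature", {
  ev <- tibble::tibble(
    fwd_meth = c(20, 20, 12, 0), fwd_unmeth = c(0, 0, 8, 0),
    rev_meth = c(10, 19, 11, 5), rev_unmeth = c(10, 1, 9, 5)
  )
  res <- strand_asymmetry(ev)
  expect_equal(res$difference[1], 0.5)
  expect_equal(res$status[1], "DISCORDANT")
  expect_equal(res$difference[2], 0.05)
  expect_equal(res$status[2], "CONCORDANT")
  expect_equal(res$status[3], "CONCORDANT")
  expect_equal(res$status[4], "NOT_ASSESSABLE")  # zero forward coverage
  expect_true(is.na(res$p_value[4]))
  ## exact-test p matches the enumeration oracle
  expect_equal(res$p_value[3], exact_test_oracle(12, 8, 11, 9),
               tolerance = 1e-12)
  expect_equal(res$p_value[1], exact_test_oracle(20, 0, 10, 10),
               tolerance = 1e-12)
})

test_that("pure reference evidence is called C/C with near-unit posterior", {
  ev <- tibble::tibble(
    chrom = "chr1", pos = 100L,
    fwd_meth = 14L, fwd_unmeth = 0L, rev_meth = 15L, rev_unmeth = 0L,
    rev_A = 0L, rev_C = 0L, rev_G = 15L, rev_T = 0L
  )
  call <- call_genotypes(ev, theta = 0.001)
  expect_equal(call$genotype, "C/C")
  expect_gt(call$posterior, 0.999)
  expect_equal(call$filter, "PASS")
  ## posteriors over the 10 genotypes sum to one
  expect_equal(sum(attr(call, "posterior_matrix")), 1, tolerance = 1e-9)
})

test_that("the caller posterior matches exhaustive enumeration on a worked example", {
  ev <- tibble::tibble(
    chrom = "chr1", pos = 100L,
    fwd_meth = 10L, fwd_unmeth = 0L, rev_meth = 4L, rev_unmeth = 4L,
    rev_A = 0L, rev_C = 0L, rev_G = 8L, rev_T = 7L
  )
  call <- call_genotypes(ev, error_rate = 0.01)
  expect_equal(call$genotype, "A/C")
  oracle <- caller_oracle_posterior(10, 0, 4, 4,
                                    c(A = 0, C = 0, G = 8, T = 7),
                                    error_rate = 0.01)
  post <- attr(call, "posterior_matrix")[1, ]
  expect_equal(post[names(oracle)], oracle, tolerance = 1e-9)
  ## identical evidence below min_depth is flagged LOW_COV
  low <- dplyr::mutate(ev, fwd_meth = 3L, rev_meth = 2L, rev_unmeth = 1L,
                       rev_G = 2L, rev_T = 1L)
  expect_equal(call_genotypes(low, error_rate = 0.01)$filter, "LOW_COV")
})

test_that("noiseless evidence at 20x per strand is always called correctly", {
  set.seed(61)
  gts <- rep(c("C/C", "A/C", "C/G", "C/T"), each = 250)
  ev <- dplyr::bind_rows(lapply(seq_along(gts), function(i) {
    r <- simulate_site_readout(gts[i], 1, 1,
      coverage_mean_per_strand = 20,
      non_conversion_rate = 0, sequencing_error_rate = 0
    )
    tibble::tibble(
      chrom = "chr1", pos = 10L * i,
      fwd_meth = r$fwd_meth, fwd_unmeth = r$fwd_unmeth,
      rev_meth = r$rev_meth, rev_unmeth = r$rev_unmeth,
      rev_A = r$rev_A, rev_C = r$rev_C, rev_G = r$rev_G, rev_T = r$rev_T
    )
  }))
  calls <- call_genotypes(ev)
  expect_equal(mean(calls$genotype == gts), 1)
})

test_that("C/T heterozygotes are strand-concordant and recoverable only from base counts", {
  set.seed(62)
  r <- simulate_site_readout("C/T", 1, 30,
    coverage_mean_per_strand = 30,
    non_conversion_rate = 0, sequencing_error_rate = 0,
    cph_methylation_rate = 0.01
  )
  ev <- tibble::tibble(
    chrom = "chr1", pos = seq_len(30) * 10L,
    fwd_meth = r$fwd_meth, fwd_unmeth = r$fwd_unmeth,
    rev_meth = r$rev_meth, rev_unmeth = r$rev_unmeth,
    rev_A = r$rev_A, rev_C = r$rev_C, rev_G = r$rev_G, rev_T = r$rev_T
  )
  ## both strands hover near m/2: the strand comparison sees nothing
  asym <- strand_asymmetry(ev)
  expect_gt(mean(asym$status == "CONCORDANT"), 0.9)
  ## the reverse-strand adenines give the variant away
  calls <- call_genotypes(ev)
  expect_equal(mean(calls$genotype == "C/T"), 1)
  ## with base counts zeroed out (and only strand rates left), C/T is no
  ## longer recovered
  blind <- dplyr::mutate(ev, rev_A = 0L, rev_C = 0L, rev_G = 0L, rev_T = 0L)
  blind_calls <- call_genotypes(blind)
  expect_lt(mean(blind_calls$genotype == "C/T"), 0.5)
})

test_that("catalog priors do not reduce heterozygote sensitivity on common variants", {
  set.seed(63)
  n <- 400
  af <- 0.3
  dos <- rbinom(n, 2, af)
  gts <- genotype_from_dosage_test(dos, "A")
  ev <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    r <- simulate_site_readout(gts[i], 1, 1,
      coverage_mean_per_strand = 4,
      non_conversion_rate = 0.005, sequencing_error_rate = 0.001
    )
    tibble::tibble(
      chrom = "chr1", pos = 10L * i,
      fwd_meth = r$fwd_meth, fwd_unmeth = r$fwd_unmeth,
      rev_meth = r$rev_meth, rev_unmeth = r$rev_unmeth,
      rev_A = r$rev_A, rev_C = r$rev_C, rev_G = r$rev_G, rev_T = r$rev_T
    )
  }))
  ev <- ev[ev$fwd_meth + ev$fwd_unmeth + ev$rev_meth + ev$rev_unmeth > 0, ]
  truth <- tibble::tibble(chrom = "chr1", pos = ev$pos,
                          genotype = gts[ev$pos / 10L])
  catalog <- tibble::tibble(chrom = "chr1", start = ev$pos,
                            end = ev$pos + 1L, af = af, alt = "A")
  rare <- evaluate_calls(call_genotypes(ev, min_depth = 5), truth)
  cat_mode <- evaluate_calls(
    call_genotypes(ev, prior_mode = "catalog", catalog = catalog,
                   min_depth = 5),
    truth
  )
  expect_gte(cat_mode$het_sensitivity, rare$het_sensitivity)
})

test_that("call evaluation counts detections and false variants as defined", {
  ## perfect calls
  truth <- tibble::tibble(chrom = "chr1", pos = 1:20 * 10L,
                          genotype = c(rep("A/C", 5), rep("C/C", 15)))
  perfect <- tibble::tibble(chrom = "chr1", pos = truth$pos,
                            genotype = truth$genotype, filter = "PASS")
  e <- evaluate_calls(perfect, truth)
  expect_equal(e$het_sensitivity, 1)
  expect_equal(e$false_variant_rate, 0)

  ## planted errors: one missed het, one wrong variant, one false positive
  calls <- perfect
  calls$genotype[1] <- "C/C"   # missed het
  calls$genotype[2] <- "C/G"   # wrong variant at a true het
  calls$genotype[6] <- "A/C"   # false positive at a reference site
  e2 <- evaluate_calls(calls, truth)
  expect_equal(e2$het_sensitivity, 3 / 5)
  expect_equal(e2$false_variant_rate, 2 / 20)

  ## all-reference calls on an all-het truth
  allref <- dplyr::mutate(perfect, genotype = "C/C")
  allhet <- dplyr::mutate(truth, genotype = "A/C")
  expect_equal(evaluate_calls(allref, allhet)$het_sensitivity, 0)

  ## disjoint site sets are an error
  expect_error(
    evaluate_calls(perfect, dplyr::mutate(truth, pos = pos + 1000L)),
    "disjoint"
  )
})
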