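test_that("the OLS fit matches the closed-form normal-equations oracle", {
  meth <- c(0.1, 0.12, 0.5, 0.48, 0.9, 0.88)
  dosage <- c(0, 0, 1, 1, 2, 2)
  fit <- fit_cpg_snp(meth, dosage)
  o <- ols_oracle(dosage, meth)
  expect_equal(fit$slope, o$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, o$intercept, tolerance = 1e-12)
  expect_equal(fit$r, o$r, tolerance = 1e-12)
  expect_equal(fit$p_value, o$p, tolerance = 1e-9)
  expect_gt(fit$r, 0.99)
  expect_equal(as.numeric(fit$fitted_means),
               fit$intercept + fit$slope * (0:2))
})

test_that("a noiseless line is recovered exactly", {
  dosage <- c(0, 1, 2, 1, 0, 2, 1)
  meth <- 0.2 + 0.3 * dosage
  fit <- fit_cpg_snp(meth, dosage)
  expect_equal(fit$slope, 0.3)
  expect_equal(fit$intercept, 0.2)
  expect_equal(fit$r, 1)
  expect_equal(as.numeric(fit$fitted_means), c(0.2, 0.5, 0.8))
  expect_equal(fit$accuracy, 1)
})

test_that("permuting dosage destroys the correlation", {
  meth <- c(0.1, 0.12, 0.5, 0.48, 0.9, 0.88)
  dosage <- c(0, 0, 1, 1, 2, 2)
  set.seed(8)
  ps <- replicate(50, {
    fit <- tryCatch(fit_cpg_snp(meth, sample(dosage)),
                    error = function(e) NULL)
    if (is.null(fit)) NA_real_ else fit$p_value
  })
  expect_gt(mean(ps > 0.05, na.rm = TRUE), 0.5)
})

test_that("degenerate fits raise informative errors", {
  expect_error(fit_cpg_snp(c(0.1, 0.2), c(0, 1)), "fewer than 3")
  expect_error(fit_cpg_snp(c(0.1, 0.2, 0.3), c(1, 1, 1)), "dosage is constant")
  expect_error(fit_cpg_snp(c(0.5, 0.5, 0.5), c(0, 1, 2)),
               "methylation is constant")
})

test_that("the 10 kb window is inclusive and results are ranked by |r|", {
  cpg <- list(chrom = "chr1", pos = 50000L, cpg_id = "cpgX")
  snps <- tibble::tibble(
    snp_id = c("s_at_edge", "s_out", "s_near", "s_mid"),
    chrom = "chr1",
    pos = c(60000L, 60001L, 50010L, 55000L)
  )
  set.seed(5)
  inds <- sprintf("i%02d", 1:12)
  dosages <- tibble::tibble(
    snp_id = rep(snps$snp_id, each = 12),
    individual_id = rep(inds, 4),
    dosage = c(
      rep(c(0L, 1L, 2L), 4),            # s_at_edge: strong signal
      sample(0:2, 12, replace = TRUE),  # s_out (excluded anyway)
      sample(0:2, 12, replace = TRUE),  # s_near: noise
      sample(0:2, 12, replace = TRUE)   # s_mid: noise
    )
  )
  meth <- tibble::tibble(
    sample_id = inds, individual_id = inds,
    rate = 0.1 + 0.4 * rep(c(0, 1, 2), 4) + rnorm(12, 0, 0.01)
  )
  res <- scan_window(cpg, snps, dosages, meth, window_bp = 10000)
  expect_setequal(res$snp_id, c("s_at_edge", "s_near", "s_mid"))
  expect_false("s_out" %in% res$snp_id)   # +10,001 bp is outside
  expect_equal(res$snp_id[1], "s_at_edge")  # +10,000 bp included and best
  ## ranking agrees with brute-force |r|
  brute <- vapply(res$snp_id, function(s) {
    d <- dosages[dosages$snp_id == s, ]
    abs(cor(meth$rate, d$dosage[match(meth$individual_id, d$individual_id)]))
  }, numeric(1))
  expect_equal(res$snp_id, res$snp_id[order(-brute)])
})

test_that("genotype prediction is nearest-mean with ties to the smaller dosage", {
  expect_equal(predict_genotype(0.9, c(0, 0.5, 1)), 2L)
  expect_equal(predict_genotype(0.25, c(0, 0.5, 1)), 0L)  # equidistant
  expect_equal(predict_genotype(c(0.01, 0.45, 0.77), c(0, 0.5, 1)),
               c(0L, 1L, 2L))
  ## invariance under a monotone affine transform of both arguments
  m <- runif(20)
  fm <- c(0.1, 0.4, 0.9)
  expect_equal(predict_genotype(m, fm), predict_genotype(2 * m + 1, 2 * fm + 1))
})

test_that("well-separated genotype classes are predicted with > 98% accuracy", {
  set.seed(12)
  n <- 200
  dosage <- sample(0:2, n, replace = TRUE)
  meth <- 0.2 + 0.25 * dosage + rnorm(n, 0, 0.02)  # separation 0.5 over 0..2
  fit <- fit_cpg_snp(meth, dosage)
  expect_gt(fit$accuracy, 0.98)
  ## with zero noise and distinct means, accuracy is exactly 1
  fit0 <- fit_cpg_snp(0.2 + 0.25 * dosage, dosage)
  expect_equal(fit0$accuracy, 1)
})

test_that("classification applies strict thresholds and keeps each CpG's best SNP", {
  results <- tibble::tibble(
    cpg_id = c("a", "a", "b", "c", "d"),
    snp_id = c("s1", "s2", "s3", "s4", "s5"),
    distance = c(10L, 5L, 1L, 1L, 1L),
    r = c(0.9, 0.85, 0.5, -0.8, 0.6),
    p_value = c(1e-6, 1e-8, 1e-6, 1e-6, 0.2),
    accuracy = c(0.99, 0.97, 1, 0.97, 1)
  )
  cls <- classify_candidates(results)
  expect_equal(nrow(cls), 4)          # one row per CpG
  expect_equal(cls$snp_id[cls$cpg_id == "a"], "s1")  # best |r| wins
  ## r = 0.5 exactly fails the strict threshold
  expect_false(cls$correlated[cls$cpg_id == "b"])
  ## negative r of equal magnitude counts (dosage sign is arbitrary)
  expect_true(cls$correlated[cls$cpg_id == "c"])
  expect_false(cls$highly_predictive[cls$cpg_id == "c"])  # accuracy 0.97
  expect_false(cls$correlated[cls$cpg_id == "d"])         # p too large
  expect_true(cls$highly_predictive[cls$cpg_id == "a"])
  ## empty input
  empty <- classify_candidates(results[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("correlated", "highly_predictive") %in% names(empty)))
})

test_that("pairwise sample correlations behave on exact fixtures", {
  betas <- tibble::tibble(
    cpg_id = rep(c("c1", "c2", "c3", "c4"), 3),
    sample_id = rep(c("s1", "s2", "s3"), each = 4),
    beta = c(0.1, 0.4, 0.8, 0.2,
             0.1, 0.4, 0.8, 0.2,
             0.8, 0.5, 0.1, 0.7)
  )
  pairs <- tibble::tibble(
    sample_a = c("s1", "s1"), sample_b = c("s2", "s3"),
    relationship = c("MZ", "unrelated")
  )
  pc <- pairwise_sample_correlation(betas, pairs)
  expect_equal(pc$pairs$r[1], 1)
  expect_lt(pc$pairs$r[2], 0)
  ## anti-correlated toy vectors give r = -1
  anti <- tibble::tibble(
    cpg_id = rep(c("c1", "c2", "c3"), 2),
    sample_id = rep(c("x", "y"), each = 3),
    beta = c(0.1, 0.5, 0.9, 0.9, 0.5, 0.1)
  )
  pa <- pairwise_sample_correlation(
    anti, tibble::tibble(sample_a = "x", sample_b = "y", relationship = "u")
  )
  expect_equal(pa$pairs$r, -1)
  ## pairs with too few shared CpGs are skipped and counted
  sparse <- betas[betas$cpg_id == "c1", ]
  ps <- pairwise_sample_correlation(
    sparse, tibble::tibble(sample_a = "s1", sample_b = "s2", relationship = "MZ")
  )
  expect_equal(nrow(ps$pairs), 0)
  expect_equal(ps$n_skipped, 1)
})

test_that("slope recovery is unbiased with RMSE scaling like sigma/sqrt(n)", {
  set.seed(99)
  sigma <- 0.05
  effect <- 0.2
  rmse <- sapply(c(20, 50, 200), function(n) {
    err <- replicate(60, {
      dosage <- rbinom(n, 2, 0.4)
      while (length(unique(dosage)) < 2) dosage <- rbinom(n, 2, 0.4)
      meth <- 0.3 + effect * dosage + rnorm(n, 0, sigma)
      fit_cpg_snp(meth, dosage)$slope - effect
    })
    c(bias = mean(err), rmse = sqrt(mean(err^2)))
  })
  expect_lt(max(abs(rmse["bias", ])), 0.01)
  ## RMSE should fall roughly as 1/sqrt(n): compare n=20 vs n=200
  ratio <- rmse["rmse", 1] / rmse["rmse", 3]
  expect_gt(ratio, sqrt(10) / 2)
  expect_lt(ratio, sqrt(10) * 2)
  ## and match the theoretical sigma / (sqrt(n) * sd(dosage)) within 2x
  theo <- sigma / (sqrt(200) * sqrt(2 * 0.4 * 0.6))
  expect_lt(abs(rmse["rmse", 3] / theo - 1), 1)
})
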