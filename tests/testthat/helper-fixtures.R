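# Shared fixtures built in code.

## tiny cohort used across tests
small_cohort <- function(seed = 11, ...) {
  args <- list(n_cpgs = 120, n_snps = 40, seed = seed)
  args <- utils::modifyList(args, list(...))
  simulate_cohort(do.call(cohort_design, args))
}

## independent closed-form OLS oracle (normal equations, from scratch)
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * sum(y * y) - sy^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(slope = slope, intercept = intercept, r = r, p = p)
}

## brute-force genotype-caller oracle: explicit loops over the documented
## model (10 diploid genotypes x methylation grid), independent of the
## vectorized implementation
caller_oracle_posterior <- function(fwd_meth, fwd_unmeth, rev_meth,
                                    rev_unmeth, base_counts,
                                    theta = 0.001, error_rate = 0.001,
                                    cph = 0.01, meth_grid = c(0, 0.5, 1)) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  gts <- character(0)
  for (i in 1:4) for (j in i:4) {
    gts <- c(gts, paste(bases[i], bases[j], sep = "/"))
  }
  lik <- setNames(numeric(length(gts)), gts)
  for (g in gts) {
    a <- strsplit(g, "/")[[1]]
    ## reverse-strand base mixture
    pb <- setNames(numeric(4), bases)
    for (b in bases) {
      for (k in 1:2) {
        pb[b] <- pb[b] + 0.5 *
          (if (comp[a[k]] == b) 1 - error_rate else error_rate / 3)
      }
    }
    l_bases <- prod(pb^base_counts[bases])
    ## strand methylation, marginalized over the grid
    l_meth <- 0
    for (m in meth_grid) {
      countable <- a %in% c("C", "T")
      eps <- error_rate
      if (any(countable)) {
        raw <- mean(ifelse(a[countable] == "C", m, 0))
        pf <- raw * (1 - eps) + (1 - raw) * eps
        lf <- stats::dbinom(fwd_meth, fwd_meth + fwd_unmeth, pf)
      } else {
        lf <- error_rate^(fwd_meth + fwd_unmeth) *
          stats::dbinom(fwd_meth, fwd_meth + fwd_unmeth, 0.5)
      }
      rawr <- mean(ifelse(a == "C", m, ifelse(a == "T", cph, 0)))
      pr <- rawr * (1 - eps) + (1 - rawr) * eps
      lr <- stats::dbinom(rev_meth, rev_meth + rev_unmeth, pr)
      l_meth <- l_meth + lf * lr / length(meth_grid)
    }
    prior <- if (g == "C/C") 1 - theta else theta / 9
    lik[g] <- prior * l_meth * l_bases
  }
  lik / sum(lik)
}

## genotype string from an alt dosage at a C site (test-local copy)
genotype_from_dosage_test <- function(dosage, alt) {
  vapply(dosage, function(d) {
    if (d == 0) "C/C"
    else if (d == 1) paste(sort(c("C", alt)), collapse = "/")
    else paste(alt, alt, sep = "/")
  }, character(1))
}

## random strand-evidence fixture for caller tests
random_evidence <- function(n, seed) {
  withr::with_seed(seed, {
    gts <- sample(c("C/C", "A/C", "C/G", "C/T", "A/A", "T/T"), n,
                  replace = TRUE, prob = c(0.4, 0.15, 0.15, 0.15, 0.1, 0.05))
    m <- sample(c(0, 0.5, 1), n, replace = TRUE)
    out <- lapply(seq_len(n), function(i) {
      r <- simulate_site_readout(gts[i], m[i], 1,
        coverage_mean_per_strand = sample(5:30, 1),
        non_conversion_rate = 0.002, sequencing_error_rate = 0.005
      )
      tibble::tibble(
        chrom = "chr1", pos = 100L * i, true_genotype = gts[i],
        fwd_meth = r$fwd_meth, fwd_unmeth = r$fwd_unmeth,
        rev_meth = r$rev_meth, rev_unmeth = r$rev_unmeth,
        rev_A = r$rev_A, rev_C = r$rev_C, rev_G = r$rev_G, rev_T = r$rev_T
      )
    })
    out <- dplyr::bind_rows(out)
    ## the caller requires at least one read somewhere
    out[out$fwd_meth + out$fwd_unmeth + out$rev_meth + out$rev_unmeth > 0, ]
  })
}
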