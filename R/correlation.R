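#' Fit the linear genotype-methylation model for one CpG-SNP pair
#'
#' Models each SNP allele as carrying its own methylation rate at the CpG, so
#' the observed methylation of a diploid sample is the average over its two
#' alleles: a straight line in alternate-allele dosage. The fit is ordinary
#' least squares of methylation on dosage; `r` is the Pearson correlation and
#' its p-value comes from the t statistic with n - 2 degrees of freedom. The
#' fitted slope and intercept extrapolate a mean methylation rate for each of
#' the three genotypes even when a dosage class is absent from the data, and
#' predictive `accuracy` is the fraction of samples whose dosage is
#' re-predicted correctly by nearest fitted mean ([predict_genotype()]).
#'
#' @param meth Per-sample methylation rates.
#' @param dosage Per-sample alternate-allele dosages (0/1/2).
#' @param loo Use leave-one-out prediction for `accuracy` instead of
#'   resubstitution (default `FALSE`; the reference analysis describes no
#'   held-out scheme).
#' @return Object of class `cpg_snp_fit` with elements `slope`, `intercept`,
#'   `r`, `p_value`, `n`, `fitted_means` (named "0","1","2"), `accuracy` and
#'   the fitting `data`. Supports [generics::tidy()], [generics::glance()]
#'   and [ggplot2::autoplot()].
#' @export
#' @examples
#' fit_cpg_snp(c(0.1, 0.12, 0.5, 0.48, 0.9, 0.88), c(0, 0, 1, 1, 2, 2))
fit_cpg_snp <- function(meth, dosage, loo = FALSE) {
  ok <- !is.na(meth) & !is.na(dosage)
  meth <- meth[ok]
  dosage <- dosage[ok]
  n <- length(meth)
  if (n < 3) abort("undefined fit: fewer than 3 paired observations")
  if (length(unique(dosage)) < 2) {
    abort("undefined fit: dosage is constant across samples")
  }
  if (length(unique(meth)) < 2) {
    abort("undefined fit: methylation is constant across samples")
  }
  fit <- lm(meth ~ dosage)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  ct <- suppressWarnings(cor.test(dosage, meth))
  fitted_means <- setNames(intercept + slope * (0:2), c("0", "1", "2"))
  predicted <- if (loo) {
    vapply(seq_len(n), function(i) {
      f <- lm(meth[-i] ~ dosage[-i])
      fm <- coef(f)[1] + coef(f)[2] * (0:2)
      predict_genotype(meth[i], fm)
    }, numeric(1))
  } else {
    predict_genotype(meth, fitted_means)
  }
  structure(
    list(
      slope = slope, intercept = intercept,
      r = unname(ct$estimate), p_value = ct$p.value, n = n,
      fitted_means = fitted_means,
      accuracy = mean(predicted == dosage),
      data = tibble(dosage = dosage, meth = meth)
    ),
    class = "cpg_snp_fit"
  )
}

#' @export
print.cpg_snp_fit <- function(x, ...) {
  cat(sprintf(
    "<cpg_snp_fit> n = %d, slope = %.4f, r = %.3f, p = %.3g, accuracy = %.3f\n",
    x$n, x$slope, x$r, x$p_value, x$accuracy
  ))
  cat(sprintf("  fitted means (dosage 0/1/2): %.3f / %.3f / %.3f\n",
              x$fitted_means[1], x$fitted_means[2], x$fitted_means[3]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy cpg_snp_fit
#' @export
tidy.cpg_snp_fit <- function(x, ...) {
  se_slope <- if (abs(x$r) < 1) {
    abs(x$slope) / abs(x$r) * sqrt((1 - x$r^2) / (x$n - 2))
  } else {
    0
  }
  tibble(
    term = c("intercept", "dosage"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, se_slope),
    p.value = c(NA_real_, x$p_value)
  )
}

#' @method glance cpg_snp_fit
#' @export
glance.cpg_snp_fit <- function(x, ...) {
  tibble(
    r = x$r, r.squared = x$r^2, p.value = x$p_value,
    accuracy = x$accuracy, n = x$n
  )
}

#' Predict genotype dosage from a methylation level
#'
#' Selects the genotype whose fitted mean methylation is closest to the
#' observed level; ties break toward the smaller dosage.
#'
#' @param meth_value Methylation value(s).
#' @param fitted_means Numeric length-3 vector of methylation means at
#'   dosages 0, 1, 2 (in that order).
#' @return Integer dosage(s) in `{0, 1, 2}`.
#' @export
#' @examples
#' predict_genotype(0.9, c(0, 0.5, 1))   # 2
#' predict_genotype(0.25, c(0, 0.5, 1))  # equidistant -> 0
predict_genotype <- function(meth_value, fitted_means) {
  stopifnot(length(fitted_means) == 3)
  d <- abs(outer(meth_value, as.numeric(fitted_means), "-"))
  max.col(-d, ties.method = "first") - 1L
}

#' Correlate one CpG against all SNPs within a window
#'
#' Fits the genotype-methylation model for every SNP whose position lies
#' within `window_bp` of the CpG's forward-C position (inclusive at the
#' boundary). SNPs with undefined fits (monomorphic in the cohort) are
#' returned with `NA` statistics.
#'
#' @param cpg One-row tibble or list with `chrom`, `pos` (and optionally
#'   `cpg_id`).
#' @param snps SNP table: `snp_id`, `chrom`, `pos`.
#' @param genotypes Long dosage table: `snp_id`, `individual_id`, `dosage`.
#' @param meth Per-sample methylation at this CpG: tibble `sample_id`,
#'   `individual_id`, `rate`.
#' @param window_bp Window half-width in bp (default 10000).
#' @param loo Passed to [fit_cpg_snp()].
#' @return Tibble, one row per in-window SNP, sorted by decreasing `|r|`
#'   (ties: distance, then `snp_id`): fit statistics plus `distance` and
#'   `fitted_mean0/1/2`. Empty (zero-row) when no SNP is in the window.
#' @export
scan_window <- function(cpg, snps, genotypes, meth, window_bp = 10000,
                        loo = FALSE) {
  hits <- snps |>
    filter(.data$chrom == cpg$chrom,
           abs(.data$pos - cpg$pos) <= window_bp)
  template <- tibble(
    cpg_id = character(), snp_id = character(), distance = integer(),
    n = integer(), slope = double(), intercept = double(), r = double(),
    p_value = double(), accuracy = double(),
    fitted_mean0 = double(), fitted_mean1 = double(), fitted_mean2 = double()
  )
  if (nrow(hits) == 0) return(template)
  cpg_id <- if (!is.null(cpg$cpg_id)) cpg$cpg_id else
    paste0(cpg$chrom, ":", cpg$pos)
  rows <- purrr::map(seq_len(nrow(hits)), function(i) {
    dos <- genotypes |>
      filter(.data$snp_id == hits$snp_id[i]) |>
      select("individual_id", "dosage")
    d <- inner_join(meth, dos, by = "individual_id")
    fit <- tryCatch(fit_cpg_snp(d$rate, d$dosage, loo = loo),
                    error = function(e) NULL)
    base <- tibble(
      cpg_id = cpg_id, snp_id = hits$snp_id[i],
      distance = abs(hits$pos[i] - cpg$pos)
    )
    if (is.null(fit)) {
      mutate(base, n = nrow(d), slope = NA_real_, intercept = NA_real_,
             r = NA_real_, p_value = NA_real_, accuracy = NA_real_,
             fitted_mean0 = NA_real_, fitted_mean1 = NA_real_,
             fitted_mean2 = NA_real_)
    } else {
      mutate(base, n = fit$n, slope = fit$slope, intercept = fit$intercept,
             r = fit$r, p_value = fit$p_value, accuracy = fit$accuracy,
             fitted_mean0 = fit$fitted_means[[1]],
             fitted_mean1 = fit$fitted_means[[2]],
             fitted_mean2 = fit$fitted_means[[3]])
    }
  })
  bind_rows(rows) |>
    arrange(desc(abs(.data$r)), .data$distance, .data$snp_id)
}

#' Correlate many CpGs against nearby SNPs
#'
#' Convenience wrapper running [scan_window()] for each requested CpG of a
#' methylation matrix.
#'
#' @param rates Long pooled-rate tibble (`chrom`, `pos`, `sample_id`,
#'   `rate`), e.g. from [pooled_rates()].
#' @param cpgs Tibble of CpGs to test: `chrom`, `pos` (optionally `cpg_id`).
#' @param snps,genotypes,window_bp,loo See [scan_window()].
#' @param sample_map Tibble `sample_id`, `individual_id`.
#' @return Row-bound [scan_window()] results.
#' @export
scan_cpgs <- function(rates, cpgs, snps, genotypes, sample_map,
                      window_bp = 10000, loo = FALSE) {
  rates <- inner_join(rates, sample_map, by = "sample_id")
  purrr::map(seq_len(nrow(cpgs)), function(i) {
    cpg <- cpgs[i, ]
    meth <- rates |>
      filter(.data$chrom == cpg$chrom, .data$pos == cpg$pos) |>
      select("sample_id", "individual_id", "rate")
    if (nrow(meth) == 0) return(NULL)
    res <- scan_window(cpg, snps, genotypes, meth, window_bp = window_bp,
                       loo = loo)
    if (!is.null(cpg$cpg_id)) res$cpg_id <- cpg$cpg_id
    res |> mutate(chrom = cpg$chrom, pos = cpg$pos, .after = "cpg_id")
  }) |>
    bind_rows()
}

#' Classify genotype-correlated and highly predictive CpGs
#'
#' Keeps each CpG's best SNP (largest `|r|`; ties broken by proximity then
#' `snp_id`) and applies the fixed thresholds of the leakage analysis:
#' *correlated* requires `|r| > r_min` and `p < p_max` (both strict);
#' *highly predictive* additionally requires `accuracy > accuracy_min`.
#'
#' @param results Tibble of fit results (from [scan_window()] /
#'   [scan_cpgs()]): needs `cpg_id`, `snp_id`, `distance`, `r`, `p_value`,
#'   `accuracy`.
#' @param r_min,p_max,accuracy_min Classification thresholds (defaults 0.5,
#'   0.05, 0.98).
#' @param adjust_p Apply Benjamini-Hochberg adjustment to p-values before
#'   thresholding (default `FALSE`; the reference analysis uses raw fixed
#'   thresholds).
#' @return Per-CpG tibble: best-SNP columns plus logicals `correlated` and
#'   `highly_predictive`. Empty input yields an empty tibble.
#' @export
classify_candidates <- function(results, r_min = 0.5, p_max = 0.05,
                                accuracy_min = 0.98, adjust_p = FALSE) {
  if (nrow(results) == 0) {
    return(mutate(results, correlated = logical(0),
                  highly_predictive = logical(0)))
  }
  results |>
    mutate(p_used = if (adjust_p) p.adjust(.data$p_value, "BH") else .data$p_value) |>
    group_by(.data$cpg_id) |>
    arrange(desc(abs(.data$r)), .data$distance, .data$snp_id,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    mutate(
      correlated = !is.na(.data$r) & abs(.data$r) > r_min &
        .data$p_used < p_max,
      highly_predictive = .data$correlated & !is.na(.data$accuracy) &
        .data$accuracy > accuracy_min
    ) |>
    select(-"p_used")
}

#' Does a catalog SNP fall directly inside a CpG dyad?
#'
#' @param chrom,pos CpG coordinates (0-based forward C); the dyad is
#'   `[pos, pos + 2)`.
#' @param catalog Catalog tibble (see [read_snp_catalog()]).
#' @return Logical vector.
#' @export
direct_overlap <- function(chrom, pos, catalog) {
  catalog_overlaps(catalog, chrom, pos, width = 2)
}

#' Pairwise inter-sample correlation at selected CpGs
#'
#' Computes, for every supplied sample pair, the Pearson correlation of their
#' methylation beta vectors over the selected CpGs — the twin-analysis view in
#' which genotype-driven CpGs make monozygotic twins nearly perfectly
#' correlated, dizygotic twins less so, and unrelated pairs least.
#'
#' @param betas Long tibble `cpg_id`, `sample_id`, `beta`.
#' @param pairs Tibble `sample_a`, `sample_b`, `relationship`.
#' @param min_shared Minimum shared non-missing CpGs per pair (default 2);
#'   pairs below it are skipped and counted.
#' @return List of class `pairwise_correlation`: `pairs` (per-pair `r` and
#'   `n_cpgs`), `groups` (per-relationship mean/median/quartiles of `r`),
#'   `n_skipped`.
#' @export
pairwise_sample_correlation <- function(betas, pairs, min_shared = 2) {
  wide <- betas |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "beta")
  res <- purrr::map(seq_len(nrow(pairs)), function(i) {
    a <- pairs$sample_a[i]
    b <- pairs$sample_b[i]
    if (!a %in% names(wide) || !b %in% names(wide)) return(NULL)
    x <- wide[[a]]
    y <- wide[[b]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_shared) return(NULL)
    tibble(sample_a = a, sample_b = b,
           relationship = pairs$relationship[i],
           n_cpgs = sum(ok), r = cor(x[ok], y[ok]))
  })
  kept <- bind_rows(res)
  groups <- if (nrow(kept) > 0) {
    kept |>
      group_by(.data$relationship) |>
      summarise(
        n_pairs = dplyr::n(),
        mean_r = mean(.data$r),
        median_r = median(.data$r),
        q25 = unname(quantile(.data$r, 0.25)),
        q75 = unname(quantile(.data$r, 0.75)),
        .groups = "drop"
      )
  } else {
    tibble(relationship = character(), n_pairs = integer(),
           mean_r = double(), median_r = double(), q25 = double(),
           q75 = double())
  }
  structure(
    list(pairs = kept, groups = groups,
         n_skipped = nrow(pairs) - nrow(kept)),
    class = "pairwise_correlation"
  )
}

#' @export
print.pairwise_correlation <- function(x, ...) {
  cat(sprintf("<pairwise_correlation> %d pairs (%d skipped)\n",
              nrow(x$pairs), x$n_skipped))
  print(x$groups)
  invisible(x)
}
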