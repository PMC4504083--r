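#' Screen for CpGs whose methylation is static within individuals but
#' variable between them
#'
#' A CpG whose measured methylation barely varies across tissues of the same
#' individual yet differs strongly between individuals behaves like a genotype
#' rather than an epigenotype. This screen flags such candidate
#' genotype-leaking sites: a site is a candidate when (a) strictly more than
#' half of the individuals assessable at the site (those with at least
#' `min_samples_per_individual` measured samples) have a within-individual
#' standard deviation below `sd_threshold`, and (b) the range of methylation
#' across *all* measured samples is at least `min_range`. Samples below
#' `min_coverage` combined-strand reads are treated as missing at that site.
#' The standard deviation is the population SD (divisor n), fixed so results
#' are exactly reproducible.
#'
#' @param rates Long tibble of pooled-strand rates: `chrom`, `pos`,
#'   `sample_id`, `rate`, and optionally `coverage` (assumed sufficient when
#'   absent). See [pooled_rates()].
#' @param sample_map Tibble `sample_id`, `individual_id`.
#' @param min_samples_per_individual Samples an individual needs at a site to
#'   be assessable there (default 3).
#' @param sd_threshold Within-individual SD below which an individual counts
#'   as "static" (default 0.07).
#' @param min_range Minimum methylation range across all measured samples
#'   (default 0.15).
#' @param min_coverage Minimum combined-strand reads for a measurement to
#'   count (default 4).
#' @return Per-site tibble: `chrom`, `pos`, `n_measured`, `n_assessable`,
#'   `n_static`, `range`, `status` (`"candidate"`, `"not_candidate"`,
#'   `"unassessable"`) and logical `candidate`. Sites with no assessable
#'   individual are marked unassessable and never candidates.
#' @export
screen_static_cpgs <- function(rates, sample_map,
                               min_samples_per_individual = 3,
                               sd_threshold = 0.07,
                               min_range = 0.15,
                               min_coverage = 4) {
  stopifnot(all(c("chrom", "pos", "sample_id", "rate") %in% names(rates)))
  if (any(rates$rate < 0 | rates$rate > 1, na.rm = TRUE)) {
    abort("methylation rates must lie in [0, 1]")
  }
  measured <- rates |>
    filter(!is.na(.data$rate)) |>
    {\(d) if ("coverage" %in% names(d)) filter(d, .data$coverage >= min_coverage) else d}() |>
    inner_join(sample_map, by = "sample_id")

  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

  per_ind <- measured |>
    group_by(.data$chrom, .data$pos, .data$individual_id) |>
    summarise(n = dplyr::n(), ind_sd = sd_pop(.data$rate), .groups = "drop") |>
    filter(.data$n >= min_samples_per_individual)

  ind_stats <- per_ind |>
    group_by(.data$chrom, .data$pos) |>
    summarise(
      n_assessable = dplyr::n(),
      n_static = sum(.data$ind_sd < sd_threshold),
      .groups = "drop"
    )

  site_stats <- measured |>
    group_by(.data$chrom, .data$pos) |>
    summarise(
      n_measured = dplyr::n(),
      range = max(.data$rate) - min(.data$rate),
      .groups = "drop"
    )

  site_stats |>
    left_join(ind_stats, by = c("chrom", "pos")) |>
    mutate(
      n_assessable = tidyr::replace_na(.data$n_assessable, 0L),
      n_static = tidyr::replace_na(.data$n_static, 0L),
      candidate = .data$n_assessable > 0 &
        .data$n_static > .data$n_assessable / 2 &
        .data$range >= min_range,
      status = dplyr::case_when(
        .data$n_assessable == 0 ~ "unassessable",
        .data$candidate ~ "candidate",
        .default = "not_candidate"
      )
    ) |>
    arrange(.data$chrom, .data$pos)
}

#' Derive screen thresholds from empirical percentiles
#'
#' Percentile-based calibration of the static-methylation screen: the SD
#' threshold is set so a stated fraction of within-individual SDs fall below
#' it (default: bottom 70%), and the range threshold so a stated fraction of
#' per-site ranges lie above it (default: top 35%).
#'
#' @inheritParams screen_static_cpgs
#' @param sd_quantile Quantile of within-individual SDs used as
#'   `sd_threshold`.
#' @param range_top_fraction Fraction of sites whose range should exceed
#'   `min_range`.
#' @return List with `sd_threshold` and `min_range`.
#' @export
derive_screen_thresholds <- function(rates, sample_map,
                                     sd_quantile = 0.70,
                                     range_top_fraction = 0.35,
                                     min_samples_per_individual = 3,
                                     min_coverage = 4) {
  measured <- rates |>
    filter(!is.na(.data$rate)) |>
    {\(d) if ("coverage" %in% names(d)) filter(d, .data$coverage >= min_coverage) else d}() |>
    inner_join(sample_map, by = "sample_id")
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  sds <- measured |>
    group_by(.data$chrom, .data$pos, .data$individual_id) |>
    summarise(n = dplyr::n(), ind_sd = sd_pop(.data$rate), .groups = "drop") |>
    filter(.data$n >= min_samples_per_individual)
  ranges <- measured |>
    group_by(.data$chrom, .data$pos) |>
    summarise(range = max(.data$rate) - min(.data$rate), .groups = "drop")
  list(
    sd_threshold = unname(quantile(sds$ind_sd, sd_quantile)),
    min_range = unname(quantile(ranges$range, 1 - range_top_fraction))
  )
}

#' Candidate yield under permuted individual labels
#'
#' Estimates the false-positive yield of [screen_static_cpgs()] by permuting
#' the sample-to-individual assignment and re-running the screen. The
#' permutation preserves the multiset of individual labels (group sizes), so
#' the screen's assessability structure is comparable.
#'
#' @inheritParams screen_static_cpgs
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param ... Screen parameters passed to [screen_static_cpgs()].
#' @return A list of class `perm_yield`: `yields` (tibble `perm`,
#'   `n_candidates`), `mean`, `sd`, and 95% interval bounds `lower`/`upper`.
#' @export
permutation_null_yield <- function(rates, sample_map, n_perm = 20, seed = 1,
                                   ...) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (nrow(sample_map) < length(unique(sample_map$individual_id))) {
    abort("fewer samples than individuals: permutation is ill-defined")
  }
  counts <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      permuted <- sample_map
      permuted$individual_id <- sample(permuted$individual_id)
      res <- screen_static_cpgs(rates, permuted, ...)
      sum(res$candidate)
    }, numeric(1))
  })
  structure(
    list(
      yields = tibble(perm = seq_len(n_perm), n_candidates = counts),
      mean = mean(counts),
      sd = if (n_perm > 1) sd(counts) else NA_real_,
      lower = unname(quantile(counts, 0.025)),
      upper = unname(quantile(counts, 0.975))
    ),
    class = "perm_yield"
  )
}

#' @export
print.perm_yield <- function(x, ...) {
  cat(sprintf(
    "<perm_yield> %d permutations: mean candidate yield %.2f (95%% interval %g-%g)\n",
    nrow(x$yields), x$mean, x$lower, x$upper
  ))
  invisible(x)
}
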