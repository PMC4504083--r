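#' Differentially methylated CpGs between two samples
#'
#' Pools strands per dyad in each sample and reports sites with substantial
#' coverage in *both* samples (`>= min_cov`, pooled strands) and a methylation
#' rate difference strictly greater than `min_diff` — the thresholds used when
#' auditing pairwise differential methylation for SNP confounding are a >30
#' percentage-point difference at >=15x coverage.
#'
#' @param calls_a,calls_b Stranded call tibbles for the two samples
#'   (`chrom`, `pos`, `strand`, `meth_count`, `unmeth_count`).
#' @param min_cov Minimum pooled-strand coverage in each sample (default 15,
#'   non-strict: `>=`).
#' @param min_diff Minimum absolute rate difference (default 0.30, strict:
#'   `>`).
#' @return Tibble `chrom`, `pos`, `rate_a`, `rate_b`, `delta`
#'   (`rate_a - rate_b`), `cov_a`, `cov_b` of the differential sites. A
#'   warning is raised when the samples share no sufficiently covered site.
#' @export
differential_cpgs <- function(calls_a, calls_b, min_cov = 15,
                              min_diff = 0.30) {
  pool <- function(calls) {
    calls |>
      group_by(.data$chrom, .data$pos) |>
      summarise(
        coverage = sum(.data$meth_count + .data$unmeth_count),
        meth = sum(.data$meth_count),
        .groups = "drop"
      ) |>
      filter(.data$coverage > 0) |>
      mutate(rate = .data$meth / .data$coverage)
  }
  shared <- inner_join(
    pool(calls_a), pool(calls_b),
    by = c("chrom", "pos"), suffix = c("_a", "_b")
  ) |>
    filter(.data$coverage_a >= min_cov, .data$coverage_b >= min_cov)
  if (nrow(shared) == 0) {
    warn("no shared sufficiently covered sites between the two samples")
  }
  shared |>
    mutate(delta = .data$rate_a - .data$rate_b) |>
    filter(abs(.data$delta) > min_diff) |>
    select("chrom", "pos", "rate_a", "rate_b", "delta",
           cov_a = "coverage_a", cov_b = "coverage_b")
}

## does any non-reference PASS call overlap each dyad?
variant_in_dyad <- function(chrom, pos, variant_calls) {
  n <- length(pos)
  if (is.null(variant_calls) || nrow(variant_calls) == 0) {
    return(rep(FALSE, n))
  }
  hits <- variant_calls |>
    filter(.data$filter == "PASS", .data$genotype != "C/C")
  if (nrow(hits) == 0) return(rep(FALSE, n))
  key <- paste(hits$chrom, hits$pos)
  paste(chrom, pos) %in% key | paste(chrom, pos + 1L) %in% key
}

#' Audit a sample pair for SNP confounding of differential methylation
#'
#' Counts how many differential CpGs between two samples carry a detected
#' sequence variant (a non-reference PASS genotype call within the dyad) in
#' one or both samples. Pairs comparing the same cell type across individuals
#' isolate genetic effects; pairs comparing tissues within one individual
#' isolate epigenetic effects.
#'
#' @param diff_sites Output of [differential_cpgs()].
#' @param variant_calls_a,variant_calls_b Genotype call tibbles (from
#'   [call_genotypes()]) for the two samples.
#' @param sample_a,sample_b Sample identifiers of the pair.
#' @param sample_meta Sample sheet (`sample_id`, `individual_id`, `tissue`).
#' @return One-row tibble: `sample_a`, `sample_b`, `pair_type`
#'   (`"same_individual_diff_tissue"`, `"same_tissue_diff_individual"` or
#'   `"both_differ"`), `n_diff_cpgs`, `n_overlapping_snp`,
#'   `fraction_overlap` (`NA` when there are no differential CpGs).
#' @export
audit_pair <- function(diff_sites, variant_calls_a, variant_calls_b,
                       sample_a, sample_b, sample_meta) {
  meta <- function(s) {
    row <- sample_meta[sample_meta$sample_id == s, ]
    if (nrow(row) != 1) {
      abort(paste0("sample missing from the sample sheet: ", s))
    }
    row
  }
  ma <- meta(sample_a)
  mb <- meta(sample_b)
  same_ind <- ma$individual_id == mb$individual_id
  same_tissue <- ma$tissue == mb$tissue
  if (same_ind && same_tissue) {
    abort("pair is a technical replicate (same individual, same tissue)")
  }
  pair_type <- dplyr::case_when(
    same_ind ~ "same_individual_diff_tissue",
    same_tissue ~ "same_tissue_diff_individual",
    .default = "both_differ"
  )
  n_diff <- nrow(diff_sites)
  overlap <- variant_in_dyad(diff_sites$chrom, diff_sites$pos,
                             variant_calls_a) |
    variant_in_dyad(diff_sites$chrom, diff_sites$pos, variant_calls_b)
  tibble(
    sample_a = sample_a, sample_b = sample_b, pair_type = pair_type,
    n_diff_cpgs = n_diff,
    n_overlapping_snp = sum(overlap),
    fraction_overlap = if (n_diff > 0) sum(overlap) / n_diff else NA_real_
  )
}

#' Audit many sample pairs of a cohort
#'
#' Runs [differential_cpgs()] + [audit_pair()] for each supplied pair, using
#' per-sample stranded calls and genotype calls.
#'
#' @param pairs Tibble `sample_a`, `sample_b`.
#' @param calls Long stranded calls for all samples (with `sample_id`).
#' @param variant_calls Genotype calls for all samples (with `sample_id`).
#' @param sample_meta Sample sheet.
#' @param min_cov,min_diff See [differential_cpgs()].
#' @return Row-bound [audit_pair()] results.
#' @export
audit_pairs <- function(pairs, calls, variant_calls, sample_meta,
                        min_cov = 15, min_diff = 0.30) {
  purrr::map(seq_len(nrow(pairs)), function(i) {
    a <- pairs$sample_a[i]
    b <- pairs$sample_b[i]
    diff_sites <- differential_cpgs(
      filter(calls, .data$sample_id == a),
      filter(calls, .data$sample_id == b),
      min_cov = min_cov, min_diff = min_diff
    )
    audit_pair(
      diff_sites,
      filter(variant_calls, .data$sample_id == a),
      filter(variant_calls, .data$sample_id == b),
      a, b, sample_meta
    )
  }) |>
    bind_rows()
}
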