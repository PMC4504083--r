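#' Sanitize a methylation track before open release
#'
#' Removes CpG dyads that carry direct genetic variation from a per-sample
#' methylation track, with a per-site accounting of why each record was
#' dropped. Removal reasons, in fixed precedence:
#'
#' 1. `called_variant` — a non-reference PASS genotype call overlaps the dyad
#'    (`policy` `"detected"` or `"both"`);
#' 2. `catalog` — a known catalog SNP overlaps the dyad (`policy`
#'    `"catalog"` or `"both"`);
#' 3. `unclear_context` — the cytosine context cannot be trusted: the
#'    genotype call is `AMBIGUOUS`, or the strand evidence is discordant with
#'    no resolving PASS genotype at the site (`"detected"`/`"both"`).
#'
#' `LOW_COV` calls do not trigger removal: insufficient evidence is not
#' evidence of a variant. Retained records are bit-identical to the input.
#'
#' @param track Tibble with `chrom`, `pos` (0-based forward C) and any value
#'   columns; when the strand count columns `fwd_meth`, `fwd_unmeth`,
#'   `rev_meth`, `rev_unmeth` are present, strand discordance is assessed via
#'   [strand_asymmetry()].
#' @param variant_calls Genotype calls for this sample (required for
#'   `"detected"`/`"both"`).
#' @param catalog SNP catalog (required for `"catalog"`/`"both"`).
#' @param policy `"detected"`, `"catalog"` or `"both"`.
#' @param diff_threshold,p_threshold Discordance parameters, see
#'   [strand_asymmetry()].
#' @return List of class `sanitized_track`: `track` (retained rows),
#'   `removed` (`chrom`, `pos`, `reason`) and `report` (a
#'   `sanitization_report`: totals per reason and the retention fraction).
#' @export
sanitize_track <- function(track, variant_calls = NULL, catalog = NULL,
                           policy = c("detected", "catalog", "both"),
                           diff_threshold = 0.2, p_threshold = 0.01) {
  policy <- match.arg(policy)
  if (policy %in% c("detected", "both") && is.null(variant_calls)) {
    abort(paste0("policy '", policy, "' requires variant calls"))
  }
  if (policy %in% c("catalog", "both") && is.null(catalog)) {
    abort(paste0("policy '", policy, "' requires a SNP catalog"))
  }
  n <- nrow(track)
  called <- rep(FALSE, n)
  unclear <- rep(FALSE, n)
  in_catalog <- rep(FALSE, n)

  if (policy %in% c("detected", "both")) {
    called <- variant_in_dyad(track$chrom, track$pos, variant_calls)
    ambiguous <- call_status_in_dyad(track$chrom, track$pos, variant_calls,
                                     "AMBIGUOUS")
    resolved <- call_status_in_dyad(track$chrom, track$pos, variant_calls,
                                    "PASS")
    discordant <- rep(FALSE, n)
    strand_cols <- c("fwd_meth", "fwd_unmeth", "rev_meth", "rev_unmeth")
    if (all(strand_cols %in% names(track))) {
      discordant <- strand_asymmetry(track, diff_threshold,
                                     p_threshold)$status == "DISCORDANT"
    }
    unclear <- ambiguous | (discordant & !resolved)
  }
  if (policy %in% c("catalog", "both")) {
    in_catalog <- catalog_overlaps(catalog, track$chrom, track$pos, width = 2)
  }

  reason <- dplyr::case_when(
    called ~ "called_variant",
    in_catalog ~ "catalog",
    unclear ~ "unclear_context",
    .default = NA_character_
  )
  keep <- is.na(reason)
  report <- structure(
    list(
      n_total_sites = n,
      n_removed_called_variant = sum(reason == "called_variant", na.rm = TRUE),
      n_removed_catalog = sum(reason == "catalog", na.rm = TRUE),
      n_removed_unclear_context = sum(reason == "unclear_context", na.rm = TRUE),
      n_retained = sum(keep),
      retention_fraction = if (n > 0) sum(keep) / n else NA_real_,
      policy = policy
    ),
    class = "sanitization_report"
  )
  structure(
    list(
      track = track[keep, , drop = FALSE],
      removed = tibble(chrom = track$chrom[!keep], pos = track$pos[!keep],
                       reason = reason[!keep]),
      report = report
    ),
    class = "sanitized_track"
  )
}

## any call with the given FILTER status (non-reference not required for
## AMBIGUOUS: an ambiguous site is unclear whatever its best genotype)
call_status_in_dyad <- function(chrom, pos, variant_calls, status) {
  n <- length(pos)
  if (is.null(variant_calls) || nrow(variant_calls) == 0) {
    return(rep(FALSE, n))
  }
  hits <- filter(variant_calls, .data$filter == status)
  if (nrow(hits) == 0) return(rep(FALSE, n))
  key <- paste(hits$chrom, hits$pos)
  paste(chrom, pos) %in% key | paste(chrom, pos + 1L) %in% key
}

#' @export
print.sanitization_report <- function(x, ...) {
  cat(sprintf(
    "<sanitization_report> policy '%s': %d sites, retained %d (%.1f%%)\n  removed: %d called variant, %d catalog, %d unclear context\n",
    x$policy, x$n_total_sites, x$n_retained, 100 * x$retention_fraction,
    x$n_removed_called_variant, x$n_removed_catalog,
    x$n_removed_unclear_context
  ))
  invisible(x)
}

#' @export
print.sanitized_track <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' @method tidy sanitization_report
#' @export
tidy.sanitization_report <- function(x, ...) {
  tibble(
    reason = c("called_variant", "catalog", "unclear_context", "retained"),
    n = c(x$n_removed_called_variant, x$n_removed_catalog,
          x$n_removed_unclear_context, x$n_retained)
  )
}

#' @method glance sanitization_report
#' @export
glance.sanitization_report <- function(x, ...) {
  tibble(
    policy = x$policy, n_total_sites = x$n_total_sites,
    n_retained = x$n_retained, retention_fraction = x$retention_fraction
  )
}

#' Verify that a sanitized track is clean under a policy
#'
#' Release gate: recomputes the removable set on a (supposedly) sanitized
#' track and fails if any retained dyad would still be removed. Sanitization
#' is idempotent, so a track straight out of [sanitize_track()] always
#' passes.
#'
#' @param track Retained track tibble (e.g. `sanitize_track(...)$track`).
#' @inheritParams sanitize_track
#' @return List with `pass` (logical) and `violations` (tibble of offending
#'   sites with reasons).
#' @export
verify_sanitized <- function(track, variant_calls = NULL, catalog = NULL,
                             policy = c("detected", "catalog", "both"),
                             diff_threshold = 0.2, p_threshold = 0.01) {
  res <- sanitize_track(track, variant_calls, catalog, policy,
                        diff_threshold, p_threshold)
  list(pass = nrow(res$removed) == 0, violations = res$removed)
}
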