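## Strand-level auditing of CpG methylation: discordance between the two
## strands of a dyad is the C>A / C>G heterozygote signature, and the
## reverse-strand base composition at the forward-C position carries the
## genotype directly.

logsumexp_rows <- function(x) {
  m <- apply(x, 1, max)
  m + log(rowSums(exp(x - m)))
}

#' Strand asymmetry of methylation at CpG dyads
#'
#' For each site, computes the forward-minus-reverse methylation rate
#' difference and an exact two-proportion test (Fisher's exact test on the
#' 2x2 methylated/unmethylated by strand table). A site is *discordant* when
#' the absolute difference exceeds `diff_threshold` and the exact test is
#' significant at `p_threshold`. Sites with zero coverage on either strand
#' are flagged `NOT_ASSESSABLE`.
#'
#' @param evidence Tibble with `fwd_meth`, `fwd_unmeth`, `rev_meth`,
#'   `rev_unmeth` (other columns pass through).
#' @param diff_threshold Minimum |forward - reverse| rate difference
#'   (default 0.2).
#' @param p_threshold Significance level of the exact test (default 0.01).
#' @return Input with added `fwd_rate`, `rev_rate`, `difference`, `p_value`
#'   and `status` (`"DISCORDANT"`, `"CONCORDANT"`, `"NOT_ASSESSABLE"`).
#' @export
#' @examples
#' strand_asymmetry(tibble::tibble(
#'   fwd_meth = 20, fwd_unmeth = 0, rev_meth = 10, rev_unmeth = 10
#' ))
strand_asymmetry <- function(evidence, diff_threshold = 0.2,
                             p_threshold = 0.01) {
  fwd_tot <- evidence$fwd_meth + evidence$fwd_unmeth
  rev_tot <- evidence$rev_meth + evidence$rev_unmeth
  assessable <- fwd_tot > 0 & rev_tot > 0
  fwd_rate <- ifelse(fwd_tot > 0, evidence$fwd_meth / fwd_tot, NA_real_)
  rev_rate <- ifelse(rev_tot > 0, evidence$rev_meth / rev_tot, NA_real_)
  difference <- fwd_rate - rev_rate
  p_value <- rep(NA_real_, nrow(evidence))
  idx <- which(assessable)
  p_value[idx] <- vapply(idx, function(i) {
    fisher.test(matrix(c(
      evidence$fwd_meth[i], evidence$fwd_unmeth[i],
      evidence$rev_meth[i], evidence$rev_unmeth[i]
    ), nrow = 2, byrow = TRUE))$p.value
  }, numeric(1))
  evidence |>
    mutate(
      fwd_rate = fwd_rate, rev_rate = rev_rate,
      difference = difference, p_value = p_value,
      status = dplyr::case_when(
        !assessable ~ "NOT_ASSESSABLE",
        abs(difference) > diff_threshold & p_value < p_threshold ~ "DISCORDANT",
        .default = "CONCORDANT"
      )
    )
}

## expected counted-forward-read methylation rate, reverse rate and forward
## coverage factor for every genotype x methylation-grid combination
caller_rate_table <- function(genotypes, meth_grid, error_rate,
                              cph_methylation_rate) {
  tidyr::expand_grid(genotype = genotypes, m = meth_grid) |>
    (\(d) bind_cols(
      d,
      apply_disruption_accounting(
        d$genotype, d$m,
        sequencing_error_rate = error_rate,
        cph_methylation_rate = cph_methylation_rate
      )[, c("fwd_rate", "rev_rate", "fwd_coverage_factor")]
    ))()
}

#' Call diploid genotypes at CpG cytosines from bisulfite evidence
#'
#' A simplified Bis-SNP-style caller operating on per-site count summaries
#' (no base-quality recalibration or realignment). For each site the
#' posterior over the ten diploid genotypes combines:
#'
#' * a multinomial likelihood of the reverse-strand base counts given the
#'   genotype's complementary base mixture with per-read error `error_rate`;
#' * binomial likelihoods of the methylated/unmethylated counts on each
#'   strand given the genotype's expected rates from
#'   [apply_disruption_accounting()], with the unknown true methylation
#'   marginalized uniformly over `meth_grid`. Genotypes with no countable
#'   forward allele (A/A, A/G, G/G) explain observed forward-counted reads
#'   only as errors: each contributes `log(error_rate)` plus an uninformative
#'   1/2 methylation split;
#' * a genotype prior: in `"rare"` mode, mass `1 - theta` on the C/C
#'   reference and `theta` split evenly over the nine variant genotypes (the
#'   worst-case assumption of rare SNPs with no external information); in
#'   `"catalog"` mode, Hardy-Weinberg priors from the catalog allele
#'   frequency at sites with a known SNP (other sites fall back to rare).
#'
#' @param evidence Tibble with `fwd_meth`, `fwd_unmeth`, `rev_meth`,
#'   `rev_unmeth`, `rev_A`, `rev_C`, `rev_G`, `rev_T`; identifying columns
#'   (`chrom`, `pos`, `sample_id`, ...) pass through.
#' @param prior_mode `"rare"` or `"catalog"`.
#' @param theta Prior mass on non-reference genotypes in rare mode
#'   (default 0.001, a standard human heterozygosity prior).
#' @param error_rate Per-read error probability (must be > 0; default 0.001).
#' @param cph_methylation_rate CpH methylation assumed on the reverse strand
#'   of a C>T allele.
#' @param min_depth Total read depth (both strands) below which a call is
#'   flagged `LOW_COV` (default 10).
#' @param posterior_min Posterior below which a call is flagged `AMBIGUOUS`
#'   (default 0.9).
#' @param meth_grid Methylation grid marginalized over (default
#'   `c(0, 0.5, 1)`).
#' @param catalog Catalog tibble (`chrom`, `start`, `end`, `af`, and
#'   optionally `alt`) for `"catalog"` mode.
#' @return The identifying columns of `evidence` plus `genotype` (canonical
#'   `"X/Y"`), `posterior`, `depth` and `filter`
#'   (`PASS` / `LOW_COV` / `AMBIGUOUS`). Genotype posteriors sum to 1 across
#'   the ten genotypes at every site.
#' @export
call_genotypes <- function(evidence,
                           prior_mode = c("rare", "catalog"),
                           theta = 0.001,
                           error_rate = 0.001,
                           cph_methylation_rate = 0.01,
                           min_depth = 10,
                           posterior_min = 0.9,
                           meth_grid = c(0, 0.5, 1),
                           catalog = NULL) {
  prior_mode <- match.arg(prior_mode)
  if (error_rate <= 0 || error_rate >= 1) {
    abort("error_rate must lie strictly between 0 and 1")
  }
  if (prior_mode == "catalog" && is.null(catalog)) {
    abort("catalog mode requires a `catalog`")
  }
  need <- c("fwd_meth", "fwd_unmeth", "rev_meth", "rev_unmeth",
            "rev_A", "rev_C", "rev_G", "rev_T")
  stopifnot(all(need %in% names(evidence)))
  n <- nrow(evidence)
  fwd_tot <- evidence$fwd_meth + evidence$fwd_unmeth
  rev_tot <- evidence$rev_meth + evidence$rev_unmeth
  base_counts <- as.matrix(evidence[, c("rev_A", "rev_C", "rev_G", "rev_T")])
  colnames(base_counts) <- BASES
  depth <- fwd_tot + rev_tot
  if (any(depth + rowSums(base_counts) == 0)) {
    abort("all-zero evidence row(s): nothing to call")
  }

  gts <- diploid_genotypes()
  rate_tab <- caller_rate_table(gts, meth_grid, error_rate,
                                cph_methylation_rate)
  al <- gt_alleles(gts)
  base_p <- reverse_base_probs(al[, 1], al[, 2], error_rate)

  log_prior <- genotype_log_prior(evidence, gts, prior_mode, theta, catalog)

  ll <- matrix(NA_real_, n, length(gts), dimnames = list(NULL, gts))
  for (j in seq_along(gts)) {
    g <- gts[j]
    ll_bases <- drop(base_counts %*% log(base_p[j, ]))
    rows <- rate_tab[rate_tab$genotype == g, ]
    ll_m <- matrix(NA_real_, n, nrow(rows))
    for (k in seq_len(nrow(rows))) {
      llf <- if (rows$fwd_coverage_factor[k] > 0) {
        dbinom(evidence$fwd_meth, fwd_tot, rows$fwd_rate[k], log = TRUE)
      } else {
        fwd_tot * log(error_rate) +
          dbinom(evidence$fwd_meth, fwd_tot, 0.5, log = TRUE)
      }
      llr <- dbinom(evidence$rev_meth, rev_tot, rows$rev_rate[k], log = TRUE)
      ll_m[, k] <- llf + llr
    }
    ll[, j] <- logsumexp_rows(ll_m) - log(nrow(rows)) + ll_bases +
      log_prior[, j]
  }
  post <- exp(ll - logsumexp_rows(ll))
  best <- max.col(post, ties.method = "first")

  id_cols <- intersect(c("sample_id", "cpg_id", "chrom", "pos"),
                       names(evidence))
  out <- evidence[, id_cols, drop = FALSE]
  out$genotype <- gts[best]
  out$posterior <- post[cbind(seq_len(n), best)]
  out$depth <- depth
  out$filter <- dplyr::case_when(
    depth < min_depth ~ "LOW_COV",
    out$posterior < posterior_min ~ "AMBIGUOUS",
    .default = "PASS"
  )
  attr(out, "posterior_matrix") <- post
  as_tibble(out)
}

## n x 10 matrix of log genotype priors
genotype_log_prior <- function(evidence, gts, prior_mode, theta, catalog) {
  n <- nrow(evidence)
  rare <- ifelse(gts == "C/C", 1 - theta, theta / 9)
  lp <- matrix(rep(log(rare), each = n), n, length(gts),
               dimnames = list(NULL, gts))
  if (prior_mode != "catalog") return(lp)
  if (!all(c("chrom", "pos") %in% names(evidence))) {
    abort("catalog mode needs `chrom` and `pos` columns in the evidence")
  }
  cat_snvs <- catalog |>
    filter(!is.na(.data$af), .data$end - .data$start == 1)
  if (!("alt" %in% names(cat_snvs))) cat_snvs$alt <- NA_character_
  hit <- dplyr::left_join(
    tibble(chrom = evidence$chrom, pos = evidence$pos,
           .row = seq_len(n)),
    cat_snvs |> select("chrom", start_pos = "start", "af", "alt"),
    by = dplyr::join_by("chrom", "pos" == "start_pos")
  )
  hit <- hit[!is.na(hit$af), ]
  eps <- 1e-6
  for (i in seq_len(nrow(hit))) {
    f <- hit$af[i]
    alts <- if (!is.na(hit$alt[i])) hit$alt[i] else c("A", "G", "T")
    p <- setNames(rep(eps / (length(gts)), length(gts)), gts)
    hw_mass <- (1 - eps) / length(alts)
    for (a in alts) {
      p["C/C"] <- p["C/C"] + hw_mass * (1 - f)^2
      p[genotype_string("C", a)] <- p[genotype_string("C", a)] +
        hw_mass * 2 * f * (1 - f)
      p[genotype_string(a, a)] <- p[genotype_string(a, a)] + hw_mass * f^2
    }
    lp[hit$.row[i], ] <- log(p / sum(p))
  }
  lp
}

#' Evaluate genotype calls against truth
#'
#' Heterozygote sensitivity is the fraction of truly heterozygous sites whose
#' PASS call recovers the exact genotype; the false-variant rate is the
#' fraction of all compared positions at which a PASS call asserts a wrong
#' variant (a false positive SNP, or an incorrect variant at a true SNP).
#'
#' @param calls Call tibble from [call_genotypes()].
#' @param truth Truth tibble with the same site keys (`chrom`, `pos`, and
#'   `sample_id`/`individual_id` when present in both) and a `genotype`
#'   column.
#' @return List of class `call_evaluation`: `het_sensitivity`,
#'   `false_variant_rate`, `n_compared`, `n_true_het` and a `confusion`
#'   tibble of truth-by-call counts.
#' @export
evaluate_calls <- function(calls, truth) {
  keys <- intersect(intersect(names(calls), names(truth)),
                    c("chrom", "pos", "sample_id", "individual_id", "cpg_id"))
  if (length(keys) == 0) abort("calls and truth share no key columns")
  truth <- truth |> rename(true_genotype = "genotype")
  joined <- inner_join(calls, truth, by = keys)
  if (nrow(joined) == 0) abort("calls and truth cover disjoint sites")
  het <- is_heterozygous(joined$true_genotype)
  pass <- joined$filter == "PASS"
  detected <- pass & joined$genotype == joined$true_genotype
  false_variant <- pass & joined$genotype != "C/C" &
    joined$genotype != joined$true_genotype
  structure(
    list(
      het_sensitivity = if (any(het)) mean(detected[het]) else NA_real_,
      false_variant_rate = mean(false_variant),
      n_compared = nrow(joined),
      n_true_het = sum(het),
      confusion = joined |>
        count(.data$true_genotype, .data$genotype, .data$filter) |>
        arrange(desc(.data$n))
    ),
    class = "call_evaluation"
  )
}

#' @export
print.call_evaluation <- function(x, ...) {
  cat(sprintf(
    "<call_evaluation> %d positions, %d true heterozygotes\n  het sensitivity %.3f, false-variant rate %.4f%%\n",
    x$n_compared, x$n_true_het, x$het_sensitivity,
    100 * x$false_variant_rate
  ))
  invisible(x)
}
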