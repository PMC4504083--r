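#' Strand read-accounting for variants at the CpG cytosine
#'
#' Computes the methylation rate that strand-specific bisulfite sequencing is
#' expected to *measure* on each strand of a CpG dyad, given the diploid
#' genotype at the forward-strand cytosine and the true methylation level of
#' the C allele(s). The accounting follows how a bisulfite caller scores reads:
#'
#' * a **C** allele is counted on both strands and reports the true
#'   methylation `m`;
#' * an **A** or **G** allele destroys the cytosine: its forward reads carry
#'   the alternate base and are *not counted at all*, while its reverse reads
#'   carry a normal unmethylated cytosine that converts and is counted as
#'   unmethylated;
#' * a **T** allele is indistinguishable on the forward strand from a
#'   bisulfite-converted unmethylated C, so its forward reads *are* counted
#'   (as unmethylated), and its reverse reads report CpH methylation at the
#'   mutated position.
#'
#' Consequently a C/A or C/G heterozygote at a fully methylated CpG shows
#' about 50 percentage points more methylation on the forward than on the
#' reverse strand, whereas a C/C homozygote shows no strand difference, and a
#' C/T heterozygote stays strand-concordant (both strands near `m/2`) and is
#' invisible to strand comparison.
#'
#' After the per-allele accounting, measurement error is mixed in
#' symmetrically: a read's methylation call flips with probability
#' `non_conversion_rate + sequencing_error_rate`.
#'
#' @param genotype Character vector of `"X/Y"` genotypes at the forward C
#'   (see [genotype_string()]).
#' @param true_meth True methylation proportion of the C allele(s), in
#'   `[0, 1]`. Recycled against `genotype`.
#' @param non_conversion_rate,sequencing_error_rate Per-read miscall
#'   probabilities, combined additively into a symmetric flip rate.
#' @param cph_methylation_rate Methylation rate of the cytosine in the CpH
#'   context created on the reverse strand by a C>T variant.
#' @return A tibble with one row per input: `genotype`, `true_meth`,
#'   `fwd_rate`, `rev_rate` (expected measured rates; `fwd_rate` is `NA` when
#'   no forward read is countable), and `fwd_coverage_factor` (fraction of
#'   forward-strand reads that are counted: 1 for C/C or C/T, 0.5 for C/A or
#'   C/G heterozygotes, 0 for A/A, A/G or G/G).
#' @export
#' @examples
#' apply_disruption_accounting(c("C/C", "A/C", "C/T"), 1.0,
#'   cph_methylation_rate = 0.01)
apply_disruption_accounting <- function(genotype, true_meth,
                                        non_conversion_rate = 0,
                                        sequencing_error_rate = 0,
                                        cph_methylation_rate = 0) {
  n <- max(length(genotype), length(true_meth))
  genotype <- rep_len(genotype, n)
  m <- rep_len(true_meth, n)
  if (any(m < 0 | m > 1)) abort("true_meth must lie in [0, 1]")
  al <- gt_alleles(genotype)

  counted <- function(a) as.numeric(a %in% c("C", "T"))
  fwd_meth_contrib <- function(a) ifelse(a == "C", m, 0) * counted(a)
  rev_rate_allele <- function(a) {
    ifelse(a == "C", m, ifelse(a == "T", cph_methylation_rate, 0))
  }

  n_counted <- counted(al[, 1]) + counted(al[, 2])
  fwd_pre <- ifelse(n_counted > 0,
    (fwd_meth_contrib(al[, 1]) + fwd_meth_contrib(al[, 2])) / n_counted,
    NA_real_
  )
  rev_pre <- (rev_rate_allele(al[, 1]) + rev_rate_allele(al[, 2])) / 2

  eps <- non_conversion_rate + sequencing_error_rate
  mix <- function(r) r * (1 - eps) + (1 - r) * eps

  tibble(
    genotype = genotype,
    true_meth = m,
    fwd_rate = mix(fwd_pre),
    rev_rate = mix(rev_pre),
    fwd_coverage_factor = n_counted / 2
  )
}

#' Simulate reverse-strand base evidence at a CpG cytosine
#'
#' Reverse-strand reads physically carry the base-paired complement of the
#' forward-strand allele, so the variant that silently corrupts forward-strand
#' methylation counts is directly observable as non-G bases on the reverse
#' strand. Each read samples one of the two alleles with equal probability and
#' reports its complement; with probability `sequencing_error_rate` the read
#' instead reports one of the other three bases uniformly.
#'
#' @param genotype Single `"X/Y"` genotype at the forward C.
#' @param coverage Number of reverse-strand reads.
#' @param sequencing_error_rate Per-read error probability.
#' @return Named integer vector of base counts `c(A=, C=, G=, T=)` summing to
#'   `coverage`.
#' @export
#' @examples
#' simulate_reverse_base_evidence("C/C", 20, 0)  # all G
simulate_reverse_base_evidence <- function(genotype, coverage,
                                           sequencing_error_rate = 0) {
  stopifnot(length(genotype) == 1, coverage >= 0)
  al <- gt_alleles(genotype)
  p <- reverse_base_probs(al[, 1], al[, 2], sequencing_error_rate)[1, ]
  counts <- if (coverage == 0) rep(0L, 4) else
    as.integer(rmultinom(1, coverage, p))
  setNames(counts, BASES)
}

## expected reverse-strand base distribution; returns an n x 4 matrix (A,C,G,T)
reverse_base_probs <- function(a1, a2, error_rate) {
  n <- length(a1)
  p <- matrix(0, n, 4, dimnames = list(NULL, BASES))
  for (b in BASES) {
    hit1 <- complement_base(a1) == b
    hit2 <- complement_base(a2) == b
    p[, b] <- 0.5 * ifelse(hit1, 1 - error_rate, error_rate / 3) +
      0.5 * ifelse(hit2, 1 - error_rate, error_rate / 3)
  }
  p
}

## vectorized multinomial draw of reverse base counts, one row per site
sim_rev_bases <- function(a1, a2, coverage, error_rate) {
  p <- reverse_base_probs(a1, a2, error_rate)
  out <- matrix(0L, length(a1), 4, dimnames = list(NULL, BASES))
  pos <- which(coverage > 0)
  for (i in pos) out[i, ] <- as.integer(rmultinom(1, coverage[i], p[i, ]))
  out
}

#' Simulate the strand-specific readout of a single CpG across samples
#'
#' Draws per-strand coverage (Poisson), methylated/unmethylated read counts
#' (binomial around the rates from [apply_disruption_accounting()]) and
#' reverse-strand base counts for `n_samples` independent samples sharing one
#' genotype and true methylation level. This is the single-site core of the
#' cohort simulator, exposed for strand-asymmetry experiments.
#'
#' @param genotype `"X/Y"` genotype at the forward C (one value, or one per
#'   sample).
#' @param true_meth True methylation of the C allele(s).
#' @param n_samples Number of independent samples to draw.
#' @param coverage_mean_per_strand Expected reads per strand; the forward
#'   strand mean is scaled by the genotype's countable-read fraction.
#' @param non_conversion_rate,sequencing_error_rate,cph_methylation_rate
#'   Error and context parameters, as in [apply_disruption_accounting()].
#' @return Tibble with one row per sample: coverage and methylated /
#'   unmethylated counts per strand, reverse base counts (`rev_A` ... `rev_T`)
#'   and the realized `fwd_rate` / `rev_rate` (NA at zero coverage).
#' @export
simulate_site_readout <- function(genotype, true_meth, n_samples,
                                  coverage_mean_per_strand = 30,
                                  non_conversion_rate = 0.005,
                                  sequencing_error_rate = 0.001,
                                  cph_methylation_rate = 0.01) {
  gt <- rep_len(genotype, n_samples)
  acc <- apply_disruption_accounting(
    gt, true_meth,
    non_conversion_rate = non_conversion_rate,
    sequencing_error_rate = sequencing_error_rate,
    cph_methylation_rate = cph_methylation_rate
  )
  fwd_cov <- rpois(n_samples, coverage_mean_per_strand * acc$fwd_coverage_factor)
  rev_cov <- rpois(n_samples, coverage_mean_per_strand)
  fwd_meth <- rbinom(n_samples, fwd_cov, ifelse(is.na(acc$fwd_rate), 0, acc$fwd_rate))
  rev_meth <- rbinom(n_samples, rev_cov, acc$rev_rate)
  al <- gt_alleles(gt)
  bases <- sim_rev_bases(al[, 1], al[, 2], rev_cov, sequencing_error_rate)
  tibble(
    sample = seq_len(n_samples),
    genotype = gt,
    fwd_cov = fwd_cov,
    fwd_meth = fwd_meth,
    fwd_unmeth = fwd_cov - fwd_meth,
    rev_cov = rev_cov,
    rev_meth = rev_meth,
    rev_unmeth = rev_cov - rev_meth,
    rev_A = as.vector(bases[, "A"]), rev_C = as.vector(bases[, "C"]),
    rev_G = as.vector(bases[, "G"]), rev_T = as.vector(bases[, "T"]),
    fwd_rate = ifelse(fwd_cov > 0, fwd_meth / fwd_cov, NA_real_),
    rev_rate = ifelse(rev_cov > 0, rev_meth / rev_cov, NA_real_)
  )
}

## expected pooled-strand (array-like) methylation rate for a genotype,
## weighting strands by their countable coverage
pooled_expected_rate <- function(genotype, true_meth, cph_methylation_rate = 0) {
  acc <- apply_disruption_accounting(genotype, true_meth,
    cph_methylation_rate = cph_methylation_rate
  )
  f <- acc$fwd_coverage_factor
  fwd <- ifelse(is.na(acc$fwd_rate), 0, acc$fwd_rate)
  (f * fwd + acc$rev_rate) / (f + 1)
}
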