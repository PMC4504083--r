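#' Describe a synthetic WGBS cohort
#'
#' Builds the parameter object consumed by [simulate_cohort()]. The defaults
#' emulate the structure the leakage analysis assumes: a handful of
#' individuals each contributing many tissue samples (the reference design is
#' ~50 tissue samples across five individuals), bimodal baseline CpG
#' methylation, Hardy-Weinberg genotypes with a Beta-distributed allele
#' frequency spectrum, a subset of SNPs landing inside CpG dyads where they
#' disrupt the measured methylation, and a subset of CpGs under indirect
#' (meQTL) genetic control from a SNP within 10 kb.
#'
#' @param n_individuals Number of individuals.
#' @param tissues Character vector of tissue labels; every individual yields
#'   one sample per tissue.
#' @param relationships Optional tibble with columns `individual_a`,
#'   `individual_b`, `type` (one of `"MZ"`, `"DZ"`, `"unrelated"`) pairing
#'   individuals by index. MZ pairs receive identical genotypes at every
#'   site; DZ pairs are full siblings (each parental allele shared with
#'   probability 1/2); `"unrelated"` pairs are genetically independent but
#'   tracked as a pair for twin-style analyses.
#' @param n_cpgs,n_snps Number of CpG dyads and SNPs on the simulated
#'   chromosome.
#' @param fraction_cpg_disrupting Fraction of SNPs placed at a CpG cytosine
#'   (C>A / C>G / C>T), destroying the CpG context on the alternate allele.
#' @param disruption_allele_probs Probabilities of the three disrupting
#'   alternate alleles, in the order A, G, T; must sum to 1.
#' @param fraction_indirect_meqtl Fraction of CpGs whose true methylation is
#'   shifted additively by the dosage of a linked SNP within 10 kb.
#' @param meqtl_effect Absolute per-alt-allele methylation shift (proportion
#'   units) of indirect meQTLs; the sign is randomized per CpG.
#' @param maf_beta_params Shape parameters of the Beta distribution from which
#'   alternate-allele frequencies are drawn (folded at 0.5 so the alternate is
#'   the minor allele).
#' @param coverage_mean_per_strand Expected (Poisson) reads per strand per
#'   CpG.
#' @param non_conversion_rate,sequencing_error_rate Per-read miscall rates,
#'   see [apply_disruption_accounting()].
#' @param cph_methylation_rate Methylation rate of the CpH context created on
#'   the reverse strand by a C>T variant.
#' @param tissue_effect_sd SD of the per-(CpG, tissue) methylation shift
#'   shared by all individuals. The default (0.10) makes a realistic minority
#'   of CpGs differ strongly (>30 percentage points) between tissues.
#' @param residual_sd SD of per-sample residual noise on true methylation.
#' @param baseline_mixture Two-component Beta mixture for baseline CpG
#'   methylation: a list with `weight_methylated` and shape pairs
#'   `methylated`, `unmethylated`. The default places 70% of CpGs near 1 and
#'   30% near 0, matching the bimodality of somatic methylomes.
#' @param seed Integer seed; [simulate_cohort()] is deterministic given the
#'   design.
#' @return An object of class `cohort_design` (a validated list).
#' @seealso [simulate_cohort()], [twin_cohort_design()]
#' @export
cohort_design <- function(n_individuals = 5,
                          tissues = sprintf("T%02d", 1:10),
                          relationships = NULL,
                          n_cpgs = 600,
                          n_snps = 150,
                          fraction_cpg_disrupting = 0.2,
                          disruption_allele_probs = c(A = 1/3, G = 1/3, T = 1/3),
                          fraction_indirect_meqtl = 0.1,
                          meqtl_effect = 0.3,
                          maf_beta_params = c(1, 3),
                          coverage_mean_per_strand = 15,
                          non_conversion_rate = 0.005,
                          sequencing_error_rate = 0.001,
                          cph_methylation_rate = 0.01,
                          tissue_effect_sd = 0.10,
                          residual_sd = 0.02,
                          baseline_mixture = list(
                            weight_methylated = 0.7,
                            methylated = c(10, 0.5),
                            unmethylated = c(0.5, 10)
                          ),
                          seed = 1L) {
  design <- structure(
    list(
      n_individuals = n_individuals, tissues = tissues,
      relationships = relationships, n_cpgs = n_cpgs, n_snps = n_snps,
      fraction_cpg_disrupting = fraction_cpg_disrupting,
      disruption_allele_probs = disruption_allele_probs,
      fraction_indirect_meqtl = fraction_indirect_meqtl,
      meqtl_effect = meqtl_effect, maf_beta_params = maf_beta_params,
      coverage_mean_per_strand = coverage_mean_per_strand,
      non_conversion_rate = non_conversion_rate,
      sequencing_error_rate = sequencing_error_rate,
      cph_methylation_rate = cph_methylation_rate,
      tissue_effect_sd = tissue_effect_sd, residual_sd = residual_sd,
      baseline_mixture = baseline_mixture, seed = as.integer(seed)
    ),
    class = "cohort_design"
  )
  validate_cohort_design(design)
}

#' Twin-structured cohort design
#'
#' Convenience wrapper around [cohort_design()] building a single-tissue
#' cohort of MZ, DZ and unrelated pairs, for array-style pairwise-correlation
#' analyses.
#'
#' @param n_mz,n_dz,n_unrelated_pairs Numbers of pairs of each type.
#' @param tissues Tissue labels (default a single adipose-like tissue).
#' @param ... Further arguments passed to [cohort_design()].
#' @return A `cohort_design`.
#' @export
twin_cohort_design <- function(n_mz = 10, n_dz = 10, n_unrelated_pairs = 20,
                               tissues = "adipose", ...) {
  n_pairs <- n_mz + n_dz + n_unrelated_pairs
  rel <- tibble(
    individual_a = 2 * seq_len(n_pairs) - 1,
    individual_b = 2 * seq_len(n_pairs),
    type = rep(c("MZ", "DZ", "unrelated"), c(n_mz, n_dz, n_unrelated_pairs))
  )
  cohort_design(
    n_individuals = 2 * n_pairs, tissues = tissues,
    relationships = rel, ...
  )
}

validate_cohort_design <- function(design) {
  req_prop <- function(x, field, lo = 0, hi = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
      abort(sprintf("invalid cohort design: `%s` must be a number in [%s, %s]",
                    field, lo, hi))
    }
  }
  req_count <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != round(x)) {
      abort(sprintf("invalid cohort design: `%s` must be a count >= 1", field))
    }
  }
  req_count(design$n_individuals, "n_individuals")
  req_count(design$n_cpgs, "n_cpgs")
  req_count(design$n_snps, "n_snps")
  if (length(design$tissues) < 1 || anyDuplicated(design$tissues)) {
    abort("invalid cohort design: `tissues` must be >= 1 distinct labels")
  }
  for (f in c("fraction_cpg_disrupting", "fraction_indirect_meqtl",
              "non_conversion_rate", "sequencing_error_rate",
              "cph_methylation_rate")) {
    req_prop(design[[f]], f)
  }
  req_prop(design$meqtl_effect, "meqtl_effect")
  req_prop(design$tissue_effect_sd, "tissue_effect_sd")
  req_prop(design$residual_sd, "residual_sd")
  if (design$coverage_mean_per_strand <= 0) {
    abort("invalid cohort design: `coverage_mean_per_strand` must be > 0")
  }
  p <- design$disruption_allele_probs
  if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    abort("invalid cohort design: `disruption_allele_probs` must be 3 probabilities (A, G, T) summing to 1")
  }
  if (length(design$maf_beta_params) != 2 || any(design$maf_beta_params <= 0)) {
    abort("invalid cohort design: `maf_beta_params` must be two positive shapes")
  }
  bm <- design$baseline_mixture
  if (!is.list(bm) || is.null(bm$weight_methylated) ||
      bm$weight_methylated < 0 || bm$weight_methylated > 1 ||
      length(bm$methylated) != 2 || length(bm$unmethylated) != 2) {
    abort("invalid cohort design: `baseline_mixture` must give weight_methylated and two Beta shape pairs")
  }
  n_disr <- round(design$n_snps * design$fraction_cpg_disrupting)
  n_meq <- round(design$n_cpgs * design$fraction_indirect_meqtl)
  if (n_disr + n_meq > design$n_snps) {
    abort("invalid cohort design: `n_snps` too small for `fraction_cpg_disrupting` plus `fraction_indirect_meqtl`")
  }
  if (n_disr + n_meq > design$n_cpgs) {
    abort("invalid cohort design: `n_cpgs` too small for the disrupted plus meQTL CpGs requested")
  }
  rel <- design$relationships
  if (!is.null(rel)) {
    if (!all(c("individual_a", "individual_b", "type") %in% names(rel))) {
      abort("invalid cohort design: `relationships` needs columns individual_a, individual_b, type")
    }
    if (!all(rel$type %in% c("MZ", "DZ", "unrelated"))) {
      abort("invalid cohort design: `relationships$type` must be MZ, DZ or unrelated")
    }
    ids <- c(rel$individual_a, rel$individual_b)
    if (any(ids < 1 | ids > design$n_individuals) || anyDuplicated(ids)) {
      abort("invalid cohort design: `relationships` must pair distinct individuals in range, each at most once")
    }
  }
  if (is.na(design$seed)) abort("invalid cohort design: `seed` must be an integer")
  design
}

fold_maf <- function(x) pmin(x, 1 - x)

## dosage matrix (n_snps x n_individuals) under HWE with twin structure
sample_genotype_matrix <- function(maf, n_individuals, relationships) {
  n_snps <- length(maf)
  dos <- matrix(NA_integer_, n_snps, n_individuals)
  paired <- integer(0)
  if (!is.null(relationships)) {
    for (i in seq_len(nrow(relationships))) {
      a <- relationships$individual_a[i]
      b <- relationships$individual_b[i]
      type <- relationships$type[i]
      if (type == "MZ") {
        g <- rbinom(n_snps, 2, maf)
        dos[, a] <- g
        dos[, b] <- g
      } else if (type == "DZ") {
        m1 <- rbinom(n_snps, 1, maf); m2 <- rbinom(n_snps, 1, maf)
        f1 <- rbinom(n_snps, 1, maf); f2 <- rbinom(n_snps, 1, maf)
        child <- function() {
          ifelse(runif(n_snps) < 0.5, m1, m2) +
            ifelse(runif(n_snps) < 0.5, f1, f2)
        }
        dos[, a] <- child()
        dos[, b] <- child()
      } else {
        dos[, a] <- rbinom(n_snps, 2, maf)
        dos[, b] <- rbinom(n_snps, 2, maf)
      }
      paired <- c(paired, a, b)
    }
  }
  for (j in setdiff(seq_len(n_individuals), paired)) {
    dos[, j] <- rbinom(n_snps, 2, maf)
  }
  dos
}

#' Simulate a ground-truthed strand-specific WGBS cohort
#'
#' Generates, deterministically for a fixed design (including its seed), a
#' cohort of per-sample, per-strand CpG methylation calls with known embedded
#' genetic variation: CpG-disrupting SNPs whose measured "methylation" is
#' genotype via the strand read-accounting of
#' [apply_disruption_accounting()], and indirect meQTLs that shift true
#' methylation additively with dosage.
#'
#' @param design A [cohort_design()].
#' @return An object of class `meth_cohort`: a list with tibbles
#'   * `samples` - sample sheet (`sample_id`, `individual_id`, `tissue`,
#'     `relationship_group`);
#'   * `snps` - SNP truth (`snp_id`, `chrom`, `pos`, `ref`, `alt`, `maf`,
#'     `role`, `cpg_id`);
#'   * `genotypes` - long dosage table (`snp_id`, `individual_id`, `dosage`);
#'   * `cpgs` - CpG truth (position, baseline, disrupting/linked SNP,
#'     signed meQTL effect);
#'   * `truth` - per (CpG, sample) true methylation and CpG genotype;
#'   * `evidence` - per (CpG, sample) strand evidence (counts per strand plus
#'     reverse-strand base counts);
#'   * `calls` - the same data as long stranded methylation calls
#'     (`sample_id`, `chrom`, `pos`, `strand`, `meth_count`, `unmeth_count`).
#'
#'   Positions are 0-based forward-strand C coordinates; the dyad is
#'   `[pos, pos + 2)`. Homozygous C>A/C>G sites emit a forward record with
#'   zero coverage, so "unmeasurable" stays distinguishable from
#'   "unsequenced".
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_design(n_cpgs = 50, n_snps = 20))
#' cohort$calls
simulate_cohort <- function(design) {
  design <- validate_cohort_design(design)
  withr::with_seed(design$seed, simulate_cohort_impl(design))
}

simulate_cohort_impl <- function(design) {
  n_ind <- design$n_individuals
  individuals <- sprintf("ind%02d", seq_len(n_ind))
  tissues <- design$tissues
  chrom <- "chr1"

  samples <- tidyr::expand_grid(
    individual_id = individuals,
    tissue = tissues
  ) |>
    mutate(sample_id = paste(.data$individual_id, .data$tissue, sep = "_"))
  rel_group <- rep(NA_character_, n_ind)
  if (!is.null(design$relationships)) {
    r <- design$relationships
    lab <- paste0(r$type, seq_len(nrow(r)))
    rel_group[r$individual_a] <- lab
    rel_group[r$individual_b] <- lab
  }
  samples$relationship_group <- rel_group[match(samples$individual_id, individuals)]
  samples <- select(samples, "sample_id", "individual_id", "tissue",
                    "relationship_group")

  ## CpG positions: jittered grid, dyads never overlapping
  n_cpgs <- design$n_cpgs
  spacing <- 150L
  cpg_pos <- 10000L + spacing * (seq_len(n_cpgs) - 1L) +
    sample.int(spacing - 10L, n_cpgs, replace = TRUE)
  chrom_len <- max(cpg_pos) + 20000L
  dyad_positions <- c(cpg_pos, cpg_pos + 1L)

  ## SNP placement
  n_snps <- design$n_snps
  n_disr <- round(n_snps * design$fraction_cpg_disrupting)
  n_meq <- round(n_cpgs * design$fraction_indirect_meqtl)
  n_bg <- n_snps - n_disr - n_meq
  disr_cpg <- sort(sample.int(n_cpgs, n_disr))
  meq_cpg <- sort(sample(setdiff(seq_len(n_cpgs), disr_cpg), n_meq))

  alt_disr <- sample(c("A", "G", "T"), n_disr, replace = TRUE,
                     prob = design$disruption_allele_probs)

  draw_clear_pos <- function(n, near = NULL, window = 10000L) {
    out <- integer(n)
    for (i in seq_len(n)) {
      repeat {
        p <- if (is.null(near)) {
          sample.int(chrom_len, 1)
        } else {
          off <- sample(c(-window:-1, 1:window), 1)
          near[i] + off
        }
        if (p >= 1 && p <= chrom_len && !(p %in% dyad_positions) &&
            !(p %in% out[seq_len(i - 1)])) break
      }
      out[i] <- p
    }
    out
  }
  meq_pos <- draw_clear_pos(n_meq, near = cpg_pos[meq_cpg])
  bg_pos <- draw_clear_pos(n_bg)
  rand_alleles <- function(n) {
    ref <- sample(BASES, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
    list(ref = ref, alt = unname(alt))
  }
  meq_al <- rand_alleles(n_meq)
  bg_al <- rand_alleles(n_bg)

  snps <- tibble(
    snp_id = sprintf("snp%04d", seq_len(n_snps)),
    chrom = chrom,
    pos = c(cpg_pos[disr_cpg], meq_pos, bg_pos),
    ref = c(rep("C", n_disr), meq_al$ref, bg_al$ref),
    alt = c(alt_disr, meq_al$alt, bg_al$alt),
    maf = fold_maf(rbeta(n_snps, design$maf_beta_params[1],
                         design$maf_beta_params[2])),
    role = rep(c("disrupting", "meqtl", "background"),
               c(n_disr, n_meq, n_bg)),
    cpg_id = c(sprintf("cpg%05d", disr_cpg), sprintf("cpg%05d", meq_cpg),
               rep(NA_character_, n_bg))
  )

  dos <- sample_genotype_matrix(snps$maf, n_ind, design$relationships)
  genotypes <- tibble(
    snp_id = rep(snps$snp_id, n_ind),
    individual_id = rep(individuals, each = n_snps),
    dosage = as.integer(dos)
  )

  ## CpG truth
  bm <- design$baseline_mixture
  methylated_mode <- runif(n_cpgs) < bm$weight_methylated
  baseline <- ifelse(methylated_mode,
    rbeta(n_cpgs, bm$methylated[1], bm$methylated[2]),
    rbeta(n_cpgs, bm$unmethylated[1], bm$unmethylated[2])
  )
  meq_sign <- sample(c(-1, 1), n_meq, replace = TRUE)
  cpgs <- tibble(
    cpg_id = sprintf("cpg%05d", seq_len(n_cpgs)),
    chrom = chrom,
    pos = cpg_pos,
    baseline = baseline,
    disrupting_snp = NA_character_,
    alt_allele = NA_character_,
    linked_snp = NA_character_,
    meqtl_effect = 0
  )
  cpgs$disrupting_snp[disr_cpg] <- snps$snp_id[seq_len(n_disr)]
  cpgs$alt_allele[disr_cpg] <- alt_disr
  cpgs$linked_snp[meq_cpg] <- snps$snp_id[n_disr + seq_len(n_meq)]
  cpgs$meqtl_effect[meq_cpg] <- meq_sign * design$meqtl_effect

  tissue_eff <- matrix(rnorm(n_cpgs * length(tissues), 0, design$tissue_effect_sd),
                       n_cpgs, length(tissues))

  ## dosage lookups per CpG x individual
  dos_disr <- matrix(0L, n_cpgs, n_ind)
  dos_disr[disr_cpg, ] <- dos[seq_len(n_disr), , drop = FALSE]
  dos_link <- matrix(0L, n_cpgs, n_ind)
  dos_link[meq_cpg, ] <- dos[n_disr + seq_len(n_meq), , drop = FALSE]
  alt_at_cpg <- rep("A", n_cpgs)  # placeholder for non-disrupted rows
  alt_at_cpg[disr_cpg] <- alt_disr

  ## long (CpG x sample) table
  n_samples <- nrow(samples)
  ci <- rep(seq_len(n_cpgs), times = n_samples)
  si <- rep(seq_len(n_samples), each = n_cpgs)
  ii <- match(samples$individual_id[si], individuals)
  ti <- match(samples$tissue[si], tissues)

  true_meth <- pmin(1, pmax(0,
    baseline[ci] + tissue_eff[cbind(ci, ti)] +
      cpgs$meqtl_effect[ci] * dos_link[cbind(ci, ii)] +
      rnorm(length(ci), 0, design$residual_sd)
  ))
  gt <- genotype_from_dosage(dos_disr[cbind(ci, ii)], alt_at_cpg[ci])

  acc <- apply_disruption_accounting(
    gt, true_meth,
    non_conversion_rate = design$non_conversion_rate,
    sequencing_error_rate = design$sequencing_error_rate,
    cph_methylation_rate = design$cph_methylation_rate
  )
  fwd_cov <- rpois(length(ci), design$coverage_mean_per_strand *
                     acc$fwd_coverage_factor)
  rev_cov <- rpois(length(ci), design$coverage_mean_per_strand)
  fwd_meth <- rbinom(length(ci), fwd_cov,
                     ifelse(is.na(acc$fwd_rate), 0, acc$fwd_rate))
  rev_meth <- rbinom(length(ci), rev_cov, acc$rev_rate)
  al <- gt_alleles(gt)
  bases <- sim_rev_bases(al[, 1], al[, 2], rev_cov,
                         design$sequencing_error_rate)

  evidence <- tibble(
    sample_id = samples$sample_id[si],
    cpg_id = cpgs$cpg_id[ci],
    chrom = chrom,
    pos = cpg_pos[ci],
    fwd_meth = fwd_meth,
    fwd_unmeth = fwd_cov - fwd_meth,
    rev_meth = rev_meth,
    rev_unmeth = rev_cov - rev_meth,
    rev_A = bases[, "A"], rev_C = bases[, "C"],
    rev_G = bases[, "G"], rev_T = bases[, "T"]
  )

  calls <- bind_rows(
    evidence |>
      transmute(.data$sample_id, .data$chrom, .data$pos, strand = "forward",
                meth_count = .data$fwd_meth, unmeth_count = .data$fwd_unmeth),
    evidence |>
      transmute(.data$sample_id, .data$chrom, .data$pos, strand = "reverse",
                meth_count = .data$rev_meth, unmeth_count = .data$rev_unmeth)
  ) |>
    arrange(.data$sample_id, .data$pos, .data$strand)

  truth <- tibble(
    cpg_id = cpgs$cpg_id[ci],
    sample_id = samples$sample_id[si],
    individual_id = samples$individual_id[si],
    true_meth = true_meth,
    cpg_genotype = gt
  )

  structure(
    list(
      design = design, samples = samples, snps = snps, genotypes = genotypes,
      cpgs = cpgs, truth = truth, evidence = evidence, calls = calls
    ),
    class = "meth_cohort"
  )
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf(
    "<meth_cohort> %d individuals x %d tissues (%d samples), %d CpGs, %d SNPs\n",
    x$design$n_individuals, length(x$design$tissues), nrow(x$samples),
    x$design$n_cpgs, x$design$n_snps
  ))
  cat(sprintf(
    "  %d CpG-disrupting SNPs, %d meQTL-linked CpGs, coverage %.1fx/strand, seed %d\n",
    sum(x$snps$role == "disrupting"), sum(x$snps$role == "meqtl"),
    x$design$coverage_mean_per_strand, x$design$seed
  ))
  invisible(x)
}

#' Pool strand-specific calls into per-dyad methylation rates
#'
#' @param calls Long stranded call tibble (`sample_id`, `chrom`, `pos`,
#'   `strand`, `meth_count`, `unmeth_count`).
#' @param min_coverage Minimum combined-strand read count for a rate to be
#'   reported (the reference screen uses at least 4 reads, both strands
#'   combined).
#' @return Tibble `chrom`, `pos`, `sample_id`, `coverage`, `rate`.
#' @export
pooled_rates <- function(calls, min_coverage = 1) {
  calls |>
    group_by(.data$chrom, .data$pos, .data$sample_id) |>
    summarise(
      coverage = sum(.data$meth_count + .data$unmeth_count),
      rate = ifelse(.data$coverage > 0,
                    sum(.data$meth_count) / .data$coverage, NA_real_),
      .groups = "drop"
    ) |>
    filter(.data$coverage >= min_coverage, !is.na(.data$rate))
}

#' Emit array-like (non-stranded) methylation betas
#'
#' Collapses the simulated truth into one pooled methylation proportion per
#' CpG per sample, emulating a methylation microarray readout: the expected
#' pooled-strand rate implied by the sample's CpG genotype and true
#' methylation, plus Gaussian noise, clipped to `[0, 1]`. At genotype-driven
#' CpGs the betas form three dosage-separated clusters, which is what makes
#' such probes fingerprint individuals.
#'
#' @param cohort A `meth_cohort`.
#' @param cpg_ids Optional subset of CpGs (default: all).
#' @param noise_sd SD of the array noise added to the expected beta.
#' @return Tibble `cpg_id`, `sample_id`, `beta`.
#' @export
emit_array_like_betas <- function(cohort, cpg_ids = NULL, noise_sd = 0.02) {
  stopifnot(inherits(cohort, "meth_cohort"))
  truth <- cohort$truth
  if (!is.null(cpg_ids)) truth <- filter(truth, .data$cpg_id %in% cpg_ids)
  expected <- pooled_expected_rate(
    truth$cpg_genotype, truth$true_meth,
    cph_methylation_rate = cohort$design$cph_methylation_rate
  )
  tibble(
    cpg_id = truth$cpg_id,
    sample_id = truth$sample_id,
    beta = pmin(1, pmax(0, expected + rnorm(nrow(truth), 0, noise_sd)))
  )
}
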