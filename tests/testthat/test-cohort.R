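test_that("the same design and seed reproduce the cohort exactly", {
  a <- small_cohort(seed = 5)
  b <- small_cohort(seed = 5)
  expect_identical(a$calls, b$calls)
  expect_identical(a$evidence, b$evidence)
  expect_identical(a$genotypes, b$genotypes)
  c2 <- small_cohort(seed = 6)
  expect_false(identical(a$calls, c2$calls))
})

test_that("read counts conserve coverage and zero-coverage forward records survive", {
  co <- small_cohort(seed = 9, fraction_cpg_disrupting = 0.5)
  expect_true(all(co$calls$meth_count >= 0 & co$calls$unmeth_count >= 0))
  ## every (sample, cpg) emits exactly one record per strand, even when the
  ## genotype makes the forward strand unmeasurable
  per_site <- dplyr::count(co$calls, sample_id, pos, strand)
  expect_true(all(per_site$n == 1))
  hom_alt <- dplyr::filter(co$truth, cpg_genotype %in% c("A/A", "G/G"))
  if (nrow(hom_alt) > 0) {
    fwd <- co$evidence |>
      dplyr::semi_join(hom_alt, by = c("sample_id", "cpg_id"))
    expect_true(all(fwd$fwd_meth + fwd$fwd_unmeth == 0))
  }
})

test_that("an effect-free design shows only chance genotype-methylation correlation", {
  ## 20 individuals, 1 tissue, no disruption and no meQTL: the fraction of
  ## CpGs with |r| > 0.5 against a random SNP must match the t-distribution
  ## null (P(|r| > 0.5 | n = 20) ~ 0.025)
  co <- simulate_cohort(cohort_design(
    n_individuals = 20, tissues = "blood", n_cpgs = 1000, n_snps = 1,
    fraction_cpg_disrupting = 0, fraction_indirect_meqtl = 0,
    residual_sd = 0.05, seed = 21
  ))
  rates <- pooled_rates(co$calls, min_coverage = 1)
  dos <- co$genotypes$dosage[match(
    sub("_blood", "", rates$sample_id), unique(co$genotypes$individual_id)
  )]
  rs <- rates |>
    dplyr::mutate(dosage = dos) |>
    dplyr::group_by(pos) |>
    dplyr::summarise(r = suppressWarnings(stats::cor(rate, dosage)),
                     .groups = "drop")
  frac <- mean(abs(rs$r) > 0.5, na.rm = TRUE)
  ## generous binomial envelope around the 2.5% null rate
  expect_lt(frac, 0.06)
})

test_that("MZ twins share genotypes and DZ twins share about half", {
  d <- twin_cohort_design(
    n_mz = 5, n_dz = 5, n_unrelated_pairs = 5,
    n_cpgs = 60, n_snps = 400, fraction_cpg_disrupting = 0.1,
    fraction_indirect_meqtl = 0, seed = 31
  )
  co <- simulate_cohort(d)
  wide <- tidyr::pivot_wider(co$genotypes, names_from = "individual_id",
                             values_from = "dosage")
  rel <- d$relationships
  inds <- sprintf("ind%02d", seq_len(d$n_individuals))
  share <- vapply(seq_len(nrow(rel)), function(i) {
    mean(wide[[inds[rel$individual_a[i]]]] == wide[[inds[rel$individual_b[i]]]])
  }, numeric(1))
  expect_true(all(share[rel$type == "MZ"] == 1))
  expect_true(mean(share[rel$type == "DZ"]) >
                mean(share[rel$type == "unrelated"]))
})

test_that("array-like betas are linear in dosage without noise and rank MZ > DZ > unrelated", {
  ## noiseless meQTL CpG: betas are exactly b0 + dosage * effect
  co <- simulate_cohort(cohort_design(
    n_individuals = 12, tissues = "blood", n_cpgs = 40, n_snps = 20,
    fraction_cpg_disrupting = 0, fraction_indirect_meqtl = 0.5,
    meqtl_effect = 0.2, residual_sd = 0, tissue_effect_sd = 0,
    baseline_mixture = list(weight_methylated = 0,
                            unmethylated = c(2, 8), methylated = c(8, 2)),
    seed = 41
  ))
  set.seed(1)
  betas <- emit_array_like_betas(co, noise_sd = 0)
  meq <- dplyr::filter(co$cpgs, !is.na(linked_snp))
  joined <- betas |>
    dplyr::inner_join(co$truth, by = c("cpg_id", "sample_id")) |>
    dplyr::semi_join(meq, by = "cpg_id")
  ## for intact CpGs the array beta is the true methylation itself,
  ## which the generator built as baseline + effect * dosage (clipped)
  expect_equal(joined$beta, joined$true_meth, tolerance = 1e-12)

  ## twin cohort at genotype-driven CpGs: MZ > DZ > unrelated correlation
  tw <- simulate_cohort(twin_cohort_design(
    n_mz = 10, n_dz = 10, n_unrelated_pairs = 20,
    n_cpgs = 150, n_snps = 80, fraction_cpg_disrupting = 0.6,
    fraction_indirect_meqtl = 0, seed = 43
  ))
  set.seed(2)
  driven <- dplyr::filter(tw$cpgs, !is.na(disrupting_snp))$cpg_id
  betas <- emit_array_like_betas(tw, cpg_ids = driven, noise_sd = 0.03)
  rel <- tw$samples |>
    dplyr::filter(!is.na(relationship_group)) |>
    dplyr::group_by(relationship_group) |>
    dplyr::summarise(sample_a = sample_id[1],
                     sample_b = sample_id[2], .groups = "drop") |>
    dplyr::mutate(relationship = sub("[0-9]+$", "", relationship_group))
  pc <- pairwise_sample_correlation(betas, rel)
  means <- setNames(pc$groups$mean_r, pc$groups$relationship)
  expect_gt(means[["MZ"]], means[["DZ"]])
  expect_gt(means[["DZ"]], means[["unrelated"]])
})

test_that("invalid designs are rejected with the offending field named", {
  expect_error(cohort_design(n_individuals = 0), "n_individuals")
  expect_error(cohort_design(fraction_cpg_disrupting = 1.4),
               "fraction_cpg_disrupting")
  expect_error(cohort_design(disruption_allele_probs = c(0.5, 0.5, 0.5)),
               "disruption_allele_probs")
  expect_error(
    cohort_design(n_snps = 5, n_cpgs = 100, fraction_indirect_meqtl = 0.5),
    "n_snps"
  )
  expect_error(
    cohort_design(relationships = tibble::tibble(
      individual_a = 1, individual_b = 1, type = "MZ"
    )),
    "relationships"
  )
})
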