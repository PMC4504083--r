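## build a long rate table from a per-individual rate spec:
## list(ind1 = c(s1 = rate, ...), ...) at one site
site_rates <- function(per_ind, pos = 100) {
  rows <- lapply(names(per_ind), function(ind) {
    r <- per_ind[[ind]]
    tibble::tibble(
      chrom = "chr1", pos = pos,
      sample_id = paste0(ind, "_s", seq_along(r)),
      rate = r
    )
  })
  dplyr::bind_rows(rows)
}

sample_map_of <- function(rates) {
  tibble::tibble(
    sample_id = unique(rates$sample_id),
    individual_id = sub("_s[0-9]+$", "", unique(rates$sample_id))
  )
}

test_that("static-within, variable-between sites are candidates (brute-force check)", {
  rates <- site_rates(list(
    i1 = c(0, 0, 0), i2 = c(0, 0, 0), i3 = c(1, 1, 1),
    i4 = c(1, 1, 1), i5 = c(0.5, 0.5, 0.5)
  ))
  res <- screen_static_cpgs(rates, sample_map_of(rates))
  expect_equal(res$status, "candidate")
  expect_equal(res$n_assessable, 5L)
  expect_equal(res$n_static, 5L)
  expect_equal(res$range, 1)

  ## brute-force recomputation of the rule on the same data
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  per_ind <- tapply(rates$rate, sub("_s[0-9]+$", "", rates$sample_id), sd_pop)
  expect_true(sum(per_ind < 0.07) > length(per_ind) / 2)
  expect_true(diff(range(rates$rate)) >= 0.15)
})

test_that("flat sites and under-sampled individuals are handled per the rules", {
  ## constant matrix: range 0 < 0.15, not a candidate
  flat <- site_rates(list(i1 = rep(0.8, 3), i2 = rep(0.8, 3),
                          i3 = rep(0.8, 3)))
  expect_equal(screen_static_cpgs(flat, sample_map_of(flat))$status,
               "not_candidate")

  ## two samples per individual everywhere: no assessable individual
  two <- site_rates(list(i1 = c(0, 0), i2 = c(1, 1), i3 = c(0.5, 0.5)))
  res <- screen_static_cpgs(two, sample_map_of(two))
  expect_equal(res$status, "unassessable")
  expect_false(res$candidate)

  ## low-coverage samples are treated as missing
  cov <- site_rates(list(i1 = c(0, 0, 0), i2 = c(1, 1, 1)))
  cov$coverage <- c(10, 10, 10, 10, 10, 3)
  res <- screen_static_cpgs(cov, sample_map_of(cov), min_coverage = 4)
  expect_equal(res$n_measured, 5L)
})

test_that("tightening thresholds never grows the candidate set and ordering is irrelevant", {
  co <- small_cohort(seed = 17, fraction_cpg_disrupting = 0.4,
                     coverage_mean_per_strand = 20)
  rates <- pooled_rates(co$calls, min_coverage = 4)
  smap <- co$samples[, c("sample_id", "individual_id")]
  base <- screen_static_cpgs(rates, smap)
  tighter_sd <- screen_static_cpgs(rates, smap, sd_threshold = 0.03)
  tighter_rng <- screen_static_cpgs(rates, smap, min_range = 0.4)
  cand <- function(x) x$pos[x$candidate]
  expect_true(all(cand(tighter_sd) %in% cand(base)))
  expect_true(all(cand(tighter_rng) %in% cand(base)))

  ## invariance to row order and tissue relabeling
  shuffled <- rates[sample.int(nrow(rates)), ]
  expect_equal(cand(screen_static_cpgs(shuffled, smap)), cand(base))
})

test_that("permuted individual labels estimate the screen's null yield", {
  ## seeded reproducibility
  co <- small_cohort(seed = 19, fraction_cpg_disrupting = 0.3)
  rates <- pooled_rates(co$calls, min_coverage = 4)
  smap <- co$samples[, c("sample_id", "individual_id")]
  a <- permutation_null_yield(rates, smap, n_perm = 3, seed = 7)
  b <- permutation_null_yield(rates, smap, n_perm = 3, seed = 7)
  expect_identical(a$yields, b$yields)

  ## a fully genotype-driven matrix yields far more candidates than its
  ## label permutations: within-individual constancy is destroyed by mixing
  set.seed(33)
  dos <- matrix(sample(0:2, 50 * 5, replace = TRUE), nrow = 50)
  driven <- dplyr::bind_rows(lapply(1:5, function(i) {
    tibble::tibble(
      chrom = "chr1", pos = rep(1:50 * 10L, 3),
      sample_id = rep(sprintf("i%d_s%d", i, 1:3), each = 50),
      rate = rep(dos[, i] / 2, 3)
    )
  }))
  dmap <- sample_map_of(driven)
  driven_obs <- sum(screen_static_cpgs(driven, dmap)$candidate)
  driven_perm <- permutation_null_yield(driven, dmap, n_perm = 8, seed = 1)
  expect_gt(driven_obs, 3 * driven_perm$mean)

  ## a null cohort's observed yield is consistent with its permutation yield
  null_co <- small_cohort(seed = 23, fraction_cpg_disrupting = 0,
                          fraction_indirect_meqtl = 0)
  null_rates <- pooled_rates(null_co$calls, min_coverage = 4)
  null_obs <- sum(screen_static_cpgs(null_rates, smap)$candidate)
  null_perm <- permutation_null_yield(null_rates, smap, n_perm = 8, seed = 1)
  expect_lte(null_obs, max(null_perm$yields$n_candidates) + 3)
})

test_that("percentile calibration recovers thresholds from the data", {
  co <- small_cohort(seed = 29)
  rates <- pooled_rates(co$calls, min_coverage = 4)
  smap <- co$samples[, c("sample_id", "individual_id")]
  thr <- derive_screen_thresholds(rates, smap)
  expect_true(thr$sd_threshold > 0 && thr$sd_threshold < 1)
  expect_true(thr$min_range > 0 && thr$min_range < 1)
  ## by construction ~35% of sites pass the derived range cut
  res <- screen_static_cpgs(rates, smap, sd_threshold = thr$sd_threshold,
                            min_range = thr$min_range)
  expect_equal(mean(res$range >= thr$min_range), 0.35, tolerance = 0.05)
})
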