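#' Default pipeline configuration
#'
#' Returns the nested configuration list consumed by [run_pipeline()], with
#' one block per stage mirroring that stage's parameters. Any block can be
#' overridden by the corresponding argument of [run_pipeline()] or by a YAML
#' file with the same structure.
#'
#' @return Named list with blocks `design`, `screen`, `correlate`,
#'   `callgeno`, `diffaudit`, `sanitize`, plus `seed` and
#'   `max_pairs_per_type`.
#' @export
pipeline_config <- function() {
  list(
    seed = 1L,
    design = list(),
    screen = list(min_samples_per_individual = 3, sd_threshold = 0.07,
                  min_range = 0.15, min_coverage = 4),
    correlate = list(window_bp = 10000, r_min = 0.5, p_max = 0.05,
                     accuracy_min = 0.98),
    callgeno = list(prior_mode = "rare", theta = 0.001, error_rate = 0.001,
                    min_depth = 10, posterior_min = 0.9),
    diffaudit = list(min_cov = 15, min_diff = 0.30),
    sanitize = list(policy = "detected"),
    max_pairs_per_type = 8,
    catalog = NULL
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full leakage-audit pipeline on a simulated cohort
#'
#' Orchestrates simulate -> screen -> correlate -> call genotypes -> audit
#' differential methylation -> sanitize, in dependency order, each stage
#' feeding the next, and aggregates a machine-readable summary. Rerunning
#' with an identical configuration (including `seed`) reproduces all outputs.
#'
#' @param config Either a nested list overriding [pipeline_config()] blocks,
#'   or the path of a YAML file with the same structure.
#' @param summary_path Optional path; when given, the summary is written
#'   there as JSON.
#' @return List of class `methleak_pipeline`: `cohort`, `screen`,
#'   `correlation`, `classification`, `variant_calls`, `evaluation`,
#'   `audits`, `sanitization` (per-sample report tibble), and `summary`
#'   (nested list of per-stage counts and metrics). On a stage failure an
#'   error condition of class `methleakr_pipeline_error` is signalled whose
#'   `stage` and `partial` fields name the failed stage and carry the stages
#'   already completed.
#' @export
run_pipeline <- function(config = list(), summary_path = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("pipeline config file not found: ", config))
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(pipeline_config(), config)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(
        paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
        class = "methleakr_pipeline_error",
        stage = name, partial = results
      )
    })
  }

  ## catalog: external file or derived from the simulated SNP truth
  external_catalog <- NULL
  if (!is.null(cfg$catalog)) {
    if (!file.exists(cfg$catalog)) {
      abort(paste0("catalog path does not exist: ", cfg$catalog))
    }
    external_catalog <- read_snp_catalog(cfg$catalog)
  }

  cohort <- stage("simulate", {
    design_args <- cfg$design
    design_args$seed <- design_args$seed %||% cfg$seed
    cohort <- simulate_cohort(do.call(cohort_design, design_args))
    cohort
  })
  results$cohort <- cohort
  catalog <- external_catalog %||% catalog_from_truth(cohort)

  screen_res <- stage("screen", {
    rates <- pooled_rates(cohort$calls,
                          min_coverage = cfg$screen$min_coverage)
    do.call(screen_static_cpgs, c(
      list(rates = rates, sample_map = cohort$samples[, c("sample_id", "individual_id")]),
      cfg$screen
    ))
  })
  results$screen <- screen_res

  correlation <- stage("correlate", {
    rates <- pooled_rates(cohort$calls,
                          min_coverage = cfg$screen$min_coverage)
    cand <- screen_res |>
      filter(.data$candidate) |>
      left_join(select(cohort$cpgs, "cpg_id", "chrom", "pos"),
                by = c("chrom", "pos"))
    scan_cpgs(rates, cand, cohort$snps, cohort$genotypes,
              cohort$samples[, c("sample_id", "individual_id")],
              window_bp = cfg$correlate$window_bp)
  })
  results$correlation <- correlation

  classification <- stage("classify", {
    cls <- classify_candidates(correlation,
                               r_min = cfg$correlate$r_min,
                               p_max = cfg$correlate$p_max,
                               accuracy_min = cfg$correlate$accuracy_min)
    if (nrow(cls) > 0) {
      cls$direct_overlap <- direct_overlap(cls$chrom, cls$pos, catalog)
    }
    cls
  })
  results$classification <- classification

  variant_calls <- stage("callgeno", {
    do.call(call_genotypes, c(
      list(evidence = cohort$evidence),
      cfg$callgeno,
      if (identical(cfg$callgeno$prior_mode, "catalog")) list(catalog = catalog)
    ))
  })
  results$variant_calls <- variant_calls

  evaluation <- stage("evaluate", {
    truth <- cohort$truth |>
      left_join(select(cohort$cpgs, "cpg_id", "chrom", "pos"), by = "cpg_id") |>
      select("chrom", "pos", "sample_id", genotype = "cpg_genotype")
    evaluate_calls(variant_calls, truth)
  })
  results$evaluation <- evaluation

  audits <- stage("diffaudit", {
    pairs <- withr::with_seed(cfg$seed, {
      sample_pairs(cohort$samples, cfg$max_pairs_per_type)
    })
    audit_pairs(pairs, cohort$calls, variant_calls, cohort$samples,
                min_cov = cfg$diffaudit$min_cov,
                min_diff = cfg$diffaudit$min_diff)
  })
  results$audits <- audits

  sanitization <- stage("sanitize", {
    purrr::map(unique(cohort$samples$sample_id), function(s) {
      res <- sanitize_track(
        filter(cohort$evidence, .data$sample_id == s),
        variant_calls = filter(variant_calls, .data$sample_id == s),
        catalog = catalog,
        policy = cfg$sanitize$policy
      )
      tibble(
        sample_id = s,
        n_total_sites = res$report$n_total_sites,
        n_removed_called_variant = res$report$n_removed_called_variant,
        n_removed_catalog = res$report$n_removed_catalog,
        n_removed_unclear_context = res$report$n_removed_unclear_context,
        n_retained = res$report$n_retained,
        retention_fraction = res$report$retention_fraction
      )
    }) |>
      bind_rows()
  })
  results$sanitization <- sanitization

  summary <- list(
    design = list(
      n_individuals = cohort$design$n_individuals,
      n_samples = nrow(cohort$samples),
      n_cpgs = cohort$design$n_cpgs,
      n_snps = cohort$design$n_snps,
      seed = cfg$seed
    ),
    screen = list(
      n_sites = nrow(screen_res),
      n_candidates = sum(screen_res$candidate),
      n_unassessable = sum(screen_res$status == "unassessable")
    ),
    correlate = list(
      n_pairs_tested = nrow(correlation),
      n_correlated = sum(classification$correlated %||% logical(0)),
      n_highly_predictive = sum(classification$highly_predictive %||% logical(0)),
      n_direct_overlap = sum(classification$direct_overlap %||% logical(0))
    ),
    callgeno = list(
      n_calls = nrow(variant_calls),
      n_pass = sum(variant_calls$filter == "PASS"),
      n_low_cov = sum(variant_calls$filter == "LOW_COV"),
      het_sensitivity = evaluation$het_sensitivity,
      false_variant_rate = evaluation$false_variant_rate
    ),
    diffaudit = audits |>
      group_by(.data$pair_type) |>
      summarise(n_pairs = dplyr::n(),
                median_fraction_overlap = median(.data$fraction_overlap,
                                                 na.rm = TRUE),
                .groups = "drop") |>
      as.data.frame(),
    sanitize = list(
      policy = cfg$sanitize$policy,
      median_retention = median(sanitization$retention_fraction),
      n_sites_removed = sum(sanitization$n_total_sites -
                              sanitization$n_retained)
    )
  )
  results$summary <- summary

  if (!is.null(summary_path)) {
    jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                         digits = NA)
  }
  structure(results, class = "methleak_pipeline")
}

#' @export
print.methleak_pipeline <- function(x, ...) {
  cat("<methleak_pipeline>\n")
  utils::str(x$summary, max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Build a SNP catalog from simulated truth
#'
#' Converts a cohort's SNP table into the catalog shape used for masking and
#' catalog-prior genotype calling (0-based half-open single-base intervals
#' with allele frequencies).
#'
#' @param cohort A `meth_cohort`.
#' @return Catalog tibble `chrom`, `start`, `end`, `af`, `alt`.
#' @export
catalog_from_truth <- function(cohort) {
  out <- cohort$snps |>
    transmute(.data$chrom, start = .data$pos, end = .data$pos + 1L,
              af = .data$maf, alt = .data$alt)
  class(out) <- c("snp_catalog", class(out))
  out
}

## enumerate sample pairs by type and subsample each type
sample_pairs <- function(samples, max_per_type) {
  idx <- utils::combn(nrow(samples), 2)
  all_pairs <- tibble(
    sample_a = samples$sample_id[idx[1, ]],
    sample_b = samples$sample_id[idx[2, ]],
    same_ind = samples$individual_id[idx[1, ]] ==
      samples$individual_id[idx[2, ]],
    same_tissue = samples$tissue[idx[1, ]] == samples$tissue[idx[2, ]]
  ) |>
    filter(!(.data$same_ind & .data$same_tissue)) |>
    mutate(pair_type = dplyr::case_when(
      .data$same_ind ~ "same_individual_diff_tissue",
      .data$same_tissue ~ "same_tissue_diff_individual",
      .default = "both_differ"
    ))
  all_pairs |>
    group_by(.data$pair_type) |>
    slice_sample(n = max_per_type) |>
    ungroup() |>
    select("sample_a", "sample_b")
}
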