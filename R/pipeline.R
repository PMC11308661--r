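# End-to-end pipeline: synthetic cohort -> mapping fits -> base-case CEA ->
# tornado -> PSA -> CEAC, with a machine-readable run manifest.

#' Base-case results table for all arms
#'
#' One row per strategy with cost, incremental cost, QALYs, incremental QALYs,
#' ICER (vs the reference arm) and responder counts per 1000 patients. The
#' placebo arm is reported but excluded from the headline pairwise increment.
#'
#' @param params [cea_parameters()].
#' @param reference name of the reference arm (default `"low_dose"`).
#' @param comparator name of the comparator arm (default `"high_dose"`).
#' @return data frame mirroring the published results layout.
#' @export
cea_results_table <- function(params, reference = "low_dose",
                              comparator = "high_dose") {
  results <- lapply(params$arms, function(a)
    evaluate_arm(a, params$econ, params$util))
  inc <- icer(results[[reference]], results[[comparator]])
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    is_cmp <- nm == comparator
    data.frame(
      strategy = nm,
      cost = r$expected_cost,
      incremental_cost = if (is_cmp) inc$delta_cost else NA_real_,
      qaly = r$expected_qaly,
      incremental_qaly = if (is_cmp) inc$delta_qaly else NA_real_,
      icer = if (is_cmp) inc$icer else NA_real_,
      dominance = if (is_cmp) inc$dominance else "",
      partial_per_1000 = r$partial_per_1000,
      posthoc_per_1000 = r$posthoc_per_1000,
      responders_per_1000 = r$responders_per_1000,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' simulate cohort -> fit all eight mapping models -> base-case CEA ->
#' one-way sensitivity -> PSA -> CEAC, writing every stage's CSV plus a JSON
#' run manifest to `out_dir`. Deterministic (byte-identical stochastic
#' outputs) for a fixed config.
#'
#' @param out_dir output directory (created if needed).
#' @param params [cea_parameters()].
#' @param cohort_cfg [cohort_config()].
#' @param n_iterations PSA iterations (>= 1).
#' @param seed master seed for the PSA stage (the cohort stage uses the seed
#'   inside `cohort_cfg`).
#' @param wtp_grid WTP grid for the CEAC.
#' @return named list of output file paths, invisibly.
#' @export
full_run <- function(out_dir,
                     params = cea_parameters(),
                     cohort_cfg = cohort_config(),
                     n_iterations = 1000,
                     seed = 20240807,
                     wtp_grid = seq(0, 200000, by = 1000)) {
  if (n_iterations < 1) abort_config("PSA stage: n_iterations must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  message("stage cohort: n = ", cohort_cfg$n, ", seed = ", cohort_cfg$seed)
  cohort <- stage("simulate-cohort", {
    x <- generate_cohort(cohort_cfg)
    write_cohort(x, path("cohort.csv"))
    x
  })

  message("stage mapping: 2 families x 4 models")
  comparison <- stage("fit-mapping", {
    fits <- list()
    for (fam in c("gaussian_identity", "beta_logit")) {
      for (m in 1:4) {
        fits[[paste(fam, m, sep = "_")]] <-
          fit_mapping(cohort, mapping_spec(fam, m))
      }
    }
    cmp <- compare_models(fits, cohort)
    utils::write.csv(cmp$table, path("mapping_comparison.csv"), row.names = FALSE)
    utils::write.csv(cmp$screening, path("mapping_screening.csv"), row.names = FALSE)
    cmp
  })

  message("stage cea: convention = ", params$util$ae_utility_convention)
  stage("run-cea", {
    utils::write.csv(cea_results_table(params), path("cea_results.csv"),
                     row.names = FALSE)
  })

  ranges <- default_ranges(params)
  message("stage owsa: ", nrow(ranges), " parameters")
  stage("owsa", {
    utils::write.csv(owsa(params, ranges), path("tornado.csv"), row.names = FALSE)
  })

  message("stage psa: ", n_iterations, " iterations, seed = ", seed)
  psa <- stage("psa", {
    x <- run_psa(params, ranges, n_iterations = n_iterations, seed = seed)
    utils::write.csv(x$iterations, path("psa.csv"), row.names = FALSE)
    export_scatter(x, params$wtp, path("psa_scatter.csv"))
    x
  })

  message("stage ceac: ", length(wtp_grid), " WTP points")
  stage("ceac", {
    utils::write.csv(ceac(psa, wtp_grid), path("ceac.csv"), row.names = FALSE)
  })

  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("ticonomics")),
    config_hash = config_hash(jsonlite::toJSON(
      list(params = params_to_list(params), cohort = unclass(cohort_cfg),
           n_iterations = n_iterations, seed = seed),
      auto_unbox = TRUE, digits = NA)),
    seeds = list(cohort = cohort_cfg$seed, psa = seed),
    ae_utility_convention = params$util$ae_utility_convention,
    wtp = params$wtp,
    n_iterations = n_iterations,
    outputs = c("cohort.csv", "mapping_comparison.csv", "mapping_screening.csv",
                "cea_results.csv", "tornado.csv", "psa.csv", "psa_scatter.csv",
                "ceac.csv")
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(stats::setNames(
    as.list(path(c(manifest$outputs, "manifest.json"))),
    c(manifest$outputs, "manifest.json")))
}
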