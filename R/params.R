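# The full parameter bundle of the cost-utility model (all published baseline
# inputs), JSON/YAML (de)serialisation, and named-parameter plumbing used by
# the sensitivity analyses.

#' Full parameter set of the cost-utility model
#'
#' Bundles the three strategy arms (low-dose 5 mg/day, high-dose 10 mg/day,
#' placebo), the economic conventions, the health-state utilities and the
#' willingness-to-pay threshold (three times China's 2022 per-capita GDP,
#' $36,832.95/QALY). All defaults are the published baseline inputs.
#'
#' @param arms named list of [arm_parameters()] (`low_dose`, `high_dose`,
#'   `placebo`).
#' @param econ [economic_parameters()].
#' @param util [utility_parameters()].
#' @param wtp willingness-to-pay threshold in USD per QALY.
#' @return object of class `cea_parameters`.
#' @export
#' @examples
#' p <- cea_parameters()
#' evaluate_arm(p$arms$low_dose, p$econ, p$util)
cea_parameters <- function(arms = list(
                             low_dose = arm_parameters(
                               "low_dose", p_discontinue_ae = 0.023,
                               p_posthoc = 0.405, p_partial = 0.333,
                               daily_dose_mg = 5),
                             high_dose = arm_parameters(
                               "high_dose", p_discontinue_ae = 0.156,
                               p_posthoc = 0.571, p_partial = 0.314,
                               daily_dose_mg = 10),
                             placebo = arm_parameters(
                               "placebo", p_discontinue_ae = 0.023,
                               p_posthoc = 0.167, p_partial = 0.548,
                               daily_dose_mg = 0)),
                           econ = economic_parameters(),
                           util = utility_parameters(),
                           wtp = 36832.95) {
  stopifnot(inherits(econ, "economic_parameters"),
            inherits(util, "utility_parameters"))
  if (!all(c("low_dose", "high_dose") %in% names(arms))) {
    abort_config("arms must include at least 'low_dose' and 'high_dose'")
  }
  structure(list(arms = arms, econ = econ, util = util, wtp = wtp),
            class = "cea_parameters")
}

# ---- named scalar access for OWSA/PSA --------------------------------------
# Parameter names: econ/util fields by their own name; arm probabilities as
# "<field>.<arm>", e.g. "p_posthoc.high_dose".

#' Set one named model parameter
#'
#' @param params [cea_parameters()].
#' @param name e.g. `"drug_price_per_5mg"`, `"baseline_ygtss_total"`,
#'   `"p_posthoc.high_dose"`.
#' @param value new scalar value; arm and bundle invariants are re-validated.
#' @return modified `cea_parameters`.
#' @export
set_param <- function(params, name, value) {
  if (grepl(".", name, fixed = TRUE)) {
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    field <- parts[1]; arm_name <- parts[2]
    if (!arm_name %in% names(params$arms)) {
      stop("unknown arm '", arm_name, "' in parameter '", name, "'")
    }
    a <- params$arms[[arm_name]]
    if (!field %in% c("p_discontinue_ae", "p_posthoc", "p_partial",
                      "daily_dose_mg")) {
      stop("unknown arm field '", field, "' in parameter '", name, "'")
    }
    a[[field]] <- value
    params$arms[[arm_name]] <- arm_parameters(
      a$name, a$p_discontinue_ae, a$p_posthoc, a$p_partial, a$daily_dose_mg)
  } else if (name %in% names(params$econ)) {
    e <- unclass(params$econ); e[[name]] <- value
    # changing the horizon re-derives the drug-year unless set explicitly
    if (name == "horizon_weeks") e$days_per_horizon <- NULL
    params$econ <- do.call(economic_parameters, e[!vapply(e, is.null, TRUE)])
  } else if (name %in% names(params$util)) {
    u <- unclass(params$util); u[[name]] <- value
    params$util <- do.call(utility_parameters, u)
  } else if (name == "wtp") {
    params$wtp <- value
  } else {
    stop("unknown parameter '", name, "'")
  }
  params
}

#' Get one named model parameter
#' @inheritParams set_param
#' @return scalar value.
#' @export
get_param <- function(params, name) {
  if (grepl(".", name, fixed = TRUE)) {
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    params$arms[[parts[2]]][[parts[1]]]
  } else if (name %in% names(params$econ)) {
    params$econ[[name]]
  } else if (name %in% names(params$util)) {
    params$util[[name]]
  } else if (name == "wtp") {
    params$wtp
  } else {
    stop("unknown parameter '", name, "'")
  }
}

# ---- (de)serialisation -----------------------------------------------------

params_to_list <- function(params) {
  list(
    arms = lapply(params$arms, function(a)
      list(p_discontinue_ae = a$p_discontinue_ae, p_posthoc = a$p_posthoc,
           p_partial = a$p_partial, daily_dose_mg = a$daily_dose_mg)),
    econ = unclass(params$econ),
    util = unclass(params$util),
    wtp = params$wtp
  )
}

#' Write model parameters to JSON (or YAML)
#'
#' @param params [cea_parameters()].
#' @param path output path; format chosen by extension (`.json` canonical,
#'   `.yaml`/`.yml` if the yaml package is installed).
#' @export
write_params <- function(params, path) {
  x <- params_to_list(params)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML output; use .json")
    }
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Load model parameters from JSON/YAML, filling published defaults
#'
#' Any field absent from the file is filled from the published baseline value
#' (a notice is logged); present fields are validated against the type
#' invariants (probabilities in \[0, 1\], non-negative costs, ordered
#' utilities, known AE convention).
#'
#' @param path config file; an empty/absent body yields the full default set.
#' @param quiet suppress default-fill notices.
#' @return list with `params` ([cea_parameters()]) and `ranges`
#'   ([default_ranges()], overridable through a `ranges` array in the file).
#' @export
load_params <- function(path, quiet = FALSE) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML; use JSON")
    }
    yaml::read_yaml(path)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list() else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  }
  raw <- raw %||% list()
  defaults <- params_to_list(cea_parameters())
  note <- function(what) if (!quiet) message("load_params: using default for ", what)

  merge_block <- function(user, def, label) {
    out <- def
    for (k in names(def)) {
      if (!is.null(user[[k]])) out[[k]] <- user[[k]] else note(paste0(label, "$", k))
    }
    extra <- setdiff(names(user), names(def))
    if (length(extra)) {
      stop("unknown keys in ", label, ": ", paste(extra, collapse = ", "))
    }
    out
  }

  arms <- lapply(stats::setNames(names(defaults$arms), names(defaults$arms)),
                 function(an) {
    merged <- merge_block(raw$arms[[an]] %||% list(), defaults$arms[[an]],
                          paste0("arms$", an))
    do.call(arm_parameters, c(list(name = an), merged))
  })
  econ_l <- merge_block(raw$econ %||% list(), defaults$econ, "econ")
  util_l <- merge_block(raw$util %||% list(), defaults$util, "util")
  params <- cea_parameters(
    arms = arms,
    econ = do.call(economic_parameters, econ_l),
    util = do.call(utility_parameters, util_l),
    wtp = raw$wtp %||% {
      note("wtp")
      36832.95
    }
  )
  ranges <- if (!is.null(raw$ranges)) {
    as_parameter_ranges(as.data.frame(raw$ranges))
  } else {
    default_ranges(params)
  }
  list(params = params, ranges = ranges)
}
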