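# One-way (tornado) and probabilistic sensitivity analysis, CEAC and
# incremental cost-effectiveness scatter export for the high-dose vs low-dose
# comparison.

#' Parameter ranges for sensitivity analysis
#'
#' @param name parameter name understood by [set_param()].
#' @param base,low,high base-case value and range bounds (`low <= base <= high`).
#' @param distribution `"gamma"` (non-negative quantities), `"beta"`
#'   (quantities mappable to (0, 1); a negative disutility is sampled on its
#'   magnitude scale then negated) or `"fixed"`.
#' @return one-row `parameter_ranges` data frame; rbind rows to build a set.
#' @export
parameter_range <- function(name, base, low, high,
                            distribution = c("gamma", "beta", "fixed")) {
  distribution <- match.arg(distribution)
  if (!(low <= base && base <= high)) {
    abort_config("range for '", name, "' must satisfy low <= base <= high")
  }
  if (distribution == "gamma" && low < 0) {
    abort_config("gamma range for '", name, "' must be non-negative")
  }
  as_parameter_ranges(data.frame(
    name = name, base = base, low = low, high = high,
    distribution = distribution, stringsAsFactors = FALSE
  ))
}

as_parameter_ranges <- function(df) {
  need <- c("name", "base", "low", "high", "distribution")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("ranges need columns: ", paste(missing_cols, collapse = ", "))
  }
  structure(df[need], class = c("parameter_ranges", "data.frame"))
}

# Published ranges: costs and the baseline YGTSS score at +/-20%, response and
# discontinuation probabilities at +/-10% (as printed, i.e. rounded to 3 dp),
# AE disutility at +/-50%, drug price over its printed market spread.
published_ranges <- list(
  weekly_direct_medical_cost = c(25.20, 37.80, "gamma"),
  drug_price_per_5mg = c(0.32, 1.52, "gamma"),
  p_discontinue_ae.low_dose = c(0.021, 0.025, "beta"),
  p_discontinue_ae.high_dose = c(0.140, 0.172, "beta"),
  p_discontinue_ae.placebo = c(0.021, 0.025, "beta"),
  p_posthoc.low_dose = c(0.365, 0.446, "beta"),
  p_posthoc.high_dose = c(0.514, 0.628, "beta"),
  p_posthoc.placebo = c(0.150, 0.184, "beta"),
  p_partial.low_dose = c(0.300, 0.366, "beta"),
  p_partial.high_dose = c(0.283, 0.345, "beta"),
  p_partial.placebo = c(0.493, 0.603, "beta"),
  baseline_ygtss_total = c(24.30, 36.44, "gamma"),
  disutility_ae = c(-0.135, -0.045, "beta")
)

#' Default sensitivity ranges (published table)
#'
#' Uses the printed range where one exists; for any other parameter the
#' fallback convention is probabilities at ±10%, disutilities at ±50% and
#' everything else at ±20% of base.
#'
#' @param params [cea_parameters()].
#' @param include_placebo also vary the placebo arm's parameters (default
#'   `FALSE`: placebo is outside the pairwise comparison).
#' @param extra character vector of additional [set_param()] names to include
#'   via the fallback convention.
#' @return `parameter_ranges` data frame.
#' @export
default_ranges <- function(params, include_placebo = FALSE, extra = character()) {
  names_use <- names(published_ranges)
  if (!include_placebo) names_use <- grep("\\.placebo$", names_use,
                                          value = TRUE, invert = TRUE)
  rows <- lapply(names_use, function(nm) {
    base <- get_param(params, nm)
    pr <- published_ranges[[nm]]
    parameter_range(nm, base, as.numeric(pr[1]), as.numeric(pr[2]), pr[3])
  })
  fallback <- lapply(extra, function(nm) {
    base <- get_param(params, nm)
    if (startsWith(nm, "p_")) {
      parameter_range(nm, base, 0.9 * base, 1.1 * base, "beta")
    } else if (base < 0) {
      parameter_range(nm, base, 1.5 * base, 0.5 * base, "beta")
    } else {
      parameter_range(nm, base, 0.8 * base, 1.2 * base, "gamma")
    }
  })
  out <- do.call(rbind, c(rows, fallback))
  as_parameter_ranges(out)
}

# Evaluate the high-vs-low incremental result for one parameter set.
incremental_high_vs_low <- function(params) {
  low <- evaluate_arm(params$arms$low_dose, params$econ, params$util)
  high <- evaluate_arm(params$arms$high_dose, params$econ, params$util)
  icer(low, high)
}

#' One-way sensitivity analysis (tornado)
#'
#' Sets each parameter to its low then high bound (all others at base) and
#' recomputes the high-dose vs low-dose incremental result. Dominated
#' scenarios are flagged, not coerced to a negative ICER; `swing` is the
#' |ICER difference| when both ends yield a defined ICER, otherwise NA, and
#' entries are ordered by `nmb_swing` (the |difference| of the comparator's
#' net monetary benefit at `wtp`), which is well-defined in every scenario.
#'
#' @param params [cea_parameters()].
#' @param ranges [parameter_ranges] (default [default_ranges()]).
#' @param wtp threshold for the NMB columns (default `params$wtp`).
#' @return data frame of tornado entries, sorted by descending `nmb_swing`.
#' @export
owsa <- function(params, ranges = default_ranges(params), wtp = params$wtp) {
  base_inc <- incremental_high_vs_low(params)
  one <- function(nm, value) {
    inc <- incremental_high_vs_low(set_param(params, nm, value))
    list(icer = inc$icer, dominance = inc$dominance,
         nmb = net_monetary_benefit(inc, wtp))
  }
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    r <- ranges[i, ]
    lo <- one(r$name, r$low)
    hi <- one(r$name, r$high)
    data.frame(
      parameter = r$name, low = r$low, high = r$high,
      icer_at_low = lo$icer, icer_at_high = hi$icer,
      dominance_at_low = lo$dominance, dominance_at_high = hi$dominance,
      nmb_at_low = lo$nmb, nmb_at_high = hi$nmb,
      swing = abs(hi$icer - lo$icer),
      nmb_swing = abs(hi$nmb - lo$nmb),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$nmb_swing), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_inc$icer
  attr(out, "base_dominance") <- base_inc$dominance
  attr(out, "wtp") <- wtp
  out
}

# ---- probabilistic sensitivity analysis ------------------------------------

gamma_mom <- function(mean, sd) {
  list(shape = (mean / sd)^2, rate = mean / sd^2)
}

beta_mom <- function(mean, sd, name) {
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("beta moment matching infeasible for '", name,
         "': SD too large for mean ", mean)
  }
  k <- mean * (1 - mean) / v - 1
  list(shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Draw one parameter set for the PSA
#'
#' Each range is read as a 95% interval: the sampled distribution has mean
#' `base` and SD `(high - low) / 3.92`. Gamma and beta parameters come from
#' the method of moments; negative (disutility) betas are sampled on the
#' magnitude scale and negated; `fixed` and degenerate ranges pass the base
#' through. Draws are mutually independent and consume the current RNG state.
#'
#' @param ranges [parameter_ranges].
#' @return named numeric vector of drawn values.
#' @export
draw_parameters <- function(ranges) {
  vapply(seq_len(nrow(ranges)), function(i) {
    r <- ranges[i, ]
    sd <- (r$high - r$low) / 3.92
    if (r$distribution == "fixed" || sd == 0) return(r$base)
    if (r$distribution == "gamma") {
      g <- gamma_mom(r$base, sd)
      stats::rgamma(1, shape = g$shape, rate = g$rate)
    } else if (r$distribution == "beta") {
      neg <- r$base < 0
      m <- abs(r$base)
      b <- beta_mom(m, sd, r$name)
      x <- stats::rbeta(1, b$shape1, b$shape2)
      if (neg) -x else x
    } else {
      stop("unknown distribution '", r$distribution, "'")
    }
  }, numeric(1)) |> stats::setNames(ranges$name)
}

#' Probabilistic sensitivity analysis
#'
#' `n_iterations` Monte Carlo draws of all ranged parameters; each iteration
#' re-evaluates both arms and stores the incremental cost and QALY pair.
#' Drawn sets whose response probabilities would exceed 1 within an arm are
#' rejected and redrawn (this keeps the tree well-formed; rejection is part of
#' the seeded stream, so runs are bit-reproducible).
#'
#' @param params [cea_parameters()].
#' @param ranges [parameter_ranges].
#' @param n_iterations number of Monte Carlo iterations (>= 1; 1000 in the
#'   reference analysis).
#' @param seed integer seed.
#' @return object of class `psa_result`: `iterations` data frame
#'   (`delta_cost`, `delta_qaly`, drawn parameter columns), `n_iterations`,
#'   `seed`, `wtp`, and summary quantiles.
#' @export
run_psa <- function(params, ranges = default_ranges(params),
                    n_iterations = 1000, seed = 20240807) {
  if (n_iterations < 1) abort_config("n_iterations must be >= 1")
  set.seed(seed)
  draws <- matrix(NA_real_, n_iterations, nrow(ranges),
                  dimnames = list(NULL, ranges$name))
  dc <- dq <- numeric(n_iterations)
  for (i in seq_len(n_iterations)) {
    repeat {
      d <- draw_parameters(ranges)
      p_i <- tryCatch({
        p <- params
        for (nm in names(d)) p <- set_param(p, nm, d[[nm]])
        p
      }, ticonomics_config_error = function(e) NULL)
      if (!is.null(p_i)) break
    }
    inc <- incremental_high_vs_low(p_i)
    draws[i, ] <- d
    dc[i] <- inc$delta_cost
    dq[i] <- inc$delta_qaly
  }
  iterations <- data.frame(iteration = seq_len(n_iterations),
                           delta_cost = dc, delta_qaly = dq)
  iterations <- cbind(iterations, as.data.frame(draws))
  structure(list(
    iterations = iterations,
    n_iterations = n_iterations,
    seed = seed,
    wtp = params$wtp,
    summary = list(
      delta_cost = stats::quantile(dc, c(0.025, 0.5, 0.975)),
      delta_qaly = stats::quantile(dq, c(0.025, 0.5, 0.975))
    )
  ), class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that high dose is
#' cost-effective is the fraction of PSA iterations with positive net monetary
#' benefit `wtp * dQALY - dCost`; low dose takes the complement. Exact ties
#' (NMB = 0) go to the cheaper strategy.
#'
#' @param psa a [run_psa()] result.
#' @param wtp_grid non-empty numeric vector of WTP values.
#' @return data frame `wtp`, `p_high_dose`, `p_low_dose` (rows sum to 1).
#' @export
ceac <- function(psa, wtp_grid) {
  if (length(wtp_grid) == 0) stop("wtp_grid must be non-empty")
  it <- psa$iterations
  p_high <- vapply(wtp_grid, function(w) {
    nmb <- w * it$delta_qaly - it$delta_cost
    mean(nmb > 0 | (nmb == 0 & it$delta_cost < 0))
  }, numeric(1))
  data.frame(wtp = wtp_grid, p_high_dose = p_high, p_low_dose = 1 - p_high)
}

#' Export the incremental cost-effectiveness scatter
#'
#' Plot-ready CSV of the PSA cloud: one row per iteration with the incremental
#' QALY/cost pair and its position relative to the WTP ray
#' (`above` when `dCost > wtp * dQALY`, i.e. high dose not cost-effective;
#' points exactly on the ray are flagged `on-threshold`).
#'
#' @param psa a [run_psa()] result.
#' @param wtp willingness-to-pay threshold.
#' @param path output CSV path.
#' @return the exported data frame, invisibly.
#' @export
export_scatter <- function(psa, wtp, path) {
  it <- psa$iterations
  margin <- it$delta_cost - wtp * it$delta_qaly
  pos <- ifelse(margin > 0, "above", ifelse(margin < 0, "below", "on-threshold"))
  out <- data.frame(iteration = it$iteration,
                    delta_qaly = it$delta_qaly,
                    delta_cost = it$delta_cost,
                    position = pos,
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0) {
    out <- out[0, ]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
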