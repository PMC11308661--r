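# 52-week decision tree for oral aripiprazole in paediatric tic disorders.
# Each strategy arm: a chance node splitting AE-driven discontinuation from
# continuation; continuers split into post hoc response (>50% YGTSS total
# reduction), partial response (25-50%) and non-response (<25%).

#' Strategy arm parameters
#'
#' @param name strategy label.
#' @param p_discontinue_ae probability of discontinuation due to adverse
#'   events over the horizon.
#' @param p_posthoc,p_partial response probabilities AMONG CONTINUERS (the
#'   response split is conditional on not discontinuing); non-response is the
#'   complement.
#' @param daily_dose_mg daily aripiprazole dose in mg (0 for placebo).
#' @return object of class `arm_parameters`.
#' @export
arm_parameters <- function(name, p_discontinue_ae, p_posthoc, p_partial,
                           daily_dose_mg) {
  probs <- c(p_discontinue_ae = p_discontinue_ae,
             p_posthoc = p_posthoc, p_partial = p_partial)
  if (any(probs < 0 | probs > 1)) {
    abort_config("arm '", name, "': probabilities must lie in [0, 1]")
  }
  if (p_posthoc + p_partial > 1 + 1e-12) {
    abort_config("arm '", name, "': p_posthoc + p_partial exceeds 1")
  }
  if (daily_dose_mg < 0) abort_config("arm '", name, "': negative dose")
  structure(list(name = name,
                 p_discontinue_ae = p_discontinue_ae,
                 p_posthoc = p_posthoc, p_partial = p_partial,
                 p_nonresponse = 1 - p_posthoc - p_partial,
                 daily_dose_mg = daily_dose_mg),
            class = "arm_parameters")
}

#' Economic conventions of the tree
#'
#' The cost conventions that reproduce the published per-patient totals to
#' the cent: every patient accrues the weekly direct medical cost for the full
#' horizon; drug cost is price-per-5mg scaled linearly by dose, accrued over a
#' 364-day drug-year (52 x 7) by continuers and over `ae_treatment_weeks`
#' (default 8, the source trial's treatment period) by AE-discontinuers.
#'
#' @param weekly_direct_medical_cost USD per week, all patients.
#' @param drug_price_per_5mg USD per 5 mg of aripiprazole.
#' @param horizon_weeks model horizon (default 52).
#' @param ae_treatment_weeks weeks on drug before AE discontinuation.
#' @param days_per_horizon drug-exposure days for continuers (default
#'   `horizon_weeks * 7`).
#' @param discount_rate annual discount rate; the default 0 reflects the
#'   1-year horizon (costs and QALYs inside year one are not discounted).
#' @return object of class `economic_parameters`.
#' @export
economic_parameters <- function(weekly_direct_medical_cost = 31.50,
                                drug_price_per_5mg = 0.72,
                                horizon_weeks = 52,
                                ae_treatment_weeks = 8,
                                days_per_horizon = horizon_weeks * 7,
                                discount_rate = 0) {
  if (weekly_direct_medical_cost < 0 || drug_price_per_5mg < 0) {
    abort_config("costs must be >= 0")
  }
  if (ae_treatment_weeks > horizon_weeks) {
    abort_config("ae_treatment_weeks must not exceed horizon_weeks")
  }
  structure(list(weekly_direct_medical_cost = weekly_direct_medical_cost,
                 drug_price_per_5mg = drug_price_per_5mg,
                 horizon_weeks = horizon_weeks,
                 ae_treatment_weeks = ae_treatment_weeks,
                 days_per_horizon = days_per_horizon,
                 discount_rate = discount_rate),
            class = "economic_parameters")
}

ae_conventions <- c("baseline_minus_disutility",
                    "nonresponse_minus_disutility",
                    "response_mix_minus_disutility")

#' Health-state utility parameters
#'
#' Response-state utilities come from the selected YGTSS-to-utility mapping
#' applied to the source trial's outcomes; the AE disutility is assumed to be
#' 10% of the pre-treatment utility (see [disutility_from_baseline()]), with
#' the published rounded value -0.090 as the default literal.
#'
#' Because the utility attached to the AE-discontinuation branch is not
#' uniquely determined by the published inputs, three explicit conventions are
#' implemented: `baseline_minus_disutility` (default; AE patients sit at the
#' mapped baseline utility plus the disutility), `nonresponse_minus_disutility`
#' (non-response utility plus disutility) and `response_mix_minus_disutility`
#' (the continuers' expected utility plus disutility).
#'
#' @param u_posthoc,u_partial,u_nonresponse response-state utilities.
#' @param disutility_ae utility decrement (<= 0) for AE discontinuation.
#' @param baseline_ygtss_total pre-treatment YGTSS total tic score.
#' @param mapping_intercept,mapping_slope coefficients of the utility mapping
#'   used to convert the baseline score to a baseline utility.
#' @param ae_utility_convention one of the three conventions above.
#' @return object of class `utility_parameters`.
#' @export
utility_parameters <- function(u_posthoc = 0.934,
                               u_partial = 0.919,
                               u_nonresponse = 0.902,
                               disutility_ae = -0.090,
                               baseline_ygtss_total = 30.37,
                               mapping_intercept = 0.9881,
                               mapping_slope = -0.0035,
                               ae_utility_convention = "baseline_minus_disutility") {
  if (!(u_posthoc >= u_partial && u_partial >= u_nonresponse)) {
    abort_config("need u_posthoc >= u_partial >= u_nonresponse")
  }
  if (disutility_ae > 0) abort_config("disutility_ae must be <= 0")
  if (!ae_utility_convention %in% ae_conventions) {
    abort_config("unknown ae_utility_convention '", ae_utility_convention,
                 "'; use one of: ", paste(ae_conventions, collapse = ", "))
  }
  structure(list(u_posthoc = u_posthoc, u_partial = u_partial,
                 u_nonresponse = u_nonresponse,
                 disutility_ae = disutility_ae,
                 baseline_ygtss_total = baseline_ygtss_total,
                 mapping_intercept = mapping_intercept,
                 mapping_slope = mapping_slope,
                 ae_utility_convention = ae_utility_convention),
            class = "utility_parameters")
}

#' AE disutility derived from the baseline utility
#'
#' The disutility of adverse reactions leading to discontinuation is assumed
#' to be 10% of the pre-treatment utility, itself obtained from the utility
#' mapping evaluated at the baseline YGTSS total score.
#'
#' @param baseline_ygtss_total baseline YGTSS total tic score.
#' @param mapping_intercept,mapping_slope mapping coefficients.
#' @return negative utility decrement.
#' @export
#' @examples
#' disutility_from_baseline(30.37) # -0.0881805; published rounded input -0.090
disutility_from_baseline <- function(baseline_ygtss_total,
                                     mapping_intercept = 0.9881,
                                     mapping_slope = -0.0035) {
  -0.10 * (mapping_intercept + mapping_slope * baseline_ygtss_total)
}

#' Expected 52-week cost per patient for one arm
#'
#' @param arm [arm_parameters()].
#' @param econ [economic_parameters()].
#' @return list with `direct_medical`, `drug`, `total` (USD per patient).
#' @export
expected_cost <- function(arm, econ) {
  direct <- econ$weekly_direct_medical_cost * econ$horizon_weeks
  daily_drug <- econ$drug_price_per_5mg * arm$daily_dose_mg / 5
  drug_cont <- daily_drug * econ$days_per_horizon
  drug_ae <- daily_drug * econ$ae_treatment_weeks * 7
  p_dc <- arm$p_discontinue_ae
  drug <- (1 - p_dc) * drug_cont + p_dc * drug_ae
  list(direct_medical = direct, drug = drug, total = direct + drug)
}

ae_branch_utility <- function(arm, util) {
  mix <- arm$p_posthoc * util$u_posthoc +
    arm$p_partial * util$u_partial +
    arm$p_nonresponse * util$u_nonresponse
  base_u <- util$mapping_intercept +
    util$mapping_slope * util$baseline_ygtss_total
  switch(util$ae_utility_convention,
    baseline_minus_disutility = base_u + util$disutility_ae,
    nonresponse_minus_disutility = util$u_nonresponse + util$disutility_ae,
    response_mix_minus_disutility = mix + util$disutility_ae,
    abort_config("unknown ae_utility_convention")
  )
}

#' Expected QALYs per patient for one arm
#'
#' Continuers accrue the expectation of their response-state utility for the
#' full horizon; AE-discontinuers accrue the utility chosen by the arm's AE
#' convention (see [utility_parameters()]). Horizon is expressed in years as
#' `horizon_weeks / 52`.
#'
#' @inheritParams expected_cost
#' @param util [utility_parameters()].
#' @return expected QALYs per patient.
#' @export
expected_qaly <- function(arm, util, econ) {
  mix <- arm$p_posthoc * util$u_posthoc +
    arm$p_partial * util$u_partial +
    arm$p_nonresponse * util$u_nonresponse
  ae_u <- ae_branch_utility(arm, util)
  years <- econ$horizon_weeks / 52
  ((1 - arm$p_discontinue_ae) * mix + arm$p_discontinue_ae * ae_u) * years
}

#' Responder counts per 1000 patients
#'
#' Counts use round-half-away-from-zero on `1000 * p_response * (1 - p_ae)`;
#' the total is the sum of the two rounded counts.
#'
#' @inheritParams expected_cost
#' @return list with `posthoc`, `partial`, `responders` per 1000 patients.
#' @export
cases_per_1000 <- function(arm) {
  keep <- 1 - arm$p_discontinue_ae
  posthoc <- round_half_away(1000 * arm$p_posthoc * keep)
  partial <- round_half_away(1000 * arm$p_partial * keep)
  list(posthoc = posthoc, partial = partial, responders = posthoc + partial)
}

#' Evaluate one strategy arm
#'
#' @inheritParams expected_qaly
#' @return object of class `arm_result`: expected cost (with components),
#'   expected QALYs and responder counts per 1000 patients.
#' @export
evaluate_arm <- function(arm, econ, util) {
  cost <- expected_cost(arm, econ)
  cases <- cases_per_1000(arm)
  structure(list(
    name = arm$name,
    expected_cost = cost$total,
    cost_direct_medical = cost$direct_medical,
    cost_drug = cost$drug,
    expected_qaly = expected_qaly(arm, util, econ),
    posthoc_per_1000 = cases$posthoc,
    partial_per_1000 = cases$partial,
    responders_per_1000 = cases$responders
  ), class = "arm_result")
}

#' Brute-force leaf enumeration of one arm (rollback oracle)
#'
#' Enumerates the tree's leaf paths (discontinue; continue x {post hoc,
#' partial, non-response}) and sums probability x payoff for cost and QALYs.
#' Exists as an independent check that the closed-form rollback in
#' [evaluate_arm()] is the correct expectation.
#'
#' @inheritParams expected_qaly
#' @return list with `expected_cost` and `expected_qaly`.
#' @export
enumerate_arm <- function(arm, econ, util) {
  daily_drug <- econ$drug_price_per_5mg * arm$daily_dose_mg / 5
  direct <- econ$weekly_direct_medical_cost * econ$horizon_weeks
  years <- econ$horizon_weeks / 52
  ae_u <- ae_branch_utility(arm, util)
  p_dc <- arm$p_discontinue_ae
  leaves <- list(
    list(p = p_dc,
         cost = direct + daily_drug * econ$ae_treatment_weeks * 7,
         qaly = ae_u * years),
    list(p = (1 - p_dc) * arm$p_posthoc,
         cost = direct + daily_drug * econ$days_per_horizon,
         qaly = util$u_posthoc * years),
    list(p = (1 - p_dc) * arm$p_partial,
         cost = direct + daily_drug * econ$days_per_horizon,
         qaly = util$u_partial * years),
    list(p = (1 - p_dc) * arm$p_nonresponse,
         cost = direct + daily_drug * econ$days_per_horizon,
         qaly = util$u_nonresponse * years)
  )
  list(
    expected_cost = sum(vapply(leaves, function(l) l$p * l$cost, 0)),
    expected_qaly = sum(vapply(leaves, function(l) l$p * l$qaly, 0)),
    total_probability = sum(vapply(leaves, function(l) l$p, 0))
  )
}

#' Incremental cost-effectiveness of a comparator versus a reference
#'
#' @param reference `arm_result` of the reference strategy (e.g. low dose).
#' @param comparator `arm_result` of the comparator (e.g. high dose).
#' @return object of class `incremental_result` with `delta_cost`,
#'   `delta_qaly`, `icer` (NA when undefined or dominated) and `dominance`
#'   (`"none"`, `"comparator_dominated"`, `"comparator_dominant"`,
#'   `"undefined_dqaly_zero"`).
#' @export
icer <- function(reference, comparator) {
  dc <- comparator$expected_cost - reference$expected_cost
  dq <- comparator$expected_qaly - reference$expected_qaly
  dominance <- "none"
  value <- NA_real_
  if (dq == 0) {
    dominance <- "undefined_dqaly_zero"
  } else if (dc > 0 && dq < 0) {
    dominance <- "comparator_dominated"
  } else if (dc < 0 && dq > 0) {
    dominance <- "comparator_dominant"
  } else {
    value <- dc / dq
  }
  structure(list(reference = reference$name, comparator = comparator$name,
                 delta_cost = dc, delta_qaly = dq,
                 icer = value, dominance = dominance),
            class = "incremental_result")
}

#' Net monetary benefit of the comparator
#'
#' `NMB = WTP * dQALY - dCost`; the comparator is preferred when NMB > 0.
#'
#' @param incremental an `incremental_result` from [icer()].
#' @param wtp willingness-to-pay threshold (USD per QALY, >= 0).
#' @return NMB in USD.
#' @export
net_monetary_benefit <- function(incremental, wtp) {
  if (wtp < 0) abort_config("wtp must be >= 0")
  wtp * incremental$delta_qaly - incremental$delta_cost
}
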