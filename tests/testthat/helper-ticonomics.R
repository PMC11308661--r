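# Shared fixtures. Everything is generated in code; no stored data.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cohort config for parameter-recovery work: censoring disabled so OLS against
# the generating truth is unbiased.
recovery_config <- function(n, seed, noise_sd = 0.07, ...) {
  cohort_config(n = n, seed = seed, noise_sd = noise_sd,
                utility_ceiling = Inf, utility_floor = -Inf,
                height_na_rate = 0, weight_na_rate = 0, ...)
}

default_cohort <- function(n = 144, seed = 20240807, ...) {
  generate_cohort(cohort_config(n = n, seed = seed, ...))
}

# Hand-rolled simple-regression oracle: slope = cov(x, y) / var(x).
ols_oracle <- function(x, y) {
  slope <- stats::cov(x, y) / stats::var(x)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Minimal psa_result stand-in for CEAC/scatter edge cases.
fake_psa <- function(delta_cost, delta_qaly) {
  structure(list(
    iterations = data.frame(iteration = seq_along(delta_cost),
                            delta_cost = delta_cost, delta_qaly = delta_qaly),
    n_iterations = length(delta_cost), seed = NA_integer_, wtp = 36832.95,
    summary = list()
  ), class = "psa_result")
}

all_ae_conventions <- c("baseline_minus_disutility",
                        "nonresponse_minus_disutility",
                        "response_mix_minus_disutility")
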