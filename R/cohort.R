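# Synthetic survey cohort: patient-level YGTSS scores and EQ-5D-Y utilities
# with the statistical structure the mapping stage assumes (negative linear
# utility-severity relationship, ceiling effect at utility 1).

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the published survey summaries of the mapping sample:
#' 144 children, ~87% male, age 9.01 (SD 2.47) years, YGTSS motor 11.28
#' (SD 5.07), vocal 4.95 (SD 6.36). The generating truth for utility is a
#' linear model \eqn{U = a + b \cdot YT + \epsilon} censored above at the
#' value-set ceiling (1 by default) and truncated below at the value-set
#' floor (0 by default).
#'
#' @param n cohort size (>= 10).
#' @param seed integer seed; generation is bit-reproducible for a fixed seed.
#' @param male_fraction proportion of males (sex coded 1 = male, 0 = female).
#' @param age_mean,age_sd age distribution in years, truncated to [2, 17]
#'   (paediatric inclusion window).
#' @param height_mean,height_sd height in cm.
#' @param weight_mean,weight_sd weight in kg.
#' @param motor_mean,motor_sd,vocal_mean,vocal_sd YGTSS subscale truncated
#'   normals on [0, 25], rounded to integers; the total score is their sum.
#' @param utility_intercept,utility_slope generating truth linking utility to
#'   the YGTSS total score.
#' @param utility_sex_effect additive utility shift for males (default 0); used
#'   to generate data with a genuine sex effect for model-comparison tests.
#' @param noise_sd Gaussian noise SD on the utility scale.
#' @param ceiling_prob_at_zero extra point-mass probability of utility exactly
#'   1 for a patient with YT = 0, decaying linearly to 0 at YT = 50; stress-
#'   test hook for an explicit ceiling mixture beyond plain censoring.
#' @param utility_ceiling upper censoring bound (default 1; `Inf` disables
#'   censoring, which the parameter-recovery simulations rely on).
#' @param utility_floor lower truncation bound (default 0; EQ-5D-Y value sets
#'   can go below 0, so this is configurable).
#' @param height_na_rate,weight_na_rate missingness injection rates for the
#'   two covariates the survey reported incomplete.
#'
#' @return an object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n = 50, seed = 1)
#' cohort <- generate_cohort(cfg)
#' summarize_cohort(cohort)
cohort_config <- function(n = 144L,
                          seed = 20240807L,
                          male_fraction = 0.8699,
                          age_mean = 9.01, age_sd = 2.47,
                          height_mean = 139.05, height_sd = 14.50,
                          weight_mean = 34.49, weight_sd = 11.92,
                          motor_mean = 11.28, motor_sd = 5.07,
                          vocal_mean = 4.95, vocal_sd = 6.36,
                          utility_intercept = 0.9881,
                          utility_slope = -0.0035,
                          utility_sex_effect = 0,
                          noise_sd = 0.07,
                          ceiling_prob_at_zero = 0,
                          utility_ceiling = 1,
                          utility_floor = 0,
                          height_na_rate = 1 / 144,
                          weight_na_rate = 2 / 144) {
  cfg <- list(
    n = as.integer(n), seed = as.integer(seed),
    male_fraction = male_fraction,
    age_mean = age_mean, age_sd = age_sd,
    height_mean = height_mean, height_sd = height_sd,
    weight_mean = weight_mean, weight_sd = weight_sd,
    motor_mean = motor_mean, motor_sd = motor_sd,
    vocal_mean = vocal_mean, vocal_sd = vocal_sd,
    utility_intercept = utility_intercept,
    utility_slope = utility_slope,
    utility_sex_effect = utility_sex_effect,
    noise_sd = noise_sd,
    ceiling_prob_at_zero = ceiling_prob_at_zero,
    utility_ceiling = utility_ceiling,
    utility_floor = utility_floor,
    height_na_rate = height_na_rate,
    weight_na_rate = weight_na_rate
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n < 10) abort_config("cohort n must be >= 10, got ", cfg$n)
  sds <- c(age = cfg$age_sd, height = cfg$height_sd, weight = cfg$weight_sd,
           motor = cfg$motor_sd, vocal = cfg$vocal_sd)
  if (any(sds <= 0)) {
    abort_config("all SDs must be > 0; offending: ",
                 paste(names(sds)[sds <= 0], collapse = ", "))
  }
  if (cfg$noise_sd < 0) abort_config("noise_sd must be >= 0")
  props <- c(male_fraction = cfg$male_fraction,
             ceiling_prob_at_zero = cfg$ceiling_prob_at_zero,
             height_na_rate = cfg$height_na_rate,
             weight_na_rate = cfg$weight_na_rate)
  if (any(props < 0 | props > 1)) {
    abort_config("proportions must lie in [0, 1]; offending: ",
                 paste(names(props)[props < 0 | props > 1], collapse = ", "))
  }
  if (cfg$utility_floor >= cfg$utility_ceiling) {
    abort_config("utility_floor must be below utility_ceiling")
  }
  invisible(cfg)
}

#' Generate a synthetic survey cohort
#'
#' Draws sex, age, height, weight and YGTSS motor/vocal subscores (independent
#' truncated normals on \[0, 25\], rounded to integers; the total score is
#' their exact sum), then utility as
#' `intercept + sex_effect * sex + slope * YT + N(0, noise_sd)`,
#' censored above at the value-set ceiling and truncated below at the floor.
#'
#' @param config a [cohort_config()].
#' @return a `data.frame` of patient records with columns `id, sex, age,
#'   height, weight, ygtss_motor, ygtss_vocal, ygtss_total, eq5dy_utility`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n
  set.seed(config$seed)

  sex <- stats::rbinom(n, 1L, config$male_fraction)
  # locations are moment-matched so the REALIZED truncated means equal the
  # configured (published) means despite the hard score bounds
  age <- rtruncnorm(n, trunc_mean_match(config$age_mean, config$age_sd, 2, 17),
                    config$age_sd, 2, 17)
  height <- rtruncnorm(n, config$height_mean, config$height_sd, 50, Inf)
  weight <- rtruncnorm(n, config$weight_mean, config$weight_sd, 5, Inf)
  motor <- as.integer(round(rtruncnorm(
    n, trunc_mean_match(config$motor_mean, config$motor_sd, 0, 25),
    config$motor_sd, 0, 25)))
  vocal <- as.integer(round(rtruncnorm(
    n, trunc_mean_match(config$vocal_mean, config$vocal_sd, 0, 25),
    config$vocal_sd, 0, 25)))
  total <- motor + vocal

  u <- config$utility_intercept +
    config$utility_sex_effect * sex +
    config$utility_slope * total +
    stats::rnorm(n, 0, config$noise_sd)
  # optional explicit ceiling point mass, decaying linearly in severity
  if (config$ceiling_prob_at_zero > 0) {
    p_mass <- config$ceiling_prob_at_zero * pmax(0, 1 - total / 50)
    at_ceiling <- stats::runif(n) < p_mass
    u[at_ceiling] <- config$utility_ceiling
  }
  u <- pmin(u, config$utility_ceiling)  # censor (ceiling effect)
  u <- pmax(u, config$utility_floor)    # truncate at value-set floor

  if (config$height_na_rate > 0) {
    height[stats::runif(n) < config$height_na_rate] <- NA_real_
  }
  if (config$weight_na_rate > 0) {
    weight[stats::runif(n) < config$weight_na_rate] <- NA_real_
  }

  data.frame(
    id = sprintf("P%04d", seq_len(n)),
    sex = as.integer(sex),
    age = round(age, 2),
    height = round(height, 1),
    weight = round(weight, 1),
    ygtss_motor = motor,
    ygtss_vocal = vocal,
    ygtss_total = total,
    eq5dy_utility = u,
    stringsAsFactors = FALSE
  )
}

#' Summarise a cohort in the survey-table layout
#'
#' Per-variable n (non-missing), mean and SD, plus sex counts and ratio.
#'
#' @param records cohort data frame as produced by [generate_cohort()].
#' @return list with components `variables` (data.frame: variable, n, mean,
#'   sd) and `sex` (data.frame: level, count, ratio_pct).
#' @export
summarize_cohort <- function(records) {
  validate_cohort(records, max_utility = Inf)
  if (nrow(records) == 0) stop("cannot summarise an empty cohort")
  num_vars <- c("age", "height", "weight",
                "ygtss_motor", "ygtss_vocal", "ygtss_total", "eq5dy_utility")
  variables <- do.call(rbind, lapply(num_vars, function(v) {
    x <- records[[v]]
    data.frame(variable = v, n = sum(!is.na(x)),
               mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  n_male <- sum(records$sex == 1L)
  n_female <- sum(records$sex == 0L)
  sex <- data.frame(
    level = c("male", "female"),
    count = c(n_male, n_female),
    ratio_pct = 100 * c(n_male, n_female) / nrow(records),
    stringsAsFactors = FALSE
  )
  list(variables = variables, sex = sex)
}

cohort_columns <- c("id", "sex", "age", "height", "weight",
                    "ygtss_motor", "ygtss_vocal", "ygtss_total",
                    "eq5dy_utility")

#' Validate patient records against the cohort invariants
#'
#' Checks column presence, sex coding, YGTSS ranges, the motor + vocal = total
#' identity and the utility ceiling. Errors name the first offending row.
#'
#' @param records data frame of patient records.
#' @param max_utility utility ceiling to enforce (default 1, the value-set
#'   ceiling; `Inf` for cohorts generated with censoring disabled).
#' @return the records, invisibly.
#' @export
validate_cohort <- function(records, max_utility = 1) {
  missing_cols <- setdiff(cohort_columns, names(records))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0) return(invisible(records))
  fail_row <- function(ok, what) {
    ok <- ok | is.na(ok) # missing values are handled downstream, not here
    if (!all(ok)) stop("row ", which(!ok)[1], ": ", what, call. = FALSE)
  }
  fail_row(is.na(records$sex) | records$sex %in% c(0L, 1L),
           "sex must be 0 (female) or 1 (male)")
  fail_row(records$ygtss_motor >= 0 & records$ygtss_motor <= 25,
           "ygtss_motor outside [0, 25]")
  fail_row(records$ygtss_vocal >= 0 & records$ygtss_vocal <= 25,
           "ygtss_vocal outside [0, 25]")
  fail_row(records$ygtss_total == records$ygtss_motor + records$ygtss_vocal,
           "ygtss_total != ygtss_motor + ygtss_vocal")
  fail_row(records$eq5dy_utility <= max_utility,
           paste0("eq5dy_utility above ", max_utility))
  invisible(records)
}

#' Write / read a cohort CSV
#'
#' UTF-8 CSV with a header row and dot decimal separator; `read_cohort()`
#' validates every row and reports the index of the first malformed one.
#' The pair round-trips field-for-field.
#'
#' @param records cohort data frame.
#' @param path file path.
#' @return `read_cohort()` returns the validated data frame.
#' @export
write_cohort <- function(records, path) {
  validate_cohort(records)
  utils::write.csv(records[cohort_columns], path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        na.strings = c("NA", ""))
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols)) {
    stop("cohort CSV missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) > 0) {
    df$sex <- as.integer(df$sex)
    df$ygtss_motor <- as.integer(df$ygtss_motor)
    df$ygtss_vocal <- as.integer(df$ygtss_vocal)
    df$ygtss_total <- as.integer(df$ygtss_total)
  } else {
    df$id <- character(0)
  }
  validate_cohort(df)
  df[cohort_columns]
}

#' Toy additive EQ-5D-Y value-set hook
#'
#' Interface stub for scoring 5-digit EQ-5D-Y health states (e.g. "11111",
#' "21231") with an additive SYNTHETIC value set: 1 minus a fixed decrement
#' per level above 1 in each dimension. The real national value set is not
#' reproduced here; this exists so code paths that consume a value-set
#' function can be exercised.
#'
#' @param states character vector of 5-digit level strings (levels 1-3).
#' @param decrement utility loss per level step (default 0.06).
#' @return numeric utilities, 1 for "11111".
#' @export
toy_value_set <- function(states, decrement = 0.06) {
  if (!all(grepl("^[1-3]{5}$", states))) {
    stop("states must be 5-digit strings with levels 1-3")
  }
  vapply(states, function(s) {
    lv <- as.integer(strsplit(s, "")[[1]])
    1 - decrement * sum(lv - 1L)
  }, numeric(1), USE.NAMES = FALSE)
}
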