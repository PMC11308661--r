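# YGTSS -> EQ-5D-Y utility mapping: two families (Gaussian-identity OLS and
# logit-link beta regression) crossed with four predictor sets, plus fit
# metrics, validation metrics and model comparison.

model_predictors <- list(
  model1 = "ygtss_total",
  model2 = c("ygtss_motor", "ygtss_vocal"),
  model3 = c("ygtss_total", "sex"),
  model4 = c("ygtss_motor", "ygtss_vocal", "sex")
)

#' Mapping model specification
#'
#' @param family `"gaussian_identity"` (ordinary least squares on the raw
#'   utility) or `"beta_logit"` (beta regression, logit mean link, constant
#'   precision, maximum likelihood on boundary-transformed utilities).
#' @param model predictor set: 1 = total tic score, 2 = motor + vocal
#'   subscales, 3 = total + sex, 4 = subscales + sex.
#' @return an object of class `mapping_spec`.
#' @export
mapping_spec <- function(family = c("gaussian_identity", "beta_logit"),
                         model = 1L) {
  family <- match.arg(family)
  model <- as.integer(model)
  if (!model %in% 1:4) stop("model must be one of 1, 2, 3, 4")
  structure(list(family = family, model = model,
                 predictors = model_predictors[[model]]),
            class = "mapping_spec")
}

#' Boundary transform for beta regression
#'
#' Compresses observed utilities on a closed interval into the open unit
#' interval with the affine map `(Y * (N - 1) + 0.5) / N`, where `N` is the
#' number of survey participants. The map is order-preserving, fixes 0.5, and
#' sends \[0, 1\] to \[0.5/N, 1 - 0.5/N\].
#'
#' @param utilities numeric vector of observed utilities.
#' @param N participant count (>= 2).
#' @return transformed utilities.
#' @export
#' @examples
#' transform_boundaries(c(0, 0.5, 1), N = 144)
transform_boundaries <- function(utilities, N) {
  if (length(N) != 1 || is.na(N) || N < 2) stop("N must be a single count >= 2")
  (utilities * (N - 1) + 0.5) / N
}

# ---- beta regression MLE (logit mean link, constant precision) -------------
# y_i ~ Beta(mu_i * phi, (1 - mu_i) * phi), logit(mu_i) = x_i' beta.
# Estimated by BFGS on (beta, log phi); SEs from the observed information.

beta_loglik <- function(theta, X, y) {
  k <- ncol(X)
  mu <- inv_logit(drop(X %*% theta[seq_len(k)]))
  phi <- exp(theta[k + 1])
  sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

fit_beta_logit <- function(X, y) {
  stopifnot(all(y > 0 & y < 1))
  k <- ncol(X)
  # start values: OLS on the logit scale; phi by method of moments at the mean
  z <- logit(y)
  beta0 <- tryCatch(stats::lsfit(X, z, intercept = FALSE)$coefficients,
                    error = function(e) rep(0, k))
  mu0 <- mean(y)
  phi0 <- max(mu0 * (1 - mu0) / stats::var(y) - 1, 1)
  theta0 <- c(beta0, log(phi0))
  opt <- stats::optim(theta0, beta_loglik, X = X, y = y,
                      method = "BFGS", hessian = TRUE,
                      control = list(fnscale = -1, maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop("beta regression did not converge (optim code ", opt$convergence, ")")
  }
  vcov_all <- tryCatch(solve(-opt$hessian), error = function(e) {
    stop("beta regression information matrix is singular")
  })
  list(
    coefficients = stats::setNames(opt$par[seq_len(k)], colnames(X)),
    se = stats::setNames(sqrt(diag(vcov_all))[seq_len(k)], colnames(X)),
    phi = exp(opt$par[k + 1]),
    loglik = opt$value,
    n_par = k + 1L
  )
}

# ---- fitting ---------------------------------------------------------------

#' Fit a utility mapping model
#'
#' Gaussian family: ordinary least squares of the raw utility on the
#' predictors. Beta family: observed utilities are first passed through
#' [transform_boundaries()] (with `N` = number of rows entering the fit unless
#' overridden), then fitted by maximum likelihood with a logit mean link and
#' constant precision. Rows with missing required covariates are dropped and
#' the count actually used is reported.
#'
#' Adjusted R-squared for the beta family is a pseudo version: the squared
#' Pearson correlation between `logit(y)` and the fitted linear predictor,
#' degree-of-freedom adjusted like the OLS statistic.
#'
#' @param records cohort data frame (see [generate_cohort()]).
#' @param spec a [mapping_spec()].
#' @param boundary_N override for the boundary-transform `N`; default is the
#'   number of complete rows for this spec.
#' @return an object of class `fitted_mapping` with coefficients, standard
#'   errors, p-values, `n_used`, `aic`, `bic`, `adj_r2` and (beta only)
#'   `phi` and `boundary_N`.
#' @export
fit_mapping <- function(records, spec, boundary_N = NULL) {
  stopifnot(inherits(spec, "mapping_spec"))
  validate_cohort(records, max_utility = Inf) # gaussian fits allow >1; beta checks (0,1) itself
  vars <- c("eq5dy_utility", spec$predictors)
  complete <- stats::complete.cases(records[vars])
  d <- records[complete, , drop = FALSE]
  n <- nrow(d)
  if (n < 10) stop("need >= 10 complete records, have ", n)
  constant <- vapply(spec$predictors,
                     function(v) stats::var(d[[v]]) == 0, logical(1))
  if (any(constant)) {
    stop("singular design: constant predictor(s) ",
         paste(spec$predictors[constant], collapse = ", "))
  }

  X <- cbind(`(Intercept)` = 1, as.matrix(d[spec$predictors]))
  y <- d$eq5dy_utility
  p <- length(spec$predictors)

  if (spec$family == "gaussian_identity") {
    fml <- stats::reformulate(spec$predictors, response = "eq5dy_utility")
    lmfit <- stats::lm(fml, data = d)
    sm <- summary(lmfit)
    out <- list(
      coefficients = stats::coef(lmfit),
      standard_errors = sm$coefficients[, "Std. Error"],
      p_values = sm$coefficients[, "Pr(>|t|)"],
      aic = stats::AIC(lmfit), bic = stats::BIC(lmfit),
      adj_r2 = sm$adj.r.squared,
      boundary_N = NULL, phi = NULL
    )
  } else {
    bN <- boundary_N %||% n
    yb <- transform_boundaries(y, bN)
    if (any(yb <= 0 | yb >= 1)) {
      stop("boundary-transformed utilities fall outside (0, 1); ",
           "utilities must lie in [0, 1] for the beta family")
    }
    bf <- fit_beta_logit(X, yb)
    eta <- drop(X %*% bf$coefficients)
    r2 <- stats::cor(logit(yb), eta)^2
    adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
    zval <- bf$coefficients / bf$se
    out <- list(
      coefficients = bf$coefficients,
      standard_errors = bf$se,
      p_values = 2 * stats::pnorm(-abs(zval)),
      aic = -2 * bf$loglik + 2 * bf$n_par,
      bic = -2 * bf$loglik + log(n) * bf$n_par,
      adj_r2 = adj_r2,
      boundary_N = bN, phi = bf$phi
    )
  }

  out$spec <- spec
  out$n_used <- n
  out$n_total <- nrow(records)
  # fingerprint of the records used, so compare_models can refuse to rank
  # fits from different data sets
  out$data_checksum <- config_hash(paste(
    nrow(records), sprintf("%.10f", sum(records$eq5dy_utility)),
    sum(records$ygtss_total), collapse = "|"
  ))
  class(out) <- "fitted_mapping"
  out
}

#' @export
print.fitted_mapping <- function(x, ...) {
  cat(sprintf("Utility mapping fit: %s, model %d (%s)\n",
              x$spec$family, x$spec$model,
              paste(x$spec$predictors, collapse = " + ")))
  tab <- data.frame(beta = x$coefficients, se = x$standard_errors,
                    p = x$p_values)
  print(round(tab, 4))
  cat(sprintf("n = %d, AIC = %.2f, BIC = %.2f, adj. R2 = %.3f\n",
              x$n_used, x$aic, x$bic, x$adj_r2))
  invisible(x)
}

#' Published utility mapping predictor
#'
#' Coefficient set of the selected total-score linear mapping
#' (utility = 0.9881 - 0.0035 * YT) used downstream by the decision tree.
#'
#' @return a `fitted_mapping`-like object usable with [predict_utility()].
#' @export
published_mapping <- function() {
  structure(list(
    coefficients = c(`(Intercept)` = 0.9881, ygtss_total = -0.0035),
    standard_errors = c(`(Intercept)` = 0.0139, ygtss_total = 0.0008),
    spec = mapping_spec("gaussian_identity", 1L),
    n_used = 144L
  ), class = "fitted_mapping")
}

#' Predict utilities from a fitted mapping
#'
#' Gaussian family: the linear predictor, deliberately NOT clipped to the
#' utility range. Beta family: inverse logit of the linear predictor.
#'
#' @param fit a `fitted_mapping` (e.g. from [fit_mapping()] or
#'   [published_mapping()]).
#' @param covariates data frame (or coercible list) containing every predictor
#'   the fit requires.
#' @return numeric vector of predicted utility indices.
#' @export
#' @examples
#' predict_utility(published_mapping(), data.frame(ygtss_total = c(0, 30.37)))
predict_utility <- function(fit, covariates) {
  stopifnot(inherits(fit, "fitted_mapping"))
  covariates <- as.data.frame(covariates)
  need <- fit$spec$predictors
  missing_terms <- setdiff(need, names(covariates))
  if (length(missing_terms)) {
    stop("missing covariate(s): ", paste(missing_terms, collapse = ", "))
  }
  X <- cbind(1, as.matrix(covariates[need]))
  eta <- drop(X %*% fit$coefficients[c("(Intercept)", need)])
  if (fit$spec$family == "beta_logit") inv_logit(eta) else eta
}

#' Out-of-sample style validation metrics
#'
#' MAE and RMSE of predictions against the observed utilities, on the ORIGINAL
#' utility scale for both families (beta predictions are inverse-linked, and
#' by default the boundary adjustment is not inverted before comparison;
#' set `invert_boundary = TRUE` to undo it).
#'
#' @param fit a `fitted_mapping`.
#' @param records cohort data frame with observed utilities and covariates.
#' @param invert_boundary undo the boundary transform on beta predictions
#'   before comparing (default `FALSE`).
#' @return list with `mae` and `rmse`.
#' @export
validation_metrics <- function(fit, records, invert_boundary = FALSE) {
  vars <- c("eq5dy_utility", fit$spec$predictors)
  ok <- stats::complete.cases(records[vars])
  d <- records[ok, , drop = FALSE]
  if (nrow(d) == 0) stop("no usable rows for validation")
  pred <- predict_utility(fit, d)
  if (invert_boundary && identical(fit$spec$family, "beta_logit")) {
    N <- fit$boundary_N
    pred <- (pred * N - 0.5) / (N - 1) # inverse of the boundary map
  }
  err <- d$eq5dy_utility - pred
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)))
}

#' Compare fitted mapping models
#'
#' Ranks a set of fits (all on the same records) by AIC, BIC, adjusted
#' R-squared, MAE and RMSE, flags the best per criterion (ties keep input
#' order and are all flagged), and reports per-covariate p-values so the
#' "keep demographics with p < 0.05" screening can be reproduced.
#'
#' @param fits list of `fitted_mapping` objects.
#' @param records the cohort all fits were computed on.
#' @param alpha screening level for the covariate significance flag.
#' @return list with `table` (one row per fit, metrics plus best-per-criterion
#'   flags) and `screening` (per fit and covariate: p-value and keep flag).
#' @export
compare_models <- function(fits, records, alpha = 0.05) {
  if (length(fits) < 2) stop("need at least 2 fits to compare")
  checksums <- vapply(fits, function(f) f$data_checksum %||% NA_character_,
                      character(1))
  if (length(unique(checksums)) != 1 || any(is.na(checksums))) {
    stop("fits were computed on different record sets")
  }
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    vm <- validation_metrics(f, records)
    data.frame(
      fit = i, family = f$spec$family, model = f$spec$model,
      n_used = f$n_used, aic = f$aic, bic = f$bic, adj_r2 = f$adj_r2,
      mae = vm$mae, rmse = vm$rmse, stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  tab$best_aic <- tab$aic == min(tab$aic)
  tab$best_bic <- tab$bic == min(tab$bic)
  tab$best_adj_r2 <- tab$adj_r2 == max(tab$adj_r2)
  tab$best_mae <- tab$mae == min(tab$mae)
  tab$best_rmse <- tab$rmse == min(tab$rmse)

  screening <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    covs <- setdiff(names(f$p_values), "(Intercept)")
    if (!length(covs)) return(NULL)
    data.frame(fit = i, family = f$spec$family, model = f$spec$model,
               term = covs, p_value = unname(f$p_values[covs]),
               keep = unname(f$p_values[covs]) < alpha,
               stringsAsFactors = FALSE)
  }))
  list(table = tab, screening = screening)
}
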