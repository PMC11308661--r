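# Small shared helpers.

#' Round half away from zero
#'
#' Responder counts per 1000 patients use commercial rounding, not the
#' IEC 60559 banker's rounding of base [round()].
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Inverse logit
#' @param x numeric vector on the real line.
#' @return values in (0, 1).
#' @keywords internal
inv_logit <- function(x) {
  1 / (1 + exp(-x))
}

#' Logit
#' @param p values in (0, 1).
#' @keywords internal
logit <- function(p) {
  log(p / (1 - p))
}

#' Truncated-normal draws via inverse-CDF
#'
#' @param n number of draws.
#' @param mean,sd normal parameters.
#' @param lower,upper truncation bounds.
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Rolling polynomial hash (base 31, mod 2^31 - 1) of a character scalar;
# exact in double arithmetic, used for run-manifest config fingerprints so no
# external digest package is needed.
config_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Location parameter mu such that a normal(mu, sd) truncated to [lower, upper]
# has the requested mean. Truncation (e.g. vocal scores at 0) would otherwise
# inflate the realized mean well above the published summary it must match.
trunc_mean_match <- function(target_mean, sd, lower, upper) {
  tmean <- function(mu) {
    a <- (lower - mu) / sd
    b <- (upper - mu) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    if (!is.finite(z) || z < 1e-12) {
      # far outside the window the truncated mean collapses onto a bound
      return(if (mu < lower) lower else upper)
    }
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  if (target_mean <= lower || (is.finite(upper) && target_mean >= upper)) {
    stop("target mean must lie strictly inside the truncation bounds")
  }
  stats::uniroot(function(mu) tmean(mu) - target_mean,
                 interval = c(lower - 10 * sd,
                              if (is.finite(upper)) upper + 10 * sd
                              else target_mean + 10 * sd),
                 tol = 1e-10)$root
}

abort_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("ticonomics_config_error", "error")))
}
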