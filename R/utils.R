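# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stop_input("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

#' Linearly interpolate an annual series
#'
#' Fills years between observed snapshot years by linear interpolation and
#' extrapolates constantly outside the observed range (first/last value
#' carried outward). Used for population and impervious-surface snapshots.
#'
#' @param years_obs integer years with observations (>= 2, distinct).
#' @param values values at `years_obs`.
#' @param years_out integer years at which the series is wanted.
#' @return numeric vector along `years_out`.
#' @export
interpolate_years <- function(years_obs, values, years_out) {
  if (length(years_obs) < 2L)
    stop_input("interpolation needs >= 2 snapshot years, got %d", length(years_obs))
  if (anyDuplicated(years_obs))
    stop_input("duplicate snapshot years")
  o <- order(years_obs)
  stats::approx(years_obs[o], values[o], xout = years_out, rule = 2)$y
}

#' Mean of the largest k events
#'
#' Summary used for episodic drivers (sediment input, wave exposure): the
#' mean of the `k` largest values of a series, e.g. the top five events
#' pre-disturbance or top three for later windows.
#'
#' @param x numeric values (events).
#' @param k number of top events to average; capped at `length(x)`.
#' @return scalar mean of the top `k` values.
#' @export
top_events_mean <- function(x, k) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop_input("no finite events supplied")
  assert_number(k, "k", lower = 1)
  k <- min(as.integer(k), length(x))
  mean(sort(x, decreasing = TRUE)[seq_len(k)])
}

# z-score columns of a data.frame/matrix; constant columns -> error naming them
standardize_columns <- function(x) {
  x <- as.data.frame(x)
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0 | !is.finite(sds)))
    stop_input("zero-variance predictor(s): %s",
               paste(names(x)[sds == 0 | !is.finite(sds)], collapse = ", "))
  out <- as.data.frame(scale(x))
  attr(out, "center") <- vapply(x, mean, numeric(1))
  attr(out, "scale") <- sds
  out
}

# small-sample corrected AIC
#' Akaike information criterion with small-sample correction
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1), with `k` the (effective) number
#' of estimated parameters. Returns `Inf` when the correction denominator is
#' non-positive (model too rich for the sample).
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters (may be fractional for penalized
#'   smooths, where the effective degrees of freedom are used).
#' @param n number of observations.
#' @return scalar AICc.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}
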