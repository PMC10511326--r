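# Shared fixtures and independent oracles, all built in code.

# draw an ordered three-category outcome from a proportional-odds truth
# (the fit_proportional_odds parameterization: logit P(y<=j) = C_j - z B)
draw_ordinal <- function(z, C, B) {
  eta <- as.numeric(as.matrix(z) %*% B)
  u <- stats::runif(length(eta))
  p_low <- stats::plogis(C[1] - eta)
  p_lowmod <- stats::plogis(C[2] - eta)
  ordered(ifelse(u <= p_low, "low", ifelse(u <= p_lowmod, "moderate", "high")),
          levels = c("low", "moderate", "high"))
}

# closed-form category probabilities from the same truth
ordinal_probs <- function(eta, C) {
  p_low <- stats::plogis(C[1] - eta)
  p_lowmod <- stats::plogis(C[2] - eta)
  c(low = p_low, moderate = p_lowmod - p_low, high = 1 - p_lowmod)
}

# brute-force fish biomass oracle: explicit per-fish loop
fish_biomass_oracle <- function(obs, area_m2) {
  total_g <- 0
  for (i in seq_len(nrow(obs)))
    for (f in seq_len(obs$count[i]))
      total_g <- total_g + obs$a[i] * obs$tl_cm[i]^obs$b[i]
  (total_g / 1000) / (area_m2 / 10000)
}

# fast linear fitter with the fit_additive_mixed interface, used for
# enumeration-count checks where smooth fits are not the point
linear_fitter <- function(response, predictors, subset = character(),
                          section = NULL, knots = 4, max_predictors = 5) {
  dat <- as.data.frame(predictors)[, subset, drop = FALSE]
  dat$.response <- response
  form <- if (length(subset))
    stats::as.formula(paste(".response ~", paste(subset, collapse = "+")))
  else .response ~ 1
  m <- stats::lm(form, data = dat)
  ll <- stats::logLik(m)
  k <- as.numeric(attr(ll, "df"))
  n <- length(response)
  list(fit = m, terms = subset, loglik = as.numeric(ll), k = k, n = n,
       aicc = aicc(as.numeric(ll), k, n))
}

# tiny synthetic bundle for driver/pipeline tests (kept small for speed)
small_bundle <- function(seed = 11, n_cells = 80, n_reefs = 24) {
  cfg <- synth_config(n_cells = n_cells, n_reefs = n_reefs, rng_seed = seed)
  generate_outcomes(generate_coast(cfg))
}
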