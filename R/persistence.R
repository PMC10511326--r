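# Post-disturbance stage: percentile categorization of reef-builder cover,
# proportional-odds ordinal regression by maximum likelihood, parallel-
# regression diagnostics, AICc dredging and the land-sea management
# scenario engine.

#' Categorize reef-builder cover by percentiles
#'
#' Reef-builder cover (hard coral + crustose coralline algae, %) is parsed
#' into three ordered categories: low (<= 25th percentile), moderate
#' (between the 25th and 75th) and high (>= 75th percentile), using the
#' package-wide linear-interpolation percentile convention.
#'
#' @param cover numeric cover values (>= 4).
#' @param probs the two percentile cut probabilities (default 0.25/0.75).
#' @param thresholds optional explicit `c(low, high)` thresholds
#'   overriding the percentiles (required when the sample is degenerate).
#' @return ordered factor with levels low < moderate < high and attribute
#'   `thresholds`.
#' @export
categorize_cover <- function(cover, probs = c(0.25, 0.75), thresholds = NULL) {
  if (length(cover) < 4L && is.null(thresholds))
    stop_input("need >= 4 cover values for percentile thresholds")
  if (is.null(thresholds)) {
    thresholds <- stats::quantile(cover, probs, type = 7, names = FALSE)
    if (diff(thresholds) <= 0)
      stop_input("degenerate spread: 25th and 75th percentiles coincide; supply explicit thresholds")
  }
  cat <- ifelse(cover <= thresholds[1], "low",
                ifelse(cover >= thresholds[2], "high", "moderate"))
  out <- factor(cat, levels = c("low", "moderate", "high"), ordered = TRUE)
  attr(out, "thresholds") <- thresholds
  out
}

# negative log-likelihood and gradient of the cumulative-logit model in
# the reparameterization theta = (C1, gamma_2.., B): C_j = C1 + cumsum(exp(gamma))
po_nll <- function(theta, y_idx, z, J) {
  p <- ncol(z)
  C <- theta[1] + c(0, cumsum(exp(theta[seq_len(J - 2) + 1])))
  B <- if (p) theta[J:(J - 1 + p)] else numeric(0)
  eta <- as.numeric(z %*% B)
  Fmat <- cbind(0, stats::plogis(outer(-eta, C, "+")), 1)  # F_ij = plogis(C_j - eta_i)
  pr <- Fmat[cbind(seq_along(y_idx), y_idx + 1L)] -
    Fmat[cbind(seq_along(y_idx), y_idx)]
  -sum(log(pmax(pr, 1e-300)))
}

po_grad <- function(theta, y_idx, z, J) {
  n <- length(y_idx); p <- ncol(z)
  expg <- exp(theta[seq_len(J - 2) + 1])
  C <- theta[1] + c(0, cumsum(expg))
  B <- if (p) theta[J:(J - 1 + p)] else numeric(0)
  eta <- as.numeric(z %*% B)
  a <- outer(-eta, C, "+")            # a_ij = C_j - eta_i, n x (J-1)
  Fm <- stats::plogis(a)
  fm <- Fm * (1 - Fm)
  Fful <- cbind(0, Fm, 1)
  pr <- pmax(Fful[cbind(seq_len(n), y_idx + 1L)] - Fful[cbind(seq_len(n), y_idx)], 1e-300)
  # dP_i/da_j = +f_ij if j == y_i, -f_ij if j == y_i - 1
  dP_da <- matrix(0, n, J - 1)
  sel_hi <- y_idx <= J - 1
  dP_da[cbind(which(sel_hi), y_idx[sel_hi])] <- fm[cbind(which(sel_hi), y_idx[sel_hi])]
  sel_lo <- y_idx >= 2
  dP_da[cbind(which(sel_lo), y_idx[sel_lo] - 1L)] <-
    dP_da[cbind(which(sel_lo), y_idx[sel_lo] - 1L)] -
    fm[cbind(which(sel_lo), y_idx[sel_lo] - 1L)]
  s <- dP_da / pr                      # d logP_i / d a_ij
  gC1 <- -sum(s)                       # da_j/dC1 = 1 for all j
  gGam <- numeric(J - 2)
  for (m in seq_len(J - 2))            # da_j/dgamma_m = expg[m] for j > m
    gGam[m] <- -expg[m] * sum(s[, (m + 1):(J - 1), drop = FALSE])
  gB <- as.numeric(t(z) %*% (-rowSums(s))) * -1  # da_j/dB_k = -z_ik
  c(gC1, gGam, gB) * 1
}

#' Fit a proportional-odds ordinal regression by maximum likelihood
#'
#' Cumulative-logit model for an ordered outcome with J categories:
#' `logit P(y <= j) = C_j - sum_k B_k z_k`, `j = 1..J-1`, with the slope
#' vector B shared across cut-points (the proportional-odds / parallel
#' regression assumption). In this parameterization a positive `B_k`
#' shifts probability toward higher categories, so e.g. a positive scraper
#' coefficient raises P(high reef-builder cover). Equivalently, indexing
#' categories from the top (j = 1 = high) and writing
#' `logit P(y at least as good as j) = C'_j + sum B_k z_k` gives the same
#' probabilities with `C'_j = -C_(J-j)`; the slopes are identical.
#'
#' Maximization is quasi-Newton (BFGS) on the negative log-likelihood with
#' an ordered-intercept reparameterization `C_(j+1) = C_j + exp(gamma_j)`,
#' analytic gradient, and convergence tolerance 1e-8. The covariance of
#' the natural parameters (C, B) is the inverse observed information,
#' obtained by the delta method from the reparameterized Hessian.
#'
#' @param y ordered factor (or coercible) outcome; every level must be
#'   observed.
#' @param z numeric matrix/data.frame of standardized predictors (may
#'   have zero columns for the intercept-only model).
#' @return object of class `"ordinal_fit"`: `C` (intercepts), `B` (named
#'   slopes), `vcov`, `loglik`, `n`, `levels`, `convergence`, `se`,
#'   `wald` (data.frame of per-slope z tests).
#' @export
fit_proportional_odds <- function(y, z = NULL) {
  y <- as.ordered(y)
  if (any(table(y) == 0L))
    stop_input("empty outcome category: %s",
               paste(levels(y)[table(y) == 0], collapse = ", "))
  J <- nlevels(y)
  if (J < 2L) stop_input("need >= 2 outcome categories")
  if (is.null(z)) z <- matrix(numeric(0), nrow = length(y), ncol = 0)
  z <- as.matrix(z)
  if (nrow(z) != length(y)) stop_input("predictor rows must match outcomes")
  p <- ncol(z)
  y_idx <- as.integer(y)
  # start: intercepts at the empirical cumulative logits, slopes at zero
  cum <- cumsum(prop.table(table(y)))[seq_len(J - 1)]
  C0 <- stats::qlogis(pmin(pmax(cum, 1e-3), 1 - 1e-3))
  theta0 <- c(C0[1], if (J > 2) log(pmax(diff(C0), 1e-3)), rep(0, p))
  opt <- stats::optim(theta0, po_nll, gr = po_grad, y_idx = y_idx, z = z, J = J,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  theta <- unname(opt$par)
  C <- theta[1] + c(0, cumsum(exp(theta[seq_len(J - 2) + 1])))
  B <- if (p) stats::setNames(theta[J:(J - 1 + p)],
                              colnames(z) %||% paste0("z", seq_len(p)))
       else stats::setNames(numeric(0), character(0))
  if (any(abs(B) > 25))
    stop_input("possible complete separation: coefficient magnitude > 25 (%s)",
               paste(names(B)[abs(B) > 25], collapse = ", "))
  H <- stats::optimHess(theta, po_nll, gr = po_grad, y_idx = y_idx, z = z, J = J)
  # delta method to the natural parameterization (C_1..C_{J-1}, B)
  Jac <- diag(length(theta))
  if (J > 2) {
    for (j in 2:(J - 1))
      for (m in seq_len(j - 1))
        Jac[j, m + 1] <- exp(theta[m + 1])
    Jac[2:(J - 1), 1] <- 1
  }
  V <- tryCatch({
    Vtheta <- solve(H)
    Jac %*% Vtheta %*% t(Jac)
  }, error = function(e) {
    stop_input("non-invertible information matrix (possible separation or collinearity)")
  })
  nm <- c(paste0("C", seq_len(J - 1)), names(B))
  dimnames(V) <- list(nm, nm)
  se <- sqrt(pmax(diag(V), 0))
  wald <- if (p) {
    zstat <- B / se[names(B)]
    data.frame(predictor = names(B), estimate = unname(B),
               se = unname(se[names(B)]), z = unname(zstat),
               p = unname(2 * stats::pnorm(-abs(zstat))))
  } else data.frame(predictor = character(), estimate = numeric(),
                    se = numeric(), z = numeric(), p = numeric())
  structure(list(C = C, B = B, vcov = V, se = se,
                 loglik = -opt$value, n = length(y), levels = levels(y),
                 convergence = opt$convergence, k = length(theta), wald = wald),
            class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("Proportional-odds fit: n = %d, logLik = %.3f\n", x$n, x$loglik))
  cat("Intercepts:", paste(sprintf("C%d = %.3f", seq_along(x$C), x$C), collapse = ", "), "\n")
  if (length(x$B)) print(x$wald, digits = 3) else cat("(intercept-only)\n")
  invisible(x)
}

#' Category probabilities from a proportional-odds fit
#'
#' @param object an `"ordinal_fit"`.
#' @param newdata matrix/data.frame of standardized predictor values with
#'   the fit's predictor columns (ignored for intercept-only fits).
#' @param ... unused.
#' @return matrix of category probabilities (rows sum to 1), columns
#'   named by outcome level.
#' @export
predict.ordinal_fit <- function(object, newdata = NULL, ...) {
  p <- length(object$B)
  if (p == 0) {
    eta <- if (is.null(newdata)) 0 else numeric(nrow(as.matrix(newdata)))
  } else {
    newdata <- as.matrix(as.data.frame(newdata)[, names(object$B), drop = FALSE])
    eta <- as.numeric(newdata %*% object$B)
  }
  Fm <- cbind(0, stats::plogis(outer(-eta, object$C, "+")), 1)
  pr <- Fm[, -1, drop = FALSE] - Fm[, -ncol(Fm), drop = FALSE]
  colnames(pr) <- object$levels
  pr
}

#' Brant test of the parallel-regression assumption
#'
#' Fits the J-1 separate binary logistic regressions I(y > j) ~ z and
#' forms Wald statistics on the equality of each predictor's coefficients
#' across cut-points (and an omnibus statistic over all predictors),
#' using the Brant (1990) covariance between the binary sub-models.
#' Reference distribution is chi-squared with (J-2) x p degrees of
#' freedom for the omnibus test. Not applicable to intercept-only models
#' or J = 2.
#'
#' @param y ordered outcome (J >= 3 levels observed).
#' @param z matrix/data.frame of predictors (p >= 1 columns).
#' @return data.frame with one row per predictor plus an omnibus row:
#'   `term`, `chisq`, `df`, `p`.
#' @export
brant_test <- function(y, z) {
  y <- as.ordered(y)
  J <- nlevels(droplevels(y))
  y <- droplevels(y)
  if (J < 3L) stop_input("Brant test needs >= 3 outcome categories")
  z <- as.matrix(as.data.frame(z))
  p <- ncol(z)
  if (p == 0L)
    return(data.frame(term = "omnibus", chisq = NA_real_, df = 0L, p = NA_real_,
                      note = "not applicable for intercept-only model"))
  n <- nrow(z)
  X <- cbind(1, z)
  y_idx <- as.integer(y)
  betas <- matrix(0, J - 1, p)          # slopes per cut-point
  pis <- matrix(0, n, J - 1)            # fitted P(y > j)
  for (j in seq_len(J - 1)) {
    yy <- as.integer(y_idx > j)
    fit <- suppressWarnings(stats::glm.fit(X, yy, family = stats::binomial()))
    if (!fit$converged || any(abs(fit$coefficients) > 25))
      stop_input("separation in binary sub-model at cut-point %d", j)
    betas[j, ] <- fit$coefficients[-1]
    pis[, j] <- fit$fitted.values
  }
  # Brant covariance blocks: for j <= l, w_i = pi_il - pi_ij * pi_il
  k <- p + 1
  Xt <- t(X)
  inv_jj <- lapply(seq_len(J - 1), function(j) {
    W <- pis[, j] * (1 - pis[, j])
    solve(Xt %*% (X * W))
  })
  V <- matrix(0, (J - 1) * p, (J - 1) * p)
  for (j in seq_len(J - 1)) for (l in j:(J - 1)) {
    w <- pis[, l] - pis[, j] * pis[, l]
    blk <- inv_jj[[j]] %*% (Xt %*% (X * w)) %*% inv_jj[[l]]
    blk <- blk[-1, -1, drop = FALSE]
    ri <- (j - 1) * p + seq_len(p); ci <- (l - 1) * p + seq_len(p)
    V[ri, ci] <- blk
    if (l > j) V[ci, ri] <- t(blk)
  }
  beta_vec <- as.numeric(t(betas))      # (beta_1', beta_2', ...)
  # contrasts: beta_1 - beta_j for j = 2..J-1
  D <- matrix(0, (J - 2) * p, (J - 1) * p)
  for (j in 2:(J - 1)) {
    ri <- (j - 2) * p + seq_len(p)
    D[cbind(ri, seq_len(p))] <- 1
    D[cbind(ri, (j - 1) * p + seq_len(p))] <- -1
  }
  wald_stat <- function(Dm) {
    d <- Dm %*% beta_vec
    as.numeric(t(d) %*% solve(Dm %*% V %*% t(Dm)) %*% d)
  }
  omni <- wald_stat(D)
  rows <- lapply(seq_len(p), function(kk) {
    Dk <- D[seq(kk, nrow(D), by = p), , drop = FALSE]
    st <- wald_stat(Dk)
    data.frame(term = colnames(z)[kk] %||% paste0("z", kk), chisq = st,
               df = J - 2L, p = stats::pchisq(st, J - 2L, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rbind(data.frame(term = "omnibus", chisq = omni, df = (J - 2L) * p,
                   p = stats::pchisq(omni, (J - 2L) * p, lower.tail = FALSE)),
        out)
}

#' Likelihood-ratio test between nested ordinal fits
#'
#' @param nested,full `"ordinal_fit"` objects on the same data, with the
#'   nested model's predictors a subset of the full model's.
#' @param alpha significance level for the reported decision.
#' @return list `statistic`, `df`, `p`, `reject` (logical at `alpha`).
#' @export
lr_test <- function(nested, full, alpha = 0.05) {
  if (!inherits(nested, "ordinal_fit") || !inherits(full, "ordinal_fit"))
    stop_input("both arguments must be ordinal fits")
  if (nested$n != full$n) stop_input("fits are on different data (n differs)")
  if (!all(names(nested$B) %in% names(full$B)))
    stop_input("models are not nested (predictors %s not in the full model)",
               paste(setdiff(names(nested$B), names(full$B)), collapse = ", "))
  df <- full$k - nested$k
  if (df < 0) stop_input("full model has fewer parameters than the nested model")
  stat <- max(0, 2 * (full$loglik - nested$loglik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p, reject = p < alpha)
}

#' McFadden's pseudo-R-squared
#'
#' `1 - logLik(full) / logLik(null)`; values above about 0.2 indicate an
#' excellent fit for likelihood-based models.
#'
#' @param fit fitted `"ordinal_fit"`.
#' @param null_fit intercept-only fit on the same outcomes; refitted
#'   internally when omitted (requires `y`).
#' @param y outcomes, needed only when `null_fit` is missing.
#' @return scalar pseudo-R-squared.
#' @export
mcfadden_r2 <- function(fit, null_fit = NULL, y = NULL) {
  if (is.null(null_fit)) {
    if (is.null(y)) stop_input("supply null_fit or the outcomes y")
    null_fit <- fit_proportional_odds(y, NULL)
  }
  if (null_fit$loglik == 0) stop_input("null log-likelihood is zero")
  if (fit$n != null_fit$n) stop_input("fits are on different data")
  1 - fit$loglik / null_fit$loglik
}

#' Rank all candidate proportional-odds models by AICc
#'
#' Fits every subset of the supplied predictors up to `max_predictors`
#' (default 4, reflecting the lower replication of the ordinal stage),
#' ranks by AICc, and records per-model McFadden pseudo-R-squared and
#' Wald coefficient tests. Unfittable candidates are skipped with a log
#' entry.
#'
#' @param y ordered outcome.
#' @param predictors data.frame of standardized predictors.
#' @param max_predictors largest candidate size (default 4).
#' @return `"reef_model_set"` whose `models` are `"ordinal_fit"` objects,
#'   with an extra `mcfadden` column in `$table`.
#' @export
dredge_ordinal <- function(y, predictors, max_predictors = 4) {
  predictors <- as.data.frame(predictors)
  null_fit <- fit_proportional_odds(y, NULL)
  ms <- dredge_core(names(predictors), max_predictors, function(s) {
    f <- fit_proportional_odds(y, if (length(s)) predictors[, s, drop = FALSE] else NULL)
    f$aicc <- aicc(f$loglik, f$k, f$n)
    f
  })
  ms$table$mcfadden <- vapply(ms$models, function(f)
    mcfadden_r2(f, null_fit), numeric(1))
  ms$predictors <- predictors
  ms
}

#' Percentile rank of a value in a reference sample
#'
#' Inverse of the package-wide type-7 (linear interpolation between order
#' statistics) quantile convention: the sample minimum maps to the 0th
#' percentile, the maximum to the 100th, the median of an odd-length
#' sample to the 50th; ties take the smallest attaining percentile and
#' out-of-range values clamp to 0/100.
#'
#' @param value numeric value(s).
#' @param reference non-empty numeric reference sample.
#' @return percentile(s) in `[0, 100]`.
#' @export
percentile_of <- function(value, reference) {
  reference <- reference[is.finite(reference)]
  if (!length(reference)) stop_input("empty reference sample")
  if (length(reference) == 1L) return(ifelse(value < reference, 0, 100))
  sx <- sort(reference)
  px <- 100 * (seq_along(sx) - 1) / (length(sx) - 1)
  stats::approx(sx, px, xout = value, rule = 2, ties = min)$y
}

#' Category probabilities under management scenarios
#'
#' Evaluates a fitted proportional-odds model at management lever settings
#' given on the raw measurement scale (e.g. scraper biomass in kg/ha,
#' wastewater effluent in l/ha/yr). Each lever value is passed through
#' the recorded transform (square root etc.) and standardization for that
#' predictor; all non-lever predictors are held at their sample mean
#' (standardized 0). Fold changes between scenarios are ratios of
#' category probabilities.
#'
#' @param fit `"ordinal_fit"` whose predictors include every lever.
#' @param scenarios named list; each element a named numeric vector of
#'   raw lever values, e.g.
#'   `list(initial = c(scraper = 30, wastewater = 6e5), C = c(scraper = 250, wastewater = 2500))`.
#' @param center,scale named standardization statistics on the
#'   post-transform scale (as recorded by [transform_predictors()]).
#' @param transforms named character vector of transforms per predictor
#'   (`"identity"`, `"sqrt"`, `"fourthroot"`); identity when omitted.
#' @return object of class `"scenario_result"`: `probabilities` (matrix
#'   scenario x category) and `z` (standardized lever matrix).
#' @export
scenario_probabilities <- function(fit, scenarios, center, scale,
                                   transforms = NULL) {
  if (!inherits(fit, "ordinal_fit")) stop_input("fit must be an ordinal fit")
  if (!length(fit$B)) stop_input("scenario engine needs a fitted predictor model")
  preds <- names(fit$B)
  z <- matrix(0, length(scenarios), length(preds),
              dimnames = list(names(scenarios), preds))
  for (s in seq_along(scenarios)) {
    lever <- scenarios[[s]]
    unknown <- setdiff(names(lever), preds)
    if (length(unknown))
      stop_input("lever(s) not in the fitted model: %s", paste(unknown, collapse = ", "))
    for (v in names(lever)) {
      tr <- if (!is.null(transforms) && v %in% names(transforms)) transforms[[v]] else "identity"
      if (!v %in% names(center) || !v %in% names(scale))
        stop_input("missing standardization stats for '%s'", v)
      z[s, v] <- (apply_transform(lever[[v]], tr) - center[[v]]) / scale[[v]]
    }
  }
  pr <- predict(fit, newdata = as.data.frame(z))
  rownames(pr) <- names(scenarios)
  structure(list(probabilities = pr, z = z), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario category probabilities:\n")
  print(round(x$probabilities, 3))
  invisible(x)
}

#' Fold change in a category probability between scenarios
#'
#' @param result `"scenario_result"` from [scenario_probabilities()].
#' @param category outcome category (e.g. `"high"`).
#' @param numerator,denominator scenario names.
#' @return scalar ratio `P(category | numerator) / P(category | denominator)`.
#' @export
fold_change <- function(result, category, numerator, denominator) {
  pr <- result$probabilities
  if (!category %in% colnames(pr)) stop_input("unknown category '%s'", category)
  if (!all(c(numerator, denominator) %in% rownames(pr)))
    stop_input("unknown scenario name(s)")
  pr[numerator, category] / pr[denominator, category]
}
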