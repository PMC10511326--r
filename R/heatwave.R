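# Heatwave-response stage: percentage-difference response, predictor
# preparation (outlier retention rule, transforms, correlation pruning,
# coast sectioning), penalized-spline additive mixed models, AICc
# all-subsets ranking, Akaike-weight averaging and relative importance.

#' Percentage-difference coral-cover response
#'
#' Change in coral cover relative to starting condition,
#' `delta = (A_a - A_b) / A_b * 100`, where `A_b` is the mean cover just
#' before the heatwave and `A_a` the cover the year after. Normalizing by
#' starting cover makes reefs with different scope for loss comparable.
#'
#' @param before,after percent cover before and after the event
#'   (vectorized); `before` must be > 0.
#' @return percentage difference (%).
#' @export
percentage_difference <- function(before, after) {
  if (any(before <= 0))
    stop_input("pre-event cover must be > 0 (reefs with zero cover are excluded)")
  (after - before) / before * 100
}

#' Outlier filter with a 25% retention rule
#'
#' Flags values outside `median +/- k * sd` like
#' [median_sd_outlier_filter()], then retains a flagged high value when it
#' lies within `retention` (default 25%) of the maximum unflagged value,
#' i.e. `v <= (1 + retention) * max(unflagged)`; symmetrically a flagged
#' low value is retained when `v >= (1 - sign-adjusted retention) *
#' min(unflagged)`. This avoids discarding points only marginally beyond
#' an arbitrary threshold.
#'
#' @param x numeric values (>= 3).
#' @param k threshold in SD units.
#' @param retention retention fraction (default 0.25).
#' @return list `retained` (values) and `removed` (indices into `x`).
#' @export
outlier_filter_with_retention <- function(x, k = 2, retention = 0.25) {
  if (length(x) < 3L) stop_input("outlier filter needs >= 3 values")
  assert_number(retention, "retention", lower = 0)
  m <- stats::median(x); s <- stats::sd(x)
  hi <- x > m + k * s
  lo <- x < m - k * s
  unflagged <- x[!hi & !lo]
  if (length(unflagged) == 0L) stop_input("every value flagged; nothing retained")
  hi_keep <- hi & x <= (1 + retention) * max(unflagged)
  lo_lim <- min(unflagged)
  lo_keep <- lo & x >= (if (lo_lim >= 0) (1 - retention) else (1 + retention)) * lo_lim
  removed <- which((hi & !hi_keep) | (lo & !lo_keep))
  list(retained = if (length(removed)) x[-removed] else x, removed = removed)
}

#' Transform and standardize predictors
#'
#' Applies square-root or fourth-root transforms to named predictors
#' (down-weighting extreme values of right-skewed loads), then z-score
#' standardizes every column. The transform applied to each predictor is
#' recorded so that raw management-lever values can later be mapped
#' through the identical chain.
#'
#' @param table data.frame of raw predictors (columns named).
#' @param sqrt_vars,fourthroot_vars character vectors naming columns to
#'   square-root / fourth-root transform (must be non-negative).
#' @return standardized data.frame with attributes `transforms` (named
#'   character), `center` and `scale` (post-transform standardization
#'   stats).
#' @export
transform_predictors <- function(table, sqrt_vars = character(),
                                 fourthroot_vars = character()) {
  table <- as.data.frame(table)
  unknown <- setdiff(c(sqrt_vars, fourthroot_vars), names(table))
  if (length(unknown)) stop_input("unknown predictor(s): %s", paste(unknown, collapse = ", "))
  if (length(intersect(sqrt_vars, fourthroot_vars)))
    stop_input("predictor(s) listed under both transforms")
  transforms <- stats::setNames(rep("identity", ncol(table)), names(table))
  for (v in sqrt_vars) {
    if (any(table[[v]] < 0)) stop_input("negative value under sqrt transform in '%s'", v)
    table[[v]] <- sqrt(table[[v]]); transforms[v] <- "sqrt"
  }
  for (v in fourthroot_vars) {
    if (any(table[[v]] < 0)) stop_input("negative value under fourth-root transform in '%s'", v)
    table[[v]] <- table[[v]]^0.25; transforms[v] <- "fourthroot"
  }
  out <- standardize_columns(table)
  attr(out, "transforms") <- transforms
  out
}

# map a raw value through a recorded transform name
apply_transform <- function(value, transform) {
  switch(transform,
         identity = value,
         sqrt = { if (any(value < 0)) stop_input("value outside sqrt domain"); sqrt(value) },
         fourthroot = { if (any(value < 0)) stop_input("value outside fourth-root domain"); value^0.25 },
         stop_input("unknown transform '%s'", transform))
}

#' Prune highly correlated predictors
#'
#' Iteratively removes one member of every pair of predictors with
#' `|r| > threshold` (Pearson). A caller-supplied `keep` preference list
#' encodes hypothesis-driven choices of which member to retain (e.g. keep
#' heat stress over SST mean/variability, peak over annual rainfall);
#' when neither member is preferred, the one with the larger mean absolute
#' correlation with the remaining predictors is dropped. Both members of
#' a conflicting pair being preferred is an error.
#'
#' @param table data.frame of (standardized) predictors.
#' @param threshold correlation threshold (default 0.7).
#' @param keep character vector of predictors preferred for retention.
#' @return pruned data.frame with attribute `removals`, a data.frame of
#'   `removed`, `kept`, `r` rows logging every pruning decision.
#' @export
prune_correlated <- function(table, threshold = 0.7, keep = character()) {
  table <- as.data.frame(table)
  if (ncol(table) < 2L) stop_input("need >= 2 predictors to prune")
  removals <- data.frame(removed = character(), kept = character(), r = numeric())
  repeat {
    cm <- stats::cor(table)
    diag(cm) <- 0
    if (max(abs(cm)) <= threshold) break
    ij <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    v1 <- colnames(cm)[ij[1]]; v2 <- colnames(cm)[ij[2]]
    in_keep <- c(v1, v2) %in% keep
    if (all(in_keep))
      stop_input("conflicting keep preferences: '%s' and '%s' are correlated (r = %.2f)",
                 v1, v2, cm[ij[1], ij[2]])
    if (in_keep[1]) drop <- v2
    else if (in_keep[2]) drop <- v1
    else {
      score <- colMeans(abs(cm))[c(v1, v2)]
      drop <- c(v1, v2)[which.max(score)]
    }
    kept <- setdiff(c(v1, v2), drop)
    removals <- rbind(removals,
                      data.frame(removed = drop, kept = kept, r = cm[ij[1], ij[2]]))
    table <- table[setdiff(names(table), drop)]
    if (ncol(table) < 2L) break
  }
  attr(table, "removals") <- removals
  table
}

#' Assign reefs to discrete coast sections
#'
#' Groups reefs into contiguous alongshore sections used as a random
#' spatial factor. Hierarchical agglomerative clustering (average
#' linkage) on pairwise alongshore distances is cut at every candidate
#' granularity and the intragroup variance is traced against the number
#' of groups. A pronounced inflection of that curve (discrete curvature
#' of its logarithm above `structure_threshold`, i.e. a many-fold
#' variance drop) fixes the granularity regardless of the target; absent
#' such structure, the granularity whose mean section span is closest to
#' `target_length_m` is used. Earliest qualifying granularity wins on
#' ties. A single reef forms one section.
#'
#' @param positions_m reef alongshore positions (metres).
#' @param target_length_m target section length (default 10 km).
#' @param structure_threshold log-curvature above which an inflection
#'   counts as pronounced spatial structure (default 2, about an
#'   e-squared-fold variance drop).
#' @return factor of section assignments (one level per section, ordered
#'   alongshore).
#' @export
coast_sections <- function(positions_m, target_length_m = 10000,
                           structure_threshold = 2) {
  n <- length(positions_m)
  if (n == 0L) stop_input("no reef positions supplied")
  if (n == 1L) return(factor("S1"))
  if (any(!is.finite(positions_m))) stop_input("positions must be finite")
  hc <- stats::hclust(stats::dist(positions_m), method = "average")
  ks <- seq_len(n)
  wss <- vapply(ks, function(k) {
    g <- stats::cutree(hc, k = k)
    sum(vapply(split(positions_m, g), function(p) sum((p - mean(p))^2), numeric(1)))
  }, numeric(1))
  span <- diff(range(positions_m))
  eps <- max(wss[1], 1) * 1e-9
  lw <- log(wss + eps)
  inner <- ks[ks >= 2 & ks <= n - 1]
  if (!length(inner)) {
    k_star <- if (span > target_length_m) 2L else 1L
  } else {
    curv <- lw[inner - 1] - 2 * lw[inner] + lw[inner + 1]
    if (max(curv) > structure_threshold) {
      k_star <- inner[which.max(curv)]  # pronounced inflection wins
    } else {
      k_star <- inner[which.min(abs(span / inner - target_length_m))]
    }
  }
  g <- stats::cutree(hc, k = k_star)
  # relabel sections in alongshore order
  ord <- rank(vapply(split(positions_m, g), mean, numeric(1)))
  factor(paste0("S", ord[as.character(g)]), levels = paste0("S", seq_len(k_star)))
}

#' Fit a penalized-spline additive mixed model
#'
#' Gaussian additive model for the heatwave response:
#' `delta = sum_j f_j(z_j) + section random intercept + error`, with each
#' `f_j` a penalized cubic regression spline limited to `knots` (default
#' 4) basis functions to curb overfitting, smoothness selected by
#' restricted maximum likelihood via \pkg{mgcv}. The empty subset fits an
#' intercept (plus random intercept) model. The effective number of
#' parameters (sum of effective degrees of freedom, including the scale
#' parameter) is used for AICc.
#'
#' @param response numeric response vector (percentage difference).
#' @param predictors data.frame of standardized predictors.
#' @param subset character vector of predictor names to include (<= 5).
#' @param section optional factor of coast sections (random intercept;
#'   dropped when it has fewer than 2 levels).
#' @param knots spline basis dimension per smooth (<= 4 by default).
#' @param max_predictors cap on `length(subset)`.
#' @return object of class `"reef_candidate"`: `fit` (gam), `terms`,
#'   `loglik`, `k` (effective parameters), `n`, `aicc`.
#' @export
fit_additive_mixed <- function(response, predictors, subset = character(),
                               section = NULL, knots = 4, max_predictors = 5) {
  predictors <- as.data.frame(predictors)
  if (length(subset) > max_predictors)
    stop_input("candidate model has %d predictors (max %d)", length(subset), max_predictors)
  unknown <- setdiff(subset, names(predictors))
  if (length(unknown)) stop_input("unknown predictor(s): %s", paste(unknown, collapse = ", "))
  for (v in subset) {
    if (stats::sd(predictors[[v]]) == 0)
      stop_input("zero-variance predictor '%s' in subset", v)
  }
  dat <- predictors[, subset, drop = FALSE]
  dat$.response <- response
  use_re <- !is.null(section) && nlevels(droplevels(as.factor(section))) >= 2L
  if (use_re) dat$.section <- droplevels(as.factor(section))
  smooths <- vapply(subset, function(v) {
    k_v <- min(knots, length(unique(dat[[v]])))
    sprintf("s(%s, bs = \"cr\", k = %d)", v, k_v)
  }, character(1))
  rhs <- c(smooths, if (use_re) "s(.section, bs = \"re\")")
  form <- stats::as.formula(paste(".response ~", if (length(rhs)) paste(rhs, collapse = " + ") else "1"))
  fit <- tryCatch(
    mgcv::gam(form, data = dat, method = "REML"),
    error = function(e) stop_input("model fit failed [%s]: %s",
                                   paste(subset, collapse = "+"), conditionMessage(e)))
  ll <- stats::logLik(fit)
  k_eff <- as.numeric(attr(ll, "df"))
  n <- length(response)
  structure(list(fit = fit, terms = subset, loglik = as.numeric(ll),
                 k = k_eff, n = n, aicc = aicc(as.numeric(ll), k_eff, n)),
            class = "reef_candidate")
}

# All-subsets enumeration + AICc ranking shared by the GAMM and ordinal
# stages. `fitter(subset)` must return a list with $loglik, $k, $n, $aicc.
dredge_core <- function(term_names, max_predictors, fitter) {
  subsets <- list(character())
  for (k in seq_len(min(max_predictors, length(term_names))))
    subsets <- c(subsets, utils::combn(term_names, k, simplify = FALSE))
  fits <- vector("list", length(subsets))
  skipped <- character()
  for (i in seq_along(subsets)) {
    fits[[i]] <- tryCatch(fitter(subsets[[i]]), error = function(e) {
      skipped <<- c(skipped, sprintf("[%s] %s",
                                     paste(subsets[[i]], collapse = "+"),
                                     conditionMessage(e)))
      NULL
    })
    if (!is.null(fits[[i]]) && !is.finite(fits[[i]]$aicc)) {
      skipped <- c(skipped, sprintf("[%s] AICc undefined (n - k - 1 <= 0)",
                                    paste(subsets[[i]], collapse = "+")))
      fits[[i]] <- NULL
    }
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop_input("no candidate model could be fitted")
  subsets <- subsets[ok]; fits <- fits[ok]
  aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
  delta <- aiccs - min(aiccs)
  w <- exp(-delta / 2); w <- w / sum(w)
  membership <- vapply(term_names, function(v)
    vapply(subsets, function(s) v %in% s, logical(1)),
    logical(length(subsets)))
  membership <- matrix(membership, nrow = length(subsets),
                       dimnames = list(NULL, term_names))
  ord <- order(aiccs)
  table <- data.frame(
    model = vapply(subsets, function(s)
      if (length(s)) paste(s, collapse = " + ") else "(intercept)", character(1)),
    n_terms = lengths(subsets),
    k = vapply(fits, function(f) f$k, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    AICc = aiccs, delta_AICc = delta, weight = w)[ord, ]
  rownames(table) <- NULL
  structure(list(table = table,
                 models = fits[ord],
                 subsets = subsets[ord],
                 membership = membership[ord, , drop = FALSE],
                 terms = term_names,
                 top = which(table$delta_AICc <= 2),
                 skipped = skipped),
            class = "reef_model_set")
}

#' @export
print.reef_model_set <- function(x, n = 6, ...) {
  cat(sprintf("Model set: %d candidate models over %d predictors; %d in the top set (dAICc <= 2)\n",
              nrow(x$table), length(x$terms), length(x$top)))
  print(utils::head(x$table, n), digits = 4)
  if (length(x$skipped)) cat(length(x$skipped), "candidate(s) skipped\n")
  invisible(x)
}

#' Rank all candidate additive mixed models by AICc
#'
#' Fits every subset of the supplied predictors up to `max_predictors`
#' smooth terms (all with the section random intercept), ranks by AICc
#' with small-sample correction, and computes dAICc and Akaike weights.
#' Candidates whose AICc correction is undefined (n - k - 1 <= 0) or that
#' fail to fit are skipped with a log entry.
#'
#' @param response,predictors,section,knots as [fit_additive_mixed()].
#' @param max_predictors largest candidate size (default 5).
#' @param fitter fitting function taking `(response, predictors, subset,
#'   section, knots, max_predictors)`; replaceable, e.g. by a fast linear
#'   fitter for enumeration checks.
#' @return object of class `"reef_model_set"`; see [dredge_ordinal()] for
#'   the ordinal analogue.
#' @export
dredge_rank <- function(response, predictors, section = NULL, max_predictors = 5,
                        knots = 4, fitter = fit_additive_mixed) {
  predictors <- as.data.frame(predictors)
  ms <- dredge_core(names(predictors), max_predictors, function(s)
    fitter(response, predictors, subset = s, section = section,
           knots = knots, max_predictors = max_predictors))
  ms$predictors <- predictors
  ms$section <- section
  ms
}

#' Per-predictor relative importance
#'
#' The relative importance of a predictor is the sum of Akaike weights of
#' all candidate models containing it; 1 means it appears in every model
#' carrying weight, 0 that it appears in none.
#'
#' @param model_set a `"reef_model_set"` from [dredge_rank()] or
#'   [dredge_ordinal()].
#' @return named numeric vector of importances in `[0, 1]`, sorted
#'   decreasing.
#' @export
relative_importance <- function(model_set) {
  if (!inherits(model_set, "reef_model_set")) stop_input("expected a model set")
  imp <- colSums(model_set$table$weight * model_set$membership)
  sort(imp, decreasing = TRUE)
}

#' Model-averaged prediction curve for a focal predictor
#'
#' Predicts the response over a grid of the focal predictor from every
#' top-set model (dAICc <= 2) containing it, holding all other predictors
#' at their medians, and combines the per-model predictions by (optionally
#' Akaike-weighted) averaging. The pointwise interval uses the combined
#' prediction variance (within-model squared standard errors plus
#' between-model spread).
#'
#' @param model_set a `"reef_model_set"` from [dredge_rank()].
#' @param focal name of the focal predictor.
#' @param grid grid of focal values; defaults to 50 points over the
#'   observed range.
#' @param level interval coverage (default 0.80).
#' @param weighted Akaike-weight the top models (default) or average
#'   unweighted.
#' @return data.frame `focal`, `fit`, `lower`, `upper`.
#' @export
model_average_predict <- function(model_set, focal, grid = NULL, level = 0.80,
                                  weighted = TRUE) {
  if (is.null(model_set$predictors))
    stop_input("model set lacks stored predictors; refit with dredge_rank()")
  preds <- model_set$predictors
  if (!focal %in% names(preds)) stop_input("unknown focal predictor '%s'", focal)
  top <- model_set$top
  has_focal <- top[vapply(model_set$subsets[top], function(s) focal %in% s, logical(1))]
  if (!length(has_focal))
    stop_input("focal predictor '%s' absent from every top model", focal)
  if (is.null(grid))
    grid <- seq(min(preds[[focal]]), max(preds[[focal]]), length.out = 50)
  newdata <- as.data.frame(lapply(preds, function(col)
    rep(stats::median(col), length(grid))))
  newdata[[focal]] <- grid
  if (!is.null(model_set$section)) {
    sec <- droplevels(as.factor(model_set$section))
    newdata$.section <- factor(levels(sec)[1], levels = levels(sec))
  }
  w <- model_set$table$weight[has_focal]
  w <- if (weighted) w / sum(w) else rep(1 / length(has_focal), length(has_focal))
  mu <- matrix(0, length(grid), length(has_focal))
  se <- matrix(0, length(grid), length(has_focal))
  for (j in seq_along(has_focal)) {
    f <- model_set$models[[has_focal[j]]]$fit
    # exclude the random-intercept smooth so the curve is the population level
    excl <- if (".section" %in% all.vars(stats::formula(f))) "s(.section)" else NULL
    p <- mgcv::predict.gam(f, newdata = newdata, se.fit = TRUE, exclude = excl,
                           newdata.guaranteed = TRUE)
    mu[, j] <- as.numeric(p$fit); se[, j] <- as.numeric(p$se.fit)
  }
  avg <- as.numeric(mu %*% w)
  var_comb <- as.numeric((se^2 + mu^2) %*% w) - avg^2
  var_comb[var_comb < 0] <- 0
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(focal = grid, fit = avg,
             lower = avg - z * sqrt(var_comb), upper = avg + z * sqrt(var_comb))
}
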