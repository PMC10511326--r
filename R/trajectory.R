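# Pre-disturbance stage: trajectory classification, drop-one jackknife
# group contrasts, one-factor PERMANOVA and canonical analysis of
# principal coordinates (CAP).

#' Classify a reef's pre-disturbance coral-cover trajectory
#'
#' A reef is on a positive (negative) trajectory when coral cover between
#' the first and last pre-disturbance survey changed by more than `cutoff`
#' percentage points upward (downward); otherwise it shows no change. The
#' default cutoff of 3 percentage points reflects the range in mean cover
#' across reefs over a stable 12-year period.
#'
#' @param cover_start,cover_end percent cover in the first and last survey
#'   year (0-100), vectorized.
#' @param cutoff classification threshold in percentage points (>= 0).
#' @return data.frame `delta` (percentage-point change) and `class`
#'   (factor: negative / no-change / positive).
#' @export
classify_trajectory <- function(cover_start, cover_end, cutoff = 3) {
  assert_number(cutoff, "cutoff", lower = 0)
  if (any(cover_start < 0 | cover_start > 100 | cover_end < 0 | cover_end > 100))
    stop_input("covers must lie in [0, 100]")
  delta <- cover_end - cover_start
  cls <- ifelse(delta > cutoff, "positive", ifelse(delta < -cutoff, "negative", "no-change"))
  data.frame(delta = delta,
             class = factor(cls, levels = c("negative", "no-change", "positive")))
}

#' Remove outliers beyond k standard deviations of the median
#'
#' Flags and removes values outside `median(x) +/- k * sd(x)` (sample SD).
#' A constant vector has SD 0 and every value at the median, so nothing is
#' removed unless `k = 0` would empty the sample, which errors.
#'
#' @param x numeric values (>= 3).
#' @param k threshold in SD units (default 2).
#' @return list with `retained` (values), `removed` (integer indices into
#'   `x`).
#' @export
median_sd_outlier_filter <- function(x, k = 2) {
  if (length(x) < 3L) stop_input("outlier filter needs >= 3 values")
  assert_number(k, "k", lower = 0)
  m <- stats::median(x); s <- stats::sd(x)
  out <- which(x < m - k * s | x > m + k * s)
  if (length(out) == length(x))
    stop_input("degenerate filter: every value removed")
  list(retained = if (length(out)) x[-out] else x, removed = out)
}

#' Drop-one jackknife contrast between two groups
#'
#' Computes all drop-one (leave-one-out) means within each group, then the
#' mean, minimum and maximum of the pairwise differences between group A's
#' and group B's drop-one means. Because the mean of drop-one means equals
#' the full-sample mean, the reported mean difference equals the
#' difference of group means; the min/max bracket its jackknife
#' sensitivity.
#'
#' @param a,b numeric vectors (each >= 2 values, outlier-filtered
#'   upstream).
#' @return list `mean`, `min`, `max` (of pairwise drop-one differences
#'   a - b).
#' @export
jackknife_group_difference <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop_input("each group needs >= 2 values for the drop-one jackknife")
  ja <- vapply(seq_along(a), function(i) mean(a[-i]), numeric(1))
  jb <- vapply(seq_along(b), function(i) mean(b[-i]), numeric(1))
  d <- outer(ja, jb, "-")
  list(mean = mean(d), min = min(d), max = max(d))
}

# within-group sum of squared distances from a squared-distance matrix:
# SS_w = sum over groups of (sum_{i<j in g} d2_ij) / n_g
permanova_ss <- function(d2, labels) {
  ss_w <- 0
  for (g in levels(labels)) {
    idx <- which(labels == g)
    ss_w <- ss_w + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_w
}

permanova_f <- function(d2, labels) {
  n <- length(labels); g <- nlevels(labels)
  ss_t <- sum(d2) / (2 * n)
  ss_w <- permanova_ss(d2, labels)
  ss_b <- ss_t - ss_w
  if (ss_w <= .Machine$double.eps * ss_t)
    stop_input("degenerate design: zero within-group variance (pseudo-F unbounded)")
  (ss_b / (g - 1)) / (ss_w / (n - g))
}

#' One-factor PERMANOVA on Euclidean distances
#'
#' Permutational multivariate analysis of variance for a single grouping
#' factor: pseudo-F from between/within sums of squared Euclidean
#' distances on the (z-score normalized) data, with an unrestricted
#' permutation p-value. When the number of distinct label arrangements is
#' at most `exact_limit` (two-group designs), all arrangements are
#' enumerated and the p-value is exact; otherwise `n_perm` random
#' permutations are drawn and p = (#{F_perm >= F_obs} + 1) / (n_perm + 1).
#'
#' @param x numeric matrix/data.frame, reefs x factors.
#' @param labels grouping factor (>= 2 groups, each >= 2 members).
#' @param n_perm random permutations when enumeration is infeasible.
#' @param exact_limit enumeration threshold on the number of distinct
#'   arrangements.
#' @param normalize z-score columns first (recommended; the statistic is
#'   defined on normalized data).
#' @return object of class `"reef_permanova"`: `pseudo_F`, `df`
#'   (between, residual), `p`, `n_perm`, `method` ("exact" or "sampled").
#' @export
permanova <- function(x, labels, n_perm = 9999, exact_limit = 20000,
                      normalize = TRUE) {
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop_input("need >= 2 groups")
  if (any(table(labels) < 2L)) stop_input("every group needs >= 2 members")
  if (nrow(x) != length(labels)) stop_input("labels must match rows of x")
  if (normalize) x <- as.matrix(standardize_columns(x))
  d2 <- as.matrix(stats::dist(x))^2
  f_obs <- permanova_f(d2, labels)
  n <- length(labels)
  counts <- table(labels)
  n_arrangements <- exp(lgamma(n + 1) - sum(lgamma(counts + 1)))
  if (nlevels(labels) == 2L && n_arrangements <= exact_limit) {
    idx <- utils::combn(n, counts[[1]])
    fs <- apply(idx, 2, function(i) {
      lab <- factor(ifelse(seq_len(n) %in% i, levels(labels)[1], levels(labels)[2]),
                    levels = levels(labels))
      permanova_f(d2, lab)
    })
    p <- sum(fs >= f_obs - 1e-12) / ncol(idx)
    method <- "exact"; n_used <- ncol(idx)
  } else {
    fs <- vapply(seq_len(n_perm), function(i)
      permanova_f(d2, sample(labels)), numeric(1))
    p <- (sum(fs >= f_obs - 1e-12) + 1) / (n_perm + 1)
    method <- "sampled"; n_used <- n_perm
  }
  structure(list(pseudo_F = f_obs,
                 df = c(between = nlevels(labels) - 1L, residual = n - nlevels(labels)),
                 p = p, n_perm = n_used, method = method),
            class = "reef_permanova")
}

#' @export
print.reef_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (one factor, Euclidean): pseudo-F%d,%d = %.3f, P = %.4g (%s, %d permutations)\n",
              x$df[1], x$df[2], x$pseudo_F, x$p, x$method, x$n_perm))
  invisible(x)
}

#' Canonical analysis of principal coordinates (CAP)
#'
#' Principal-coordinates analysis of the Euclidean distance matrix
#' followed by linear discriminant analysis on the first `m` PCO axes.
#' When `m` is not supplied it is chosen to maximize leave-one-out
#' cross-validation allocation success (earliest maximum on ties).
#' Allocation success above what chance alone gives (e.g. 50% for two
#' balanced groups) indicates increasingly distinct multivariate
#' conditions between the groups.
#'
#' @param x numeric matrix/data.frame, reefs x factors.
#' @param labels grouping factor, as in [permanova()].
#' @param m number of PCO axes to use; `NULL` selects by leave-one-out.
#' @param normalize z-score columns first.
#' @return object of class `"cap_result"`: `m`, `allocation_success`
#'   (percent, per group), `overall_success`, `scores` (first canonical
#'   axis per reef), `loo_by_m` (overall success per candidate m).
#' @export
cap <- function(x, labels, m = NULL, normalize = TRUE) {
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop_input("need >= 2 groups")
  if (any(table(labels) < 2L)) stop_input("every group needs >= 2 members")
  if (normalize) x <- as.matrix(standardize_columns(x))
  n <- nrow(x)
  pco <- suppressWarnings(stats::cmdscale(stats::dist(x), k = n - 1, eig = TRUE))
  keep <- which(pco$eig > max(pco$eig) * 1e-8)
  keep <- keep[keep <= ncol(pco$points)]
  scores <- pco$points[, keep, drop = FALSE]
  m_max <- max(1L, min(ncol(scores), n - nlevels(labels) - 1L))
  if (!is.null(m)) {
    assert_number(m, "m", lower = 1)
    if (m > ncol(scores))
      stop_input("m = %d exceeds the %d available PCO axes", m, ncol(scores))
  }
  loo_success <- function(mm) {
    pred <- vapply(seq_len(n), function(i) {
      fit <- MASS::lda(scores[-i, seq_len(mm), drop = FALSE], grouping = labels[-i])
      as.character(stats::predict(fit, scores[i, seq_len(mm), drop = FALSE])$class)
    }, character(1))
    pred
  }
  if (is.null(m)) {
    succ <- vapply(seq_len(m_max), function(mm)
      mean(loo_success(mm) == as.character(labels)), numeric(1))
    m <- which.max(succ)  # earliest maximum
    loo_by_m <- succ
  } else {
    loo_by_m <- NULL
  }
  pred <- loo_success(m)
  per_group <- vapply(levels(labels), function(g)
    100 * mean(pred[labels == g] == g), numeric(1))
  fit_all <- MASS::lda(scores[, seq_len(m), drop = FALSE], grouping = labels)
  axis1 <- as.numeric(scale(scores[, seq_len(m), drop = FALSE] %*% fit_all$scaling[, 1],
                            scale = FALSE))
  structure(list(m = m, allocation_success = per_group,
                 overall_success = 100 * mean(pred == as.character(labels)),
                 scores = axis1, loo_by_m = loo_by_m),
            class = "cap_result")
}

#' @export
print.cap_result <- function(x, ...) {
  cat(sprintf("CAP: m = %d PCO axes; leave-one-out allocation success %s (overall %.1f%%)\n",
              x$m,
              paste(sprintf("%s %.1f%%", names(x$allocation_success),
                            x$allocation_success), collapse = ", "),
              x$overall_success))
  invisible(x)
}

#' Jackknife contrast table across driver factors
#'
#' Applies the median +/- k SD outlier filter within each group and factor,
#' then the drop-one jackknife contrast, producing the per-factor mean /
#' min / max difference table between two trajectory groups.
#'
#' @param drivers data.frame of per-reef factor values (columns =
#'   factors).
#' @param labels trajectory classes per reef; the contrast is
#'   `group_a - group_b`.
#' @param group_a,group_b the two class labels to contrast.
#' @param k outlier threshold in SD units.
#' @return data.frame `factor`, `mean_diff`, `min_diff`, `max_diff`,
#'   `n_removed`.
#' @export
jackknife_table <- function(drivers, labels, group_a = "positive",
                            group_b = "negative", k = 2) {
  drivers <- as.data.frame(drivers)
  labels <- as.character(labels)
  out <- lapply(names(drivers), function(v) {
    a <- drivers[[v]][labels == group_a]
    b <- drivers[[v]][labels == group_b]
    fa <- median_sd_outlier_filter(a, k); fb <- median_sd_outlier_filter(b, k)
    j <- jackknife_group_difference(fa$retained, fb$retained)
    data.frame(factor = v, mean_diff = j$mean, min_diff = j$min,
               max_diff = j$max, n_removed = length(fa$removed) + length(fb$removed))
  })
  do.call(rbind, out)
}
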