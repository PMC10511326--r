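# Post-disturbance stage: categorization, proportional-odds MLE,
# assumption tests, ordinal dredge, scenario engine, percentiles.

test_that("cover categorization uses the linear-interpolation percentile cuts", {
  got <- categorize_cover(1:8)
  expect_equal(unname(attr(got, "thresholds")), c(2.75, 6.25))
  expect_equal(as.character(got),
               c("low", "low", "moderate", "moderate", "moderate", "moderate",
                 "high", "high"))
  # one quarter at each tail by construction
  x <- c(1, 2, 10, 11, 12, 13, 20, 21)
  expect_equal(as.vector(table(categorize_cover(x))), c(2, 4, 2))
  expect_error(categorize_cover(rep(5, 10)), "degenerate")
  # explicit thresholds rescue degenerate spread
  expect_equal(as.character(categorize_cover(rep(5, 4),
                                             thresholds = c(1, 10))),
               rep("moderate", 4))
})

test_that("intercept-only MLE equals the closed-form cumulative logits", {
  y <- ordered(rep(c("low", "moderate", "high"), each = 10),
               levels = c("low", "moderate", "high"))
  fit <- fit_proportional_odds(y)
  expect_equal(fit$C, c(-log(2), log(2)), tolerance = 1e-4)
  expect_equal(fit$loglik, sum(10 * log(rep(1 / 3, 3))), tolerance = 1e-6)
  # probabilities sum to one
  pr <- predict(fit)
  expect_equal(unname(rowSums(pr)), 1, tolerance = 1e-12)
})

test_that("slopes constrained to zero reduce to the intercept-only solution", {
  set.seed(29)
  z <- matrix(rnorm(30), dimnames = list(NULL, "z1"))
  y <- draw_ordinal(z, C = c(-1, 1), B = 0.8)
  fit0 <- fit_proportional_odds(y, NULL)
  cum <- cumsum(prop.table(table(y)))[1:2]
  expect_equal(fit0$C, unname(qlogis(cum)), tolerance = 1e-5)
})

test_that("estimates agree with an independent implementation and nesting holds", {
  set.seed(37)
  n <- 150
  z <- matrix(rnorm(2 * n), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- draw_ordinal(z, C = c(-1, 1), B = c(1.2, -0.7))
  fit <- fit_proportional_odds(y, z)
  pol <- MASS::polr(y ~ a + b, data = data.frame(z), Hess = TRUE)
  expect_equal(unname(fit$B), unname(coef(pol)), tolerance = 1e-4)
  expect_equal(fit$C, unname(pol$zeta), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(pol)), tolerance = 1e-6)
  expect_equal(unname(fit$se[names(fit$B)]),
               unname(sqrt(diag(vcov(pol)))[1:2]), tolerance = 1e-3)
  # adding a predictor never lowers the maximized log-likelihood
  fit_a <- fit_proportional_odds(y, z[, "a", drop = FALSE])
  expect_gte(fit$loglik + 1e-8, fit_a$loglik)
  expect_gte(fit_a$loglik + 1e-8, fit_proportional_odds(y, NULL)$loglik)
})

test_that("both category-indexing conventions give identical probabilities", {
  # fitted (low-first, C_j - eta) versus the top-down indexing with
  # C'_j = -C_(J-j): P(high) = plogis(C'_1 + eta)
  set.seed(41)
  z <- matrix(rnorm(60), dimnames = list(NULL, "z1"))
  y <- draw_ordinal(z, C = c(-1, 1), B = 1)
  fit <- fit_proportional_odds(y, z)
  pr <- predict(fit, z)
  eta <- as.numeric(z %*% fit$B)
  Cp <- rev(-fit$C)
  p_high <- plogis(Cp[1] + eta)
  p_high_or_mod <- plogis(Cp[2] + eta)
  expect_equal(unname(pr[, "high"]), p_high, tolerance = 1e-12)
  expect_equal(unname(pr[, "moderate"]), p_high_or_mod - p_high, tolerance = 1e-12)
})

test_that("Brant test holds its size under proportional odds and detects violations", {
  set.seed(43)
  rej <- replicate(300, {
    z <- matrix(rnorm(200), dimnames = list(NULL, "z1"))
    y <- draw_ordinal(z, C = c(-0.8, 0.8), B = 0.7)
    bt <- tryCatch(brant_test(y, z), error = function(e) NULL)
    if (is.null(bt)) NA else bt$p[bt$term == "omnibus"] < 0.05
  })
  expect_lt(abs(mean(rej, na.rm = TRUE) - 0.05), 0.035)
  # cut-point-specific slopes: power above 50% at n = 500
  set.seed(44)
  pow <- replicate(60, {
    z <- matrix(pmax(pmin(rnorm(500), 2.5), -2.5), dimnames = list(NULL, "z1"))
    u <- runif(500)
    p1 <- plogis(-1 - 0.4 * z[, 1]); p2 <- plogis(1 - 1.3 * z[, 1])
    p2 <- pmax(p1, p2)
    y <- ordered(ifelse(u <= p1, "low", ifelse(u <= p2, "moderate", "high")),
                 levels = c("low", "moderate", "high"))
    bt <- tryCatch(brant_test(y, z), error = function(e) NULL)
    if (is.null(bt)) NA else bt$p[bt$term == "omnibus"] < 0.05
  })
  expect_gt(mean(pow, na.rm = TRUE), 0.5)
  # intercept-only: explicit not-applicable result
  y0 <- ordered(rep(c("low", "moderate", "high"), 5),
                levels = c("low", "moderate", "high"))
  na_res <- brant_test(y0, matrix(numeric(0), nrow = 15, ncol = 0))
  expect_match(na_res$note, "not applicable")
})

test_that("likelihood-ratio test behaves at both ends", {
  set.seed(47)
  z <- matrix(rnorm(400), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- draw_ordinal(z, C = c(-1, 1), B = c(1.5, 0))
  full <- fit_proportional_odds(y, z)
  same <- lr_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # strong injected effect is detected
  nested <- fit_proportional_odds(y, z[, "b", drop = FALSE])
  lt <- lr_test(nested, full)
  expect_equal(lt$df, 1)
  expect_lt(lt$p, 0.05)
  expect_error(lr_test(full, nested), "fewer|not nested")
})

test_that("pure-noise extra parameter gives a roughly uniform LR p-value", {
  set.seed(53)
  ps <- replicate(120, {
    z <- matrix(rnorm(240), ncol = 2, dimnames = list(NULL, c("a", "b")))
    y <- draw_ordinal(z, C = c(-1, 1), B = c(1, 0))
    full <- fit_proportional_odds(y, z)
    nested <- fit_proportional_odds(y, z[, "a", drop = FALSE])
    lr_test(nested, full)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("McFadden pseudo-R2 matches direct formula evaluation", {
  set.seed(59)
  z <- matrix(c(-2, -1, 0, 0, 1, 2), dimnames = list(NULL, "z1"))
  y <- ordered(c("low", "low", "moderate", "high", "moderate", "high"),
               levels = c("low", "moderate", "high"))
  fit <- fit_proportional_odds(y, z)
  null <- fit_proportional_odds(y, NULL)
  expect_equal(mcfadden_r2(fit, null), 1 - fit$loglik / null$loglik)
  expect_equal(mcfadden_r2(null, null), 0)
  expect_gt(mcfadden_r2(fit, null), 0)
  expect_equal(mcfadden_r2(fit, y = y), mcfadden_r2(fit, null))
})

test_that("ordinal dredge enumerates 386 candidates for p = 10, max 4", {
  set.seed(61)
  n <- 60
  preds <- as.data.frame(matrix(rnorm(n * 10), ncol = 10))
  y <- draw_ordinal(as.matrix(preds[, 1, drop = FALSE]), C = c(-1, 1), B = 1.2)
  ms <- dredge_ordinal(y, preds, max_predictors = 4)
  expect_equal(nrow(ms$table) + length(ms$skipped), 386)
  expect_equal(sum(ms$table$weight), 1, tolerance = 1e-10)
  expect_equal(ms$table$delta_AICc[1], 0)
  expect_true(all(ms$table$mcfadden >= 0 | ms$table$n_terms == 0))
  expect_true("V1" %in% strsplit(ms$table$model[1], " \\+ ")[[1]])
})

test_that("scenario probabilities: closed form at zero slopes, monotone in levers", {
  # a null model with C at logit(0.25), logit(0.75) gives (0.25, 0.5, 0.25)
  fit0 <- structure(list(C = qlogis(c(0.25, 0.75)), B = c(x = 0),
                         levels = c("low", "moderate", "high")),
                    class = "ordinal_fit")
  sp0 <- scenario_probabilities(
    fit0, list(s1 = c(x = 10), s2 = c(x = 99)),
    center = c(x = 50), scale = c(x = 10))
  expect_equal(unname(sp0$probabilities["s1", ]), c(0.25, 0.5, 0.25),
               tolerance = 1e-12)
  expect_equal(fold_change(sp0, "high", "s1", "s2"), 1)
  # positive slope: raising the lever raises P(high), lowers P(low)
  fit1 <- structure(list(C = c(-1, 1), B = c(x = 1.2),
                         levels = c("low", "moderate", "high")),
                    class = "ordinal_fit")
  levers <- seq(10, 90, by = 20)
  sp1 <- scenario_probabilities(
    fit1, setNames(lapply(levers, function(v) c(x = v)), paste0("L", levers)),
    center = c(x = 50), scale = c(x = 20))
  expect_true(all(diff(sp1$probabilities[, "high"]) > 0))
  expect_true(all(diff(sp1$probabilities[, "low"]) < 0))
  expect_true(all(abs(rowSums(sp1$probabilities) - 1) < 1e-12))
  # transform chain applied to raw lever values
  fit2 <- structure(list(C = c(-1, 1), B = c(w = -1),
                         levels = c("low", "moderate", "high")),
                    class = "ordinal_fit")
  sp2 <- scenario_probabilities(fit2, list(a = c(w = 100)),
                                center = c(w = 10), scale = c(w = 5),
                                transforms = c(w = "sqrt"))
  expect_equal(unname(sp2$z[1, 1]), (sqrt(100) - 10) / 5)
  expect_error(scenario_probabilities(fit2, list(a = c(w = -4)),
                                      center = c(w = 10), scale = c(w = 5),
                                      transforms = c(w = "sqrt")), "domain")
  expect_error(scenario_probabilities(fit2, list(a = c(nope = 1)),
                                      center = c(w = 10), scale = c(w = 5)),
               "not in the fitted model")
})

test_that("percentile ranks follow the package-wide convention", {
  expect_equal(percentile_of(1, 1:5), 0)
  expect_equal(percentile_of(3, 1:5), 50)
  expect_equal(percentile_of(5, 1:5), 100)
  x <- 1:100
  expect_equal(percentile_of(42, x), (42 - 1) / 99 * 100)
  # interpolation between order statistics
  expect_equal(percentile_of(2.5, c(1, 2, 3, 4)), (1.5 / 3) * 100)
  # clamping
  expect_equal(percentile_of(-10, 1:5), 0)
  expect_equal(percentile_of(99, 1:5), 100)
  expect_error(percentile_of(1, numeric()), "empty")
})

test_that("Wald coverage of the slope approaches nominal as n grows", {
  set.seed(67)
  cover <- replicate(80, {
    n <- 400
    z <- matrix(rnorm(n), dimnames = list(NULL, "z1"))
    y <- draw_ordinal(z, C = c(-1, 1), B = 0.9)
    fit <- fit_proportional_odds(y, z)
    se <- fit$se[["z1"]]
    abs(fit$B[["z1"]] - 0.9) <= 1.96 * se
  })
  expect_lt(abs(mean(cover) - 0.95), 0.06)
})
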