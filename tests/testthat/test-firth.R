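test_that("single-binary-covariate fits equal the half-cell-corrected closed form", {
  cells <- list(c(5, 5, 0, 10),   # zero cell
                c(3, 7, 2, 8),
                c(10, 0, 1, 9),   # zero cell on the exposed row
                c(1, 1, 1, 1),
                c(12, 4, 6, 18))
  for (cl in cells) {
    d <- firth_2x2_data(cl[1], cl[2], cl[3], cl[4])
    fit <- fit_firth(y ~ x, d, ci = "wald", pvalues = "wald")
    expected <- firth_2x2_closed_form(cl[1], cl[2], cl[3], cl[4])
    expect_true(fit$converged)
    expect_equal(unname(fit$coefficients), unname(expected),
                 tolerance = 1e-6)
    # OR is exactly exp(beta)
    expect_identical(fit$or, exp(fit$coefficients))
  }
})

test_that("complete separation yields finite, converged estimates", {
  d <- data.frame(x = c(-3, -2, -1, 1, 2, 3), y = c(0, 0, 0, 1, 1, 1))
  fit <- fit_firth(y ~ x, d)
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(all(is.finite(fit$ci)))
})

test_that("penalized likelihood at the optimum dominates the null point", {
  set.seed(51)
  for (i in 1:5) {
    x <- rnorm(60)
    y <- rbinom(60, 1, plogis(0.5 * x))
    fit <- fit_firth(y ~ x, data.frame(x = x, y = y), ci = "wald",
                     pvalues = "wald")
    null_pll <- sbpmi:::firth_engine(fit$X, fit$y, free = integer(0))$pll
    expect_gte(fit$pll, null_pll)
  }
})

test_that("estimates are consistent and scale-equivariant", {
  set.seed(52)
  n <- 100000
  x <- rnorm(n)
  y <- rbinom(n, 1, 0.3)  # outcome independent of x
  fit <- fit_firth(y ~ x, data.frame(x = x, y = y), ci = "wald",
                   pvalues = "wald")
  expect_lt(abs(fit$coefficients["x"]), 0.03)

  set.seed(53)
  d <- data.frame(x = rnorm(300))
  d$y <- rbinom(300, 1, plogis(-1 + d$x))
  f1 <- fit_firth(y ~ x, d, ci = "wald", pvalues = "plr")
  d2 <- transform(d, x = x / 10)
  f2 <- fit_firth(y ~ x, d2, ci = "wald", pvalues = "plr")
  expect_equal(unname(f2$coefficients["x"]),
               unname(10 * f1$coefficients["x"]), tolerance = 1e-6)
  expect_equal(unname(f2$p["x"]), unname(f1$p["x"]), tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  d <- data.frame(x = rnorm(30))
  d$z <- 2 * d$x
  d$y <- rbinom(30, 1, 0.5)
  expect_error(fit_firth(y ~ x + z, d), "z")
})

test_that("profile intervals bracket the estimate and approach Wald at large n", {
  set.seed(54)
  n <- 4000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
  fit <- fit_firth(y ~ x, data.frame(x = x, y = y))
  expect_true(all(fit$ci[, 1] < fit$coefficients))
  expect_true(all(fit$ci[, 2] > fit$coefficients))
  wald <- sbpmi:::wald_ci(fit)
  rel_width <- abs((fit$ci[, 2] - fit$ci[, 1]) - (wald[, 2] - wald[, 1])) /
    (wald[, 2] - wald[, 1])
  expect_true(all(rel_width < 0.05))
})

test_that("profile intervals achieve near-nominal coverage at moderate n", {
  set.seed(55)
  beta_true <- 1
  covered <- replicate(400, {
    x <- rnorm(150)
    y <- rbinom(150, 1, plogis(-1 + beta_true * x))
    fit <- fit_firth(y ~ x, data.frame(x = x, y = y), ci = "wald",
                     pvalues = "wald")
    ci <- profile_ci(fit)["x", ]
    ci[1] <= beta_true && beta_true <= ci[2]
  })
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("univariable screening keeps candidates below the threshold in order", {
  set.seed(56)
  n <- 200
  d <- data.frame(strong = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-1 + 1.5 * d$strong))
  scr <- univariable_screen(d, "y", c("noise1", "strong", "noise2"),
                            threshold = 0.10)
  expect_true("strong" %in% scr$selected)
  expect_identical(scr$table$candidate, c("noise1", "strong", "noise2"))

  none <- univariable_screen(d, "y", c("strong"), threshold = 0)
  expect_length(none$selected, 0)
  all_in <- univariable_screen(d, "y", c("noise1", "strong"), threshold = 1)
  expect_identical(all_in$selected, c("noise1", "strong"))
})

test_that("the published screening rule selects exactly ten predictors", {
  tab <- published_univariable_table()
  sel <- screen_by_pvalue(tab, threshold = 0.10)
  expect_length(sel, 10)
  expect_identical(sel[1], "SBP-MI")
  expect_identical(sel[10], "Age")
  expect_false("TBil" %in% sel)
})

test_that("predicted probabilities honour the logistic link", {
  set.seed(57)
  d <- data.frame(x = rnorm(100))
  d$y <- rbinom(100, 1, 0.4)
  fit <- fit_firth(y ~ x, d, ci = "wald", pvalues = "wald")

  zero_fit <- fit
  zero_fit$coefficients[] <- 0
  expect_true(all(predict_probability(zero_fit, d) == 0.5))

  # monotone approach to 1 along the positive-coefficient direction
  mono_fit <- fit
  mono_fit$coefficients[] <- c(0, 1)
  p_seq <- predict_probability(mono_fit, data.frame(x = c(1, 5, 20, 100)))
  expect_false(is.unsorted(p_seq))
  expect_gt(p_seq[4], 0.999)

  expect_error(predict_probability(fit, data.frame(w = 1)), "x")
})

test_that("fitted models are self-calibrated across risk deciles", {
  set.seed(58)
  n <- 5000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1.5 + x))
  fit <- fit_firth(y ~ x, data.frame(x = x, y = y), ci = "wald",
                   pvalues = "wald")
  p <- predict_probability(fit, data.frame(x = x))
  dec <- cut(p, quantile(p, seq(0, 1, 0.1)), include.lowest = TRUE)
  for (lev in levels(dec)) {
    idx <- dec == lev
    se3 <- 3 * sqrt(mean(p[idx]) * (1 - mean(p[idx])) / sum(idx))
    expect_lt(abs(mean(y[idx]) - mean(p[idx])), se3 + 1e-12)
  }
})
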