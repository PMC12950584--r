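test_that("ROC handles perfect, null, and degenerate scores", {
  r <- roc_analysis(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), ci = "none")
  expect_equal(r$auc, 1)
  expect_equal(r$cutoff, 0.8)  # smallest threshold achieving J = 1
  expect_equal(r$sensitivity_at_cutoff, 1)
  expect_equal(r$specificity_at_cutoff, 1)

  set.seed(61)
  r0 <- roc_analysis(rnorm(2000), rbinom(2000, 1, 0.5))
  expect_lt(abs(r0$auc - 0.5), 0.04)

  rid <- roc_analysis(rep(1, 10), rep(c(0, 1), 5), ci = "none")
  expect_equal(rid$youden, 0)

  expect_error(roc_analysis(1:5, rep(1, 5)), "both outcome classes")
})

test_that("AUC equals the exhaustive pairwise Mann-Whitney count", {
  set.seed(62)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    scores <- round(rnorm(n), 1)  # coarse rounding forces ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    r <- roc_analysis(scores, y, ci = "none")
    pos <- scores[y == 1]; neg <- scores[y == 0]
    u <- 0
    for (a in pos) for (b in neg) u <- u + (a > b) + 0.5 * (a == b)
    expect_equal(r$auc, u / (length(pos) * length(neg)), tolerance = 1e-12)
    # complement symmetry under tie-corrected computation
    expect_equal(roc_analysis(-scores, y, ci = "none")$auc, 1 - r$auc,
                 tolerance = 1e-12)
    # curve monotone: sensitivity non-increasing along increasing thresholds
    expect_false(is.unsorted(rev(r$sensitivity)))
  }
})

test_that("DeLong intervals agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(63)
  scores <- rnorm(150)
  y <- rbinom(150, 1, plogis(scores))
  r <- roc_analysis(scores, y)
  ref <- pROC::roc(y, scores, quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(r$auc_ci, as.numeric(pROC::ci.auc(ref))[c(1, 3)],
               tolerance = 1e-9)
})

test_that("Youden cutoff matches brute-force enumeration", {
  set.seed(64)
  for (i in 1:15) {
    n <- sample(8:30, 1)
    scores <- round(runif(n), 2)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    r <- roc_analysis(scores, y, ci = "none")
    pos <- scores[y == 1]; neg <- scores[y == 0]
    j_brute <- max(vapply(unique(scores), function(t) {
      mean(pos >= t) + mean(neg < t) - 1
    }, numeric(1)))
    expect_equal(r$youden, j_brute, tolerance = 1e-12)
  }
})

test_that("calibration is self-consistent when outcomes follow the predictions", {
  set.seed(65)
  p <- plogis(rnorm(100000, -1, 1.2))
  y <- rbinom(length(p), 1, p)
  cal <- calibration(p, y)
  expect_lt(abs(cal$slope - 1), 0.05)
  expect_lt(abs(cal$intercept), 0.05)
  expect_equal(cal$hl$df, 8)
  expect_equal(sum(cal$deciles$n), length(p))

  # closed forms
  expect_equal(calibration(rep(0.5, 40), rep(c(0, 1), 20))$brier, 0.25)
  expect_warning(cal01 <- calibration(rep(c(0, 1), 20), rep(c(0, 1), 20)),
                 "clamped")
  expect_lt(cal01$brier, 1e-12)
})

test_that("the HL statistic ignores within-group ordering", {
  set.seed(66)
  p <- plogis(rnorm(500, -0.5))
  y <- rbinom(500, 1, p)
  h1 <- calibration(p, y)$hl$statistic
  o <- order(p)  # grouping depends only on p-deciles, so permute jointly
  perm <- sample(500)
  h2 <- calibration(p[perm], y[perm])$hl$statistic
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("HL type-I error is near nominal for a correctly specified model", {
  # the groups - 2 reference assumes the probabilities were estimated (two
  # fitted parameters), so the null simulation refits before testing
  set.seed(67)
  rej <- mean(replicate(300, {
    x <- rnorm(1000)
    y <- rbinom(1000, 1, plogis(-1 + x))
    p <- fitted(glm(y ~ x, family = binomial()))
    calibration(p, y)$hl$p < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("bootstrap optimism is zero for a data-independent score", {
  set.seed(68)
  d <- data.frame(x = rnorm(80))
  d$y <- rbinom(80, 1, plogis(d$x))
  recipe <- list(fit = function(data) "constant",
                 predict = function(object, data) rep(0.42, nrow(data)),
                 outcome = "y", label = "constant score")
  rep1 <- bootstrap_optimism(d, recipe, resamples = 50, seed = 2025)
  expect_true(all(rep1$optimism == 0))  # AUC 0.5 everywhere under ties
  expect_equal(rep1$corrected, rep1$apparent)
  rep2 <- bootstrap_optimism(d, recipe, resamples = 50, seed = 2025)
  expect_identical(rep1, rep2)  # bit-reproducible under a fixed seed
  expect_equal(rep1$resamples, 50)
})

test_that("overfit models show substantial positive optimism", {
  set.seed(69)
  n <- 100
  d <- as.data.frame(matrix(rnorm(n * 15), ncol = 15))
  names(d) <- paste0("z", 1:15)
  d$y <- rbinom(n, 1, 0.3)  # pure noise model
  recipe <- firth_recipe(stats::reformulate(paste0("z", 1:15), "y"))
  rep <- bootstrap_optimism(d, recipe, resamples = 100, seed = 2025)
  expect_gt(rep$mean_optimism, 0.02)
  expect_equal(rep$corrected, rep$apparent - rep$mean_optimism)
})

test_that("delta comparison separates arms as constructed", {
  set.seed(70)
  same <- data.frame(delta = rnorm(60),
                     arm = rep(c("improved", "progression"), 30))
  cd <- compare_deltas(same)
  expect_lt(abs(cd$roc$auc - 0.5), 0.2)

  apart <- data.frame(delta = c(rnorm(30, -3), rnorm(10, 3)),
                      arm = rep(c("improved", "progression"), c(30, 10)))
  cd2 <- compare_deltas(apart)
  expect_equal(cd2$roc$auc, 1)
  expect_lt(cd2$wilcoxon$p, 0.001)

  # drift acting only on genera exclusive to SBP-MI (absent from the HBCDI
  # formula): delta-SBP-MI must dominate delta-HBCDI
  cfg <- default_cohort_config(seed = 2025)
  def <- sbpmi_definition()
  hb <- hbcdi_definition()
  only_mi <- setdiff(c(def$numerator, def$denominator),
                     c(hb$numerator, hb$denominator))
  num_only <- intersect(only_mi, def$numerator)  # Klebsiella, Veillonella
  cfg$drift <- list(
    improved = setNames(rep(0.4, length(num_only)), num_only),
    progression = setNames(rep(2.5, length(num_only)), num_only))
  pf <- generate_paired_followup(cfg)
  d_mi <- paired_deltas(pf, def)
  d_hb <- paired_deltas(pf, hbcdi_definition())
  auc_mi <- compare_deltas(d_mi)$roc$auc
  auc_hb <- compare_deltas(d_hb)$roc$auc
  expect_gt(auc_mi, auc_hb)
})
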