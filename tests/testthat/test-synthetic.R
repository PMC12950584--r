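test_that("Dirichlet draws honour symmetry and concentration limits", {
  panel <- c("A", "B", "C", "D", "Remainder")[1:4]
  alpha <- matrix(1, nrow = 1, ncol = 4,
                  dimnames = list("G", panel))
  cfg <- cohort_config(group_sizes = c(G = 10000), genus_panel = panel,
                       dirichlet_params = alpha,
                       clinical_model = list(G = list(inr = c(1, 0),
                                                      meld = c(7, 0),
                                                      history = 0)),
                       seed = 11)
  ab <- generate_compositions(cfg)
  expect_true(all(abs(colMeans(ab) - 0.25) < 0.01))
  expect_lt(max(abs(rowSums(ab) - 1)), 1e-9)

  spike <- matrix(c(1e6, 1e-3, 1e-3, 1e-3), nrow = 1,
                  dimnames = list("G", panel))
  cfg2 <- cohort_config(group_sizes = c(G = 200), genus_panel = panel,
                        dirichlet_params = spike,
                        clinical_model = list(G = list(inr = c(1, 0),
                                                       meld = c(7, 0),
                                                       history = 0)),
                        seed = 12)
  ab2 <- generate_compositions(cfg2)
  expect_true(all(ab2[, "A"] > 0.99))
})

test_that("non-positive concentrations are rejected naming genus and group", {
  panel <- c("A", "B")
  alpha <- matrix(c(1, 0), nrow = 1, dimnames = list("G", panel))
  expect_error(cohort_config(group_sizes = c(G = 5), genus_panel = panel,
                             dirichlet_params = alpha,
                             clinical_model = list()),
               "genus 'B' in group 'G'")
})

test_that("default staged cohort orders index genera along the disease axis", {
  cfg <- default_cohort_config(seed = 2025)
  stage <- c("HC", "CC", "NSBP", "SBP")
  def <- sbpmi_definition()

  # configured Dirichlet means are strictly directional per genus
  dp <- cfg$dirichlet_params[stage, ]
  mu <- dp / rowSums(dp)
  for (g in def$numerator) expect_false(is.unsorted(mu[, g]))
  for (g in def$denominator) expect_false(is.unsorted(rev(mu[, g])))

  # and empirical means follow at large per-group n
  big <- cohort_config(group_sizes = c(HC = 3000, CC = 3000, NSBP = 3000,
                                       SBP = 3000), seed = 2025)
  ab_big <- generate_compositions(big)
  gr_big <- attr(ab_big, "groups")
  for (g in c(def$numerator, def$denominator)) {
    m <- vapply(stage, function(s) mean(ab_big[gr_big == s, g]), numeric(1))
    if (g %in% def$numerator) expect_false(is.unsorted(m))
    else expect_false(is.unsorted(rev(m)))
  }

  # at the study's group sizes the index itself separates the extremes
  ab <- generate_compositions(cfg)
  groups <- attr(ab, "groups")
  scores <- compute_index(ab, def)
  expect_gt(mean(scores$score[groups == "SBP"]),
            mean(scores$score[groups == "HC"]))
})

test_that("fixed seed reproduces the cohort exactly; stages use independent streams", {
  cfg <- default_cohort_config(seed = 77)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)

  # regenerating clinical covariates must not perturb compositions
  ab <- generate_compositions(cfg)
  md1 <- generate_clinical(cfg, ab)$metadata
  ab2 <- generate_compositions(cfg)
  expect_identical(unclass(ab), unclass(ab2))
  expect_identical(md1, generate_clinical(cfg, ab)$metadata)
})

test_that("clinical covariates follow the configured group models", {
  cfg <- single_group_config(n = 10000, inr = c(1.6, 0), meld = c(12, 3),
                             history = 0.2, seed = 5)
  co <- generate_clinical(cfg, generate_compositions(cfg))
  expect_true(all(co$metadata$inr == 1.6))          # degenerate normal
  expect_true(all(co$metadata$meld >= 6))           # physiologic floor
  expect_lt(abs(mean(co$metadata$history) - 0.2), 0.01)

  cfg0 <- single_group_config(n = 500, inr = c(1.6, 0.2), meld = c(12, 3),
                              history = 0, seed = 6)
  co0 <- generate_clinical(cfg0, generate_compositions(cfg0))
  expect_true(all(co0$metadata$history == 0))
  expect_true(all(co0$metadata$inr >= 0.8))

  bad <- single_group_config(n = 5, inr = c(1.6, -1), meld = c(12, 3),
                             history = 0, seed = 7)
  expect_error(generate_clinical(bad, generate_compositions(bad)),
               "negative SD")
})

test_that("outcome simulation follows the supplied coefficients", {
  cfg <- prospective_cohort_config(n = 400, seed = 9)
  base <- generate_clinical(cfg, generate_compositions(cfg))

  zero <- simulate_outcomes(base, risk_equation(0, c(sbp_mi = 0, inr = 0,
                                                     history = 0)))
  expect_true(all(zero$metadata$true_prob == 0.5))

  none <- simulate_outcomes(base, risk_equation(-50, c(sbp_mi = 0, inr = 0,
                                                       history = 0)))
  expect_true(all(none$metadata$outcome == 0))

  eq <- sbp_rp_equation()
  expect_equal(risk_probability(eq, data.frame(sbp_mi = 0, inr = 0,
                                               history = 0)),
               plogis(-6.8107))

  broken <- base
  broken$metadata$inr <- NULL
  expect_error(simulate_outcomes(broken, eq), "inr")
})

test_that("observed outcome frequency converges to the mean true probability", {
  cfg <- prospective_cohort_config(n = 100000, seed = 13)
  co <- simulate_cohort(cfg)
  p_bar <- mean(co$metadata$true_prob)
  sd3 <- 3 * sqrt(sum(co$metadata$true_prob * (1 - co$metadata$true_prob))) /
    nrow(co$metadata)
  expect_lt(abs(mean(co$metadata$outcome) - p_bar), sd3)
})

test_that("paired follow-up applies arm drift with exact arm counts", {
  cfg <- default_cohort_config(seed = 2025)
  pf <- generate_paired_followup(cfg)
  counts <- table(pf$metadata$arm)
  expect_equal(as.integer(counts[c("improved", "progression")]),
               c(64L, 16L))  # two samples per subject
  expect_equal(sum(pf$metadata$timepoint == "baseline"), 40)
  expect_lt(max(abs(rowSums(pf$abundance) - 1)), 1e-9)

  # identity drift: follow-up equals baseline, all deltas zero
  cfg_id <- default_cohort_config(seed = 2025)
  cfg_id$drift <- list(improved = c(Klebsiella = 1),
                       progression = c(Klebsiella = 1))
  pf_id <- generate_paired_followup(cfg_id)
  d_id <- paired_deltas(pf_id, sbpmi_definition())
  expect_true(all(abs(d_id$delta) < 1e-12))

  # halving every numerator genus forces the index down for every subject
  def <- sbpmi_definition()
  cfg_dn <- default_cohort_config(seed = 2025)
  half <- setNames(rep(0.5, length(def$numerator)), def$numerator)
  cfg_dn$drift <- list(improved = half, progression = half)
  d_dn <- paired_deltas(generate_paired_followup(cfg_dn), def)
  expect_true(all(d_dn$delta < 0))

  # default drifts separate the arms in the expected direction
  d <- paired_deltas(pf, def)
  expect_lt(median(d$delta[d$arm == "improved"]), 0)
  expect_gt(median(d$delta[d$arm == "progression"]), 0)
  expect_gt(median(d$delta[d$arm == "progression"]),
            median(d$delta[d$arm == "improved"]))

  bad <- default_cohort_config(seed = 1)
  bad$drift$improved["Klebsiella"] <- -1
  expect_error(generate_paired_followup(bad), "drift factors")
  expect_error(cohort_config(group_sizes = c(HC = 2),
                             drift = list(improved = c(Klebsiella = 0))),
               "drift factors")
})

test_that("cohorts serialize to plain-text files and read back", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(prospective_cohort_config(n = 30, seed = 3))
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("abundance.tsv",
                                               "metadata.csv",
                                               "config.json")))))
  back <- read_abundance(file.path(dir, "abundance.tsv"))
  expect_lt(max(abs(unclass(back) - unclass(co$abundance))), 1e-12)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(cfg$seed, 3)
})
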