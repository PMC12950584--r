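#' Modeling recipes for internal validation
#'
#' A recipe bundles the full, reproducible model-building procedure so the
#' bootstrap can re-run it inside every resample: `fit(data)` returns a
#' fitted object and `predict(object, data)` returns risk scores.
#' `firth_recipe()` fits a fixed formula; `screened_firth_recipe()` re-runs
#' univariable Firth screening at the given p threshold and then the
#' multivariable Firth fit inside each call, which is the honest (Harrell)
#' way to validate a model whose variables were selected from the data.
#' If screening selects nothing, the recipe falls back to an
#' intercept-only constant score.
#'
#' Wald intervals/p-values are used inside recipes purely for speed; the
#' discrimination metric does not depend on them (screening still uses
#' penalized likelihood-ratio p-values).
#'
#' @param formula model formula for the fixed-formula recipe.
#' @param outcome,candidates,threshold screening specification.
#' @return a list with elements `fit`, `predict`, `outcome`, `label`.
#' @export
firth_recipe <- function(formula) {
  list(fit = function(data) fit_firth(formula, data, ci = "wald",
                                      pvalues = "wald"),
       predict = function(object, data) predict_probability(object, data),
       outcome = all.vars(formula)[1],
       label = paste(deparse(formula), collapse = " "))
}

#' @rdname firth_recipe
#' @export
screened_firth_recipe <- function(outcome, candidates, threshold = 0.10) {
  list(
    fit = function(data) {
      scr <- univariable_screen(data, outcome, candidates,
                                threshold = threshold, ci = "wald",
                                pvalues = "plr")
      if (!length(scr$selected)) {
        return(structure(list(rate = mean(data[[outcome]]),
                              selected = character()),
                         class = "constant_model"))
      }
      fit <- fit_firth(stats::reformulate(sprintf("`%s`", scr$selected),
                                          response = outcome),
                       data, ci = "wald", pvalues = "wald")
      fit$selected <- scr$selected
      fit
    },
    predict = function(object, data) {
      if (inherits(object, "constant_model")) {
        return(rep(object$rate, nrow(data)))
      }
      predict_probability(object, data)
    },
    outcome = outcome,
    label = sprintf("screen(p<%g) + multivariable Firth", threshold))
}

#' Bootstrap optimism correction of the AUC (Harrell)
#'
#' For each bootstrap resample of the data, the full recipe is refit on
#' the resample; optimism is the mean difference between the resample
#' ("boot-apparent") AUC and the AUC of the resample-fitted model on the
#' original data ("boot-test").  The corrected AUC is the apparent AUC
#' minus the mean optimism (exactly).  A resample containing only one
#' outcome class is redrawn and counted.  Fixing `seed` makes the whole
#' procedure bit-reproducible.
#'
#' @param data data frame.
#' @param recipe a [firth_recipe()] / [screened_firth_recipe()] list.
#' @param resamples number of bootstrap resamples; default 500.
#' @param seed integer RNG seed; default 2025.
#' @return an object of class `optimism_report`: list with `apparent`,
#'   `optimism` (per-resample vector), `mean_optimism`, `corrected`,
#'   `resamples`, `redrawn`, `seed`.
#' @export
bootstrap_optimism <- function(data, recipe, resamples = 500, seed = 2025) {
  stopifnot(is.data.frame(data), is.function(recipe$fit),
            is.function(recipe$predict))
  y <- coerce_binary_outcome(data[[recipe$outcome]])
  n <- nrow(data)

  apparent_model <- recipe$fit(data)
  apparent_scores <- recipe$predict(apparent_model, data)
  apparent <- roc_analysis(apparent_scores, y, ci = "none")$auc

  set.seed(seed)
  optimism <- numeric(resamples)
  redrawn <- 0L
  for (b in seq_len(resamples)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- y[idx]
      if (any(yb == 1) && any(yb == 0)) break
      redrawn <- redrawn + 1L
    }
    db <- data[idx, , drop = FALSE]
    mb <- recipe$fit(db)
    boot_apparent <- roc_analysis(recipe$predict(mb, db), yb, ci = "none")$auc
    boot_test <- roc_analysis(recipe$predict(mb, data), y, ci = "none")$auc
    optimism[b] <- boot_apparent - boot_test
  }
  mean_opt <- mean(optimism)
  structure(list(apparent = apparent, optimism = optimism,
                 mean_optimism = mean_opt, corrected = apparent - mean_opt,
                 resamples = resamples, redrawn = redrawn, seed = seed,
                 recipe_label = recipe$label %||% "recipe"),
            class = "optimism_report")
}

#' @export
print.optimism_report <- function(x, ...) {
  cat(sprintf("bootstrap optimism (%d resamples, seed %d): apparent AUC %.3f, mean optimism %.4f, corrected AUC %.3f\n",
              x$resamples, x$seed, x$apparent, x$mean_optimism, x$corrected))
  if (x$redrawn > 0) cat(sprintf("  %d single-class resample(s) redrawn\n",
                                 x$redrawn))
  invisible(x)
}
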