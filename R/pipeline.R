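#' Run the full SBP risk-modelling pipeline
#'
#' Orchestrates every stage on one cohort: taxon resolution and
#' normalization, SBP-MI and HBCDI computation, univariable Firth screening
#' at the configured p threshold, the multivariable Firth fit on the
#' selected covariates, ROC analysis with the Youden cutoff, calibration
#' diagnostics, Harrell bootstrap optimism correction of the AUC (re-running
#' screening inside every resample), and the nomogram points table.  The
#' report contains only plain values (no closures), echoes the
#' configuration and seed, and is byte-identical across runs with the same
#' inputs.
#'
#' @param cohort a `synthetic_cohort` with outcomes (see
#'   [simulate_cohort()]), or `NULL` to simulate one from `config`.
#' @param config a [cohort_config()] used when `cohort` is `NULL`; default
#'   [prospective_cohort_config()].
#' @param candidates covariate columns screened univariably; default
#'   `c("sbp_mi", "hbcdi", "inr", "meld", "history")`.
#' @param screen_p univariable screening threshold; default 0.10.
#' @param resamples bootstrap resamples for optimism correction; default
#'   200.
#' @param nomogram_ranges passed to [build_nomogram()] for the refitted
#'   equation (only covariates retained in the model are used).
#' @param out optional path; when given the report is also written as JSON.
#' @return an object of class `sbp_pipeline_report` (a named list).
#' @export
run_pipeline <- function(cohort = NULL, config = prospective_cohort_config(),
                         candidates = c("sbp_mi", "hbcdi", "inr", "meld",
                                        "history"),
                         screen_p = 0.10, resamples = 200,
                         nomogram_ranges = NULL, out = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  config <- cohort$config
  md <- cohort$metadata
  if (!"outcome" %in% names(md)) {
    stop("pipeline stage 'outcomes': cohort has no outcome column",
         call. = FALSE)
  }
  candidates <- intersect(candidates, names(md))

  # indices are recomputed from the abundance table after resolution so
  # pipeline results never depend on cached metadata columns
  ab <- resolve_taxa(normalize_abundance(cohort$abundance),
                     policy = "sum_sublineages")
  md$sbp_mi <- compute_index(ab, sbpmi_definition())$score
  md$hbcdi <- compute_index(ab, hbcdi_definition())$score

  screen <- univariable_screen(md, "outcome", candidates,
                               threshold = screen_p)
  report_screen <- screen$table

  if (!length(screen$selected)) {
    report <- list(config = list(seed = config$seed,
                                 groups = as.list(config$group_sizes)),
                   n = nrow(md), events = sum(md$outcome),
                   screen = report_screen,
                   model = "empty (no candidate passed the screen)")
    class(report) <- c("sbp_pipeline_report", "list")
    return(report)
  }

  fit <- fit_firth(stats::reformulate(sprintf("`%s`", screen$selected),
                                      response = "outcome"), md)
  prob <- predict_probability(fit, md)
  roc <- roc_analysis(prob, md$outcome)
  cal <- calibration(prob, md$outcome)

  recipe <- screened_firth_recipe("outcome", candidates,
                                  threshold = screen_p)
  opt <- bootstrap_optimism(md, recipe, resamples = resamples,
                            seed = child_seed(config$seed, "bootstrap"))

  refit_eq <- risk_equation(
    intercept = unname(fit$coefficients[1]),
    coefficients = stats::setNames(unname(fit$coefficients[-1]),
                                   screen$selected),
    provenance = sprintf("refit on cohort seed %d", config$seed))
  ranges <- nomogram_ranges
  if (is.null(ranges)) {
    ranges <- lapply(screen$selected, function(v) {
      if (all(md[[v]] %in% c(0, 1))) c(0, 1) else range(md[[v]])
    })
    names(ranges) <- screen$selected
  }
  nomo <- build_nomogram(refit_eq, ranges = ranges)

  report <- list(
    config = list(seed = config$seed, groups = as.list(config$group_sizes),
                  screen_p = screen_p, resamples = resamples),
    n = nrow(md), events = sum(md$outcome),
    indices = list(
      sbp_mi = summary_stats(md$sbp_mi),
      hbcdi = summary_stats(md$hbcdi)),
    screen = report_screen,
    selected = screen$selected,
    model = list(coefficients = as.list(fit$coefficients),
                 se = as.list(fit$se),
                 or = as.list(fit$or),
                 ci_lower = as.list(fit$ci[, 1]),
                 ci_upper = as.list(fit$ci[, 2]),
                 p = as.list(fit$p),
                 converged = fit$converged, iterations = fit$iter),
    roc = list(auc = roc$auc, auc_ci = roc$auc_ci, cutoff = roc$cutoff,
               sensitivity = roc$sensitivity_at_cutoff,
               specificity = roc$specificity_at_cutoff),
    calibration = list(slope = cal$slope, intercept = cal$intercept,
                       brier = cal$brier, hl_statistic = cal$hl$statistic,
                       hl_df = cal$hl$df, hl_p = cal$hl$p),
    optimism = list(apparent = opt$apparent,
                    mean_optimism = opt$mean_optimism,
                    corrected = opt$corrected, resamples = opt$resamples,
                    redrawn = opt$redrawn, seed = opt$seed),
    nomogram = list(axes = nomo$axes, points_per_unit = nomo$points_per_unit),
    taxon_resolution = attr(ab, "resolution")$mappings)
  class(report) <- c("sbp_pipeline_report", "list")
  if (!is.null(out)) {
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, force = TRUE)
  }
  report
}

summary_stats <- function(x) {
  list(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
       median = stats::median(x, na.rm = TRUE))
}

#' @export
print.sbp_pipeline_report <- function(x, ...) {
  cat(sprintf("SBP risk pipeline: n = %d, events = %d\n", x$n, x$events))
  if (is.character(x$model)) {
    cat("  ", x$model, "\n")
    return(invisible(x))
  }
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("  AUC %.3f (cutoff %.3f: sens %.3f, spec %.3f)\n",
              x$roc$auc, x$roc$cutoff, x$roc$sensitivity,
              x$roc$specificity))
  cat(sprintf("  calibration slope %.3f, Brier %.4f, HL P %.3f\n",
              x$calibration$slope, x$calibration$brier, x$calibration$hl_p))
  cat(sprintf("  optimism-corrected AUC %.3f (%d resamples)\n",
              x$optimism$corrected, x$optimism$resamples))
  invisible(x)
}
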