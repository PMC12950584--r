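#' Calibration diagnostics for predicted probabilities
#'
#' Reports (i) the calibration slope and intercept from a logistic
#' recalibration of the outcomes on the logit of the predicted
#' probabilities (slope 1 and intercept 0 indicate neither over- nor
#' under-fitting), (ii) the Brier score (mean squared difference between
#' prediction and outcome), and (iii) the Hosmer-Lemeshow goodness-of-fit
#' statistic over risk-decile groups,
#' \eqn{\sum_g (O_g - E_g)^2 / (E_g (1 - E_g/n_g))}, referred to a
#' chi-squared distribution on groups - 2 df.  With fewer distinct risk
#' values than groups, grouping collapses to the unique values (df =
#' groups - 2, minimum 1).
#'
#' @param predicted probability vector; values of exactly 0 or 1 are
#'   clamped to `[1e-12, 1 - 1e-12]` with a warning.
#' @param outcomes binary outcome vector.
#' @param groups number of risk groups; default 10.
#' @return an object of class `calibration_report`: list with `slope`,
#'   `intercept`, `brier`, `hl` (list: `statistic`, `df`, `p`), and
#'   `deciles` (data frame of per-group n, observed and expected events).
#' @export
calibration <- function(predicted, outcomes, groups = 10) {
  predicted <- as.numeric(predicted)
  y <- coerce_binary_outcome(outcomes)
  stopifnot(length(predicted) == length(y))
  n <- length(y)
  if (n < 2 * groups) {
    stop("need at least 2 x groups observations", call. = FALSE)
  }
  if (any(predicted <= 0 | predicted >= 1)) {
    warning("predicted probabilities clamped to (0, 1)", call. = FALSE)
    predicted <- pmin(1 - 1e-12, pmax(1e-12, predicted))
  }
  lp <- stats::qlogis(predicted)

  recal <- if (stats::sd(lp) == 0) {
    list(slope = NA_real_, intercept = NA_real_)
  } else {
    g <- suppressWarnings(stats::glm(y ~ lp, family = stats::binomial()))
    list(slope = unname(stats::coef(g)[2]), intercept = unname(stats::coef(g)[1]))
  }

  brier <- mean((predicted - y)^2)

  # risk-decile grouping; collapse to unique values when too few distinct
  qs <- stats::quantile(predicted, probs = seq(0, 1, length.out = groups + 1),
                        type = 7)
  breaks <- unique(qs)
  if (length(breaks) < 3) {
    grp <- factor(predicted)
  } else {
    grp <- cut(predicted, breaks = breaks, include.lowest = TRUE)
  }
  O <- tapply(y, grp, sum)
  E <- tapply(predicted, grp, sum)
  ng <- tapply(y, grp, length)
  keep <- !is.na(O)
  O <- O[keep]; E <- E[keep]; ng <- ng[keep]
  hl_stat <- sum((O - E)^2 / (E * (1 - E / ng)))
  df <- max(length(O) - 2, 1)
  hl_p <- stats::pchisq(hl_stat, df = df, lower.tail = FALSE)

  structure(list(
    slope = recal$slope, intercept = recal$intercept, brier = brier,
    hl = list(statistic = hl_stat, df = df, p = hl_p),
    deciles = data.frame(group = names(O), n = as.integer(ng),
                         observed = as.numeric(O), expected = as.numeric(E),
                         row.names = NULL, stringsAsFactors = FALSE),
    n = n), class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("calibration slope %.3f, intercept %.3f; Brier %.4f\n",
              x$slope, x$intercept, x$brier))
  cat(sprintf("Hosmer-Lemeshow chi2 = %.3f on %d df, P = %.3f\n",
              x$hl$statistic, x$hl$df, x$hl$p))
  invisible(x)
}
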