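#' Empirical ROC analysis
#'
#' Computes the empirical ROC curve over all observed score values under
#' the fixed classification convention **score >= cutoff => predicted
#' positive**.  The AUC is the tie-corrected Mann-Whitney statistic
#' \eqn{U/(n_1 n_0)} (computed from midranks, identical to the trapezoidal
#' area under the empirical curve); its confidence interval uses DeLong's
#' variance estimate from placement values by default.
#'
#' @param scores numeric score vector (higher = more likely positive).
#' @param outcomes binary outcome vector (0/1, logical, or 2-level factor).
#' @param ci `"delong"` (default) or `"none"`.
#' @param level confidence level; default 0.95.
#' @return an object of class `roc_result`: list with `thresholds`
#'   (sorted increasing), `sensitivity`, `specificity` at each threshold,
#'   `auc`, `auc_ci`, `ci_method`, and the Youden-optimal `cutoff`,
#'   `sensitivity_at_cutoff`, `specificity_at_cutoff`, `youden`.
#' @export
roc_analysis <- function(scores, outcomes, ci = c("delong", "none"),
                         level = 0.95) {
  ci <- match.arg(ci)
  scores <- as.numeric(scores)
  y <- coerce_binary_outcome(outcomes)
  ok <- is.finite(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  thresholds <- sort(unique(scores))
  pos <- scores[y == 1]; neg <- scores[y == 0]
  sens <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(neg < t), numeric(1))

  r <- rank(scores)  # midranks: tie-corrected
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  auc_ci <- c(NA_real_, NA_real_)
  if (ci == "delong") {
    v10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n0,
                  numeric(1))
    v01 <- vapply(neg, function(x) (sum(pos > x) + 0.5 * sum(pos == x)) / n1,
                  numeric(1))
    var_auc <- stats::var(v10) / n1 + stats::var(v01) / n0
    z <- stats::qnorm(1 - (1 - level) / 2)
    auc_ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * sqrt(var_auc)))
  }

  out <- structure(list(thresholds = thresholds, sensitivity = sens,
                        specificity = spec, auc = auc, auc_ci = auc_ci,
                        ci_method = ci, n1 = n1, n0 = n0),
                   class = "roc_result")
  opt <- youden_cutoff(out)
  out$cutoff <- opt$cutoff
  out$sensitivity_at_cutoff <- opt$sensitivity
  out$specificity_at_cutoff <- opt$specificity
  out$youden <- opt$youden
  out
}

coerce_binary_outcome <- function(outcomes) {
  if (is.logical(outcomes)) return(as.numeric(outcomes))
  if (is.factor(outcomes)) {
    if (nlevels(outcomes) != 2) stop("factor outcome must have 2 levels",
                                     call. = FALSE)
    return(as.numeric(outcomes) - 1)
  }
  y <- as.numeric(outcomes)
  stopifnot_binary(y, "outcome")
  y
}

#' Youden-optimal operating cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 over the ROC thresholds,
#' under the score >= cutoff classification convention; ties are broken
#' toward the smallest cutoff value.
#'
#' @param roc a [roc_analysis()] result.
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-12)[1]  # smallest threshold among ties
  list(cutoff = roc$thresholds[best], sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best], youden = j[best])
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f", x$auc))
  if (x$ci_method != "none") {
    cat(sprintf(" (95%% CI %.3f-%.3f, %s)", x$auc_ci[1], x$auc_ci[2],
                x$ci_method))
  }
  cat(sprintf("\ncutoff %.4g (score >= cutoff positive): sensitivity %.3f, specificity %.3f\n",
              x$cutoff, x$sensitivity_at_cutoff, x$specificity_at_cutoff))
  invisible(x)
}

#' Compare paired index changes between outcome arms
#'
#' Two-sided Wilcoxon rank-sum test of the per-subject delta between the
#' two arms, plus the ROC of the delta for predicting the positive arm
#' (by default `"progression"`).
#'
#' @param delta a `delta_result` (see [compute_delta()]) with an `arm`
#'   column, or a data frame with columns `delta` and `arm`.
#' @param positive label of the arm treated as the event; default
#'   `"progression"`.
#' @return list with `wilcoxon` (`W`, `p`) and `roc` (a `roc_result`).
#' @export
compare_deltas <- function(delta, positive = "progression") {
  stopifnot(is.data.frame(delta), all(c("delta", "arm") %in% names(delta)))
  arms <- unique(delta$arm[!is.na(delta$arm)])
  if (length(arms) != 2) stop("need exactly two nonempty arms", call. = FALSE)
  if (!positive %in% arms) stop("positive arm '", positive, "' not present",
                                call. = FALSE)
  a <- delta$delta[delta$arm == positive]
  b <- delta$delta[delta$arm != positive]
  if (!length(a) || !length(b)) stop("empty arm", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
  roc <- roc_analysis(delta$delta, as.numeric(delta$arm == positive))
  list(wilcoxon = list(W = unname(wt$statistic), p = wt$p.value), roc = roc,
       positive = positive)
}
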