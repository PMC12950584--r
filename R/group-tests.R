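#' Compare an index across clinical groups
#'
#' Kruskal-Wallis across all groups plus pairwise two-sided Wilcoxon
#' rank-sum tests with Benjamini-Hochberg adjustment.  Groups with fewer
#' than two samples are excluded with a warning.
#'
#' @param scores an `index_result` (see [compute_index()]) or a numeric
#'   vector.
#' @param groups character/factor of group labels, aligned with `scores`.
#' @return a list with `kruskal` (statistic `H`, `df`, `p`), `pairwise`
#'   (data frame: group pair, W, raw and BH-adjusted p) and `n` per group.
#' @export
group_compare <- function(scores, groups) {
  x <- if (inherits(scores, "index_result")) scores$score else as.numeric(scores)
  groups <- as.character(groups)
  stopifnot(length(x) == length(groups))
  ok <- is.finite(x) & !is.na(groups)
  x <- x[ok]; groups <- groups[ok]
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("group(s) with fewer than 2 samples excluded: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !groups %in% small
    x <- x[keep]; groups <- groups[keep]
    tab <- table(groups)
  }
  if (length(tab) < 2) stop("need at least two groups with >= 2 samples",
                            call. = FALSE)
  kw <- stats::kruskal.test(x, factor(groups))
  pairs <- utils::combn(names(tab), 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   W = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    wt <- suppressWarnings(stats::wilcox.test(x[groups == pairs[1, i]],
                                              x[groups == pairs[2, i]],
                                              exact = FALSE))
    pw$W[i] <- unname(wt$statistic)
    pw$p[i] <- wt$p.value
  }
  pw$p_adj <- stats::p.adjust(pw$p, method = "BH")
  list(kruskal = list(H = unname(kw$statistic), df = unname(kw$parameter),
                      p = kw$p.value),
       pairwise = pw,
       n = as.integer(tab))
}

# Jonckheere-Terpstra statistic: sum over ordered group pairs i<j of
# #(x_i < x_j) + 1/2 #(x_i == x_j)
jt_statistic <- function(values, group_index) {
  J <- 0
  k <- max(group_index)
  for (i in seq_len(k - 1)) {
    xi <- values[group_index == i]
    for (j in (i + 1):k) {
      xj <- values[group_index == j]
      cmp <- outer(xi, xj, "<")
      ties <- outer(xi, xj, "==")
      J <- J + sum(cmp) + 0.5 * sum(ties)
    }
  }
  J
}

# Exact one-sided upper-tail p by complete enumeration of all distinct
# assignments of the pooled values to groups of the observed sizes.
jt_exact_p <- function(values, group_index) {
  sizes <- tabulate(group_index)
  n <- length(values)
  count <- 0; total <- 0
  J_obs <- jt_statistic(values, group_index)
  recurse <- function(remaining, g, assignment) {
    if (g > length(sizes)) {
      J <- jt_statistic(values[assignment$idx], assignment$grp)
      total <<- total + 1
      if (J >= J_obs - 1e-9) count <<- count + 1
      return(invisible(NULL))
    }
    combos <- utils::combn(remaining, sizes[g], simplify = FALSE)
    for (pick in combos) {
      recurse(setdiff(remaining, pick), g + 1,
              list(idx = c(assignment$idx, pick),
                   grp = c(assignment$grp, rep(g, length(pick)))))
    }
  }
  recurse(seq_len(n), 1, list(idx = integer(), grp = integer()))
  count / total
}

#' Ordered trend test across disease stages (Jonckheere-Terpstra)
#'
#' Tests for a monotone location trend against a prespecified group
#' ordering (e.g. HC < CC < NSBP < SBP).  Uses the tie-corrected normal
#' approximation; for total n <= 12 (or `method = "exact"`) the one-sided
#' p-value is computed by complete enumeration of group assignments.
#'
#' @param scores an `index_result` or numeric vector.
#' @param groups group labels aligned with `scores`.
#' @param order character vector giving the hypothesized increasing order;
#'   must cover every observed label.
#' @param alternative `"increasing"` (default), `"decreasing"` or
#'   `"two.sided"`.
#' @param method `"auto"` (exact when n <= 12), `"normal"` or `"exact"`.
#' @return a list with the JT statistic `J`, its null mean and variance,
#'   `z`, `p`, and the `method` used.
#' @export
trend_test <- function(scores, groups, order,
                       alternative = c("increasing", "decreasing", "two.sided"),
                       method = c("auto", "normal", "exact")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  x <- if (inherits(scores, "index_result")) scores$score else as.numeric(scores)
  groups <- as.character(groups)
  stopifnot(length(x) == length(groups))
  ok <- is.finite(x) & !is.na(groups)
  x <- x[ok]; groups <- groups[ok]
  unknown <- setdiff(unique(groups), order)
  if (length(unknown)) {
    stop("group label(s) not in the stated ordering: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  order <- order[order %in% groups]
  if (length(order) < 3) stop("need at least 3 ordered groups", call. = FALSE)
  gi <- match(groups, order)
  n <- length(x); ni <- tabulate(gi)

  J <- jt_statistic(x, gi)
  mu <- (n^2 - sum(ni^2)) / 4
  tie_sizes <- as.integer(table(x))
  t1 <- n * (n - 1) * (2 * n + 5) - sum(ni * (ni - 1) * (2 * ni + 5)) -
    sum(tie_sizes * (tie_sizes - 1) * (2 * tie_sizes + 5))
  t2 <- sum(ni * (ni - 1) * (ni - 2)) *
    sum(tie_sizes * (tie_sizes - 1) * (tie_sizes - 2))
  t3 <- sum(ni * (ni - 1)) * sum(tie_sizes * (tie_sizes - 1))
  v <- t1 / 72 + t2 / (36 * n * (n - 1) * (n - 2)) + t3 / (8 * n * (n - 1))
  z <- (J - mu) / sqrt(v)

  use_exact <- method == "exact" || (method == "auto" && n <= 12)
  if (use_exact) {
    p_up <- jt_exact_p(x, gi)
    p_down <- jt_exact_p(-x, (length(order) + 1) - gi)
    p <- switch(alternative,
                increasing = p_up,
                decreasing = p_down,
                two.sided = min(1, 2 * min(p_up, p_down)))
    used <- "exact"
  } else {
    p <- switch(alternative,
                increasing = stats::pnorm(z, lower.tail = FALSE),
                decreasing = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(-abs(z)))
    used <- "normal"
  }
  list(J = J, mean = mu, var = v, z = z, p = p, method = used,
       alternative = alternative, n = ni)
}

#' Spearman correlation of an index with disease severity
#'
#' Spearman rank correlation with a two-sided p-value and a 95% confidence
#' interval from the Fisher z transform of the rank correlation
#' (atanh(rho) +/- z_{1-a/2} / sqrt(n - 3)).
#'
#' @param scores an `index_result` or numeric vector.
#' @param severity numeric severity measure (e.g. MELD), aligned.
#' @param conf.level confidence level; default 0.95.
#' @return a list with `rho`, `ci` (length 2), `p`, `n`.
#' @export
correlate_with_severity <- function(scores, severity, conf.level = 0.95) {
  x <- if (inherits(scores, "index_result")) scores$score else as.numeric(scores)
  y <- as.numeric(severity)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_, n = n))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  rho <- unname(ct$estimate)
  zcrit <- stats::qnorm(1 - (1 - conf.level) / 2)
  zr <- atanh(rho)
  ci <- tanh(zr + c(-1, 1) * zcrit / sqrt(n - 3))
  list(rho = rho, ci = ci, p = ct$p.value, n = n)
}
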