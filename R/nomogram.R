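#' Nomogram points table for a risk equation
#'
#' Standard points-axis construction: each covariate's contribution
#' `beta_j * v` is shifted so its minimum over the covariate's range is 0,
#' then scaled so the covariate with the largest `|beta| x range` spans
#' exactly 0-100 points.  Total points map back to predicted probability
#' through the linear-predictor inverse, so reading a subject's points off
#' the table reproduces [risk_probability()] exactly at grid nodes.
#'
#' @param equation a [risk_equation()].
#' @param ranges named list of `c(min, max)` per covariate; defaults to
#'   clinically sensible spans for the published equation.
#' @param grid_n grid nodes per continuous covariate; default 11.  A
#'   covariate whose range is exactly `c(0, 1)` is treated as binary.
#' @return an object of class `nomogram_table`: list with `axes` (named
#'   list of data frames `value`/`points`), `points_per_unit` (the linear
#'   predictor units per point), `probability` (data frame mapping a grid
#'   of total points to predicted probability) and
#'   `total_points_to_probability` (a function).
#' @export
build_nomogram <- function(equation,
                           ranges = list(sbp_mi = c(-3, 2),
                                         inr = c(0.8, 3),
                                         history = c(0, 1)),
                           grid_n = 11) {
  stopifnot(inherits(equation, "risk_equation"))
  beta <- equation$coefficients
  missing <- setdiff(names(beta), names(ranges))
  if (length(missing)) {
    stop("ranges missing for covariate(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  spans <- vapply(names(beta), function(v) {
    r <- ranges[[v]]
    if (r[1] >= r[2]) stop("degenerate range for '", v, "'", call. = FALSE)
    abs(beta[[v]]) * (r[2] - r[1])
  }, numeric(1))
  max_span <- max(spans)
  ref <- vapply(names(beta), function(v) {
    r <- ranges[[v]]
    if (beta[[v]] >= 0) r[1] else r[2]  # endpoint minimizing beta * v
  }, numeric(1))

  axes <- lapply(names(beta), function(v) {
    r <- ranges[[v]]
    grid <- if (identical(unname(r), c(0, 1))) c(0, 1)
            else seq(r[1], r[2], length.out = grid_n)
    points <- 100 * (beta[[v]] * grid - beta[[v]] * ref[[v]]) / max_span
    data.frame(value = grid, points = points)
  })
  names(axes) <- names(beta)

  base_lp <- equation$intercept + sum(beta * ref)
  total_to_prob <- function(total_points) {
    stats::plogis(base_lp + total_points * max_span / 100)
  }
  total_grid <- seq(0, sum(vapply(axes, function(a) max(a$points),
                                  numeric(1))), length.out = 101)
  structure(list(
    axes = axes,
    points_per_unit = max_span / 100,
    reference = ref,
    probability = data.frame(total_points = total_grid,
                             probability = total_to_prob(total_grid)),
    total_points_to_probability = total_to_prob,
    equation = equation, ranges = ranges), class = "nomogram_table")
}

#' @export
print.nomogram_table <- function(x, ...) {
  cat("nomogram points table\n")
  for (v in names(x$axes)) {
    a <- x$axes[[v]]
    cat(sprintf("  %s: %.4g points at %.4g ... %.4g points at %.4g\n",
                v, a$points[1], a$value[1], a$points[nrow(a)],
                a$value[nrow(a)]))
  }
  invisible(x)
}
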