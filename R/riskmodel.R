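#' Logistic risk equation
#'
#' A frozen scoring function: intercept plus named log-odds coefficients.
#' Covariates are matched by name against the columns of the data supplied
#' to [linear_predictor()] / [risk_probability()].
#'
#' @param intercept log-odds intercept.
#' @param coefficients named numeric vector of log-odds per covariate unit.
#' @param provenance free-text label recording where the values come from.
#' @return an object of class `risk_equation`.
#' @export
risk_equation <- function(intercept, coefficients, provenance = "user") {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(coefficients), !is.null(names(coefficients)))
  if (anyDuplicated(names(coefficients))) {
    stop("coefficient names must be unique", call. = FALSE)
  }
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients,
                 provenance = provenance),
            class = "risk_equation")
}

#' The published SBP risk-prediction (SBP-RP) equation
#'
#' The frozen published model:
#' `-6.8107 + 2.9873 x SBP-MI + 2.4316 x INR + 2.0950 x previous history`.
#' These defaults are immutable; refitting on new data always produces a
#' separate, freshly labelled [risk_equation()] rather than mutating this
#' one.  Covariate names are `sbp_mi` (dimensionless), `inr` (ratio) and
#' `history` (0/1).
#'
#' @return a `risk_equation`.
#' @export
sbp_rp_equation <- function() {
  risk_equation(
    intercept = -6.8107,
    coefficients = c(sbp_mi = 2.9873, inr = 2.4316, history = 2.0950),
    provenance = "published SBP-RP model")
}

#' Linear predictor and risk probability of a risk equation
#'
#' `linear_predictor()` returns `intercept + sum(coefficient x value)` per
#' row (log-odds); `risk_probability()` its inverse-logit.  Both are pure
#' and deterministic.  The `history` covariate, when present, must be
#' strictly 0/1.
#'
#' @param equation a [risk_equation()].
#' @param covariates data frame (or named list) containing one column per
#'   equation covariate.
#' @return numeric vector, one value per row of `covariates`.
#' @examples
#' eq <- sbp_rp_equation()
#' linear_predictor(eq, data.frame(sbp_mi = 0, inr = 0, history = 0))
#' risk_probability(eq, data.frame(sbp_mi = 1, inr = 1.6, history = 1))
#' @export
linear_predictor <- function(equation, covariates) {
  stopifnot(inherits(equation, "risk_equation"))
  covariates <- as.data.frame(covariates)
  need <- names(equation$coefficients)
  missing <- setdiff(need, names(covariates))
  if (length(missing)) {
    stop("covariate(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if ("history" %in% need) {
    stopifnot_binary(covariates[["history"]], "history")
  }
  X <- as.matrix(covariates[, need, drop = FALSE])
  if (anyNA(X)) stop("missing covariate values", call. = FALSE)
  drop(equation$intercept + X %*% equation$coefficients)
}

#' @rdname linear_predictor
#' @export
risk_probability <- function(equation, covariates) {
  stats::plogis(linear_predictor(equation, covariates))
}
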