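# internal helpers shared across modules

expit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage child seeds derived from one root seed, so
# regenerating one stage (e.g. clinical covariates) never perturbs another
# (e.g. compositions).  Kept strictly below 2^31 - 1.
child_seed <- function(seed, stage) {
  stages <- c(compositions = 1L, clinical = 2L, outcomes = 3L, pairs = 4L,
              bootstrap = 5L, simulation = 6L, validation = 7L)
  if (!stage %in% names(stages)) {
    stop("unknown seed stage: ", stage, call. = FALSE)
  }
  (abs(as.integer(seed)) %% 268435455L) * 8L + stages[[stage]]
}

stopifnot_binary <- function(x, what) {
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    stop(what, " must be strictly binary (0/1)", call. = FALSE)
  }
  invisible(x)
}
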