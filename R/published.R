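#' Published univariable screening table
#'
#' The univariable logistic-regression p-values reported for the
#' prospective ascites cohort, shipped as plain text so the P < 0.10
#' screening rule can be replayed exactly.  Entries reported only as
#' `<0.001` carry a numeric stand-in of 0.0005 (any value below the
#' reporting limit gives the same screening decision at thresholds of
#' 0.001 or more); the verbatim label is kept in `p_label`.
#'
#' @return data frame with columns `variable`, `p_label`, `p`, in the
#'   reported order.
#' @seealso [screen_by_pvalue()]
#' @export
published_univariable_table <- function() {
  utils::read.csv(system.file("extdata", "univariable_pvalues.csv",
                              package = "sbpmi"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' Published cohort event counts
#'
#' Incident-SBP events in the 6-month prospective ascites cohort (15/140)
#' and prior-SBP-history prevalence in the SBP case-control group (5/25).
#'
#' @return named list of lists with `events` and `n`.
#' @export
published_study_counts <- function() {
  jsonlite::read_json(system.file("extdata", "study_counts.json",
                                  package = "sbpmi"),
                      simplifyVector = FALSE)
}

#' Percentage of events
#'
#' @param events,n event count and denominator.
#' @param digits decimals to round to; default 1.
#' @return `100 * events / n`, rounded.
#' @export
event_percent <- function(events, n, digits = 1) {
  round(100 * events / n, digits)
}
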