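#' Define a ratio-type dysbiosis index
#'
#' A dysbiosis index is a per-sample ratio of summed genus relative
#' abundances, optionally log10-transformed, with an optional per-genus
#' pseudocount so the ratio stays finite under zeros:
#'
#' \deqn{score = transform\left(\frac{\sum_{g \in num} (x_g + \epsilon)}
#'   {\sum_{g \in den} (x_g + \epsilon)}\right)}
#'
#' where \eqn{x_g} is the genus relative abundance on the proportion scale
#' and \eqn{\epsilon} is the pseudocount (added to every term when
#' `pseudocount_scope = "per_genus"`, omitted when `"none"`).
#'
#' @param name index name.
#' @param numerator,denominator disjoint, nonempty sets of canonical genus
#'   names.
#' @param pseudocount positive proportion added per genus; default `1e-6`.
#' @param transform `"log10"` or `"none"`.
#' @param pseudocount_scope `"per_genus"` or `"none"`.
#' @return an object of class `index_definition`.
#' @seealso [sbpmi_definition()], [hbcdi_definition()], [compute_index()]
#' @export
index_definition <- function(name, numerator, denominator,
                             pseudocount = 1e-6,
                             transform = c("log10", "none"),
                             pseudocount_scope = c("per_genus", "none")) {
  transform <- match.arg(transform)
  pseudocount_scope <- match.arg(pseudocount_scope)
  numerator <- unique(as.character(numerator))
  denominator <- unique(as.character(denominator))
  if (!length(numerator) || !length(denominator)) {
    stop("numerator and denominator genus sets must be nonempty", call. = FALSE)
  }
  overlap <- intersect(numerator, denominator)
  if (length(overlap)) {
    stop("genus in both numerator and denominator: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  if (pseudocount_scope == "per_genus" &&
      (!is.numeric(pseudocount) || pseudocount <= 0)) {
    stop("pseudocount must be a positive number", call. = FALSE)
  }
  structure(list(name = name, numerator = numerator,
                 denominator = denominator, pseudocount = pseudocount,
                 transform = transform,
                 pseudocount_scope = pseudocount_scope),
            class = "index_definition")
}

#' The SBP microbiota-derived index (SBP-MI)
#'
#' log10 ratio of summed pathobiont abundances (Streptococcus,
#' Escherichia-Shigella, Klebsiella, Veillonella) over summed SCFA-producer
#' abundances (Prevotella, Roseburia, Faecalibacterium, Bacteroides), with a
#' pseudocount of 1e-6 added to each genus term so zeros stay finite.
#' Higher values indicate a more pathobiont-dominated community; the index
#' rises along the healthy -> compensated cirrhosis -> ascites -> SBP axis.
#'
#' @return an [index_definition()].
#' @export
sbpmi_definition <- function() {
  index_definition(
    name = "SBP-MI",
    numerator = c("Streptococcus", "Escherichia-Shigella", "Klebsiella",
                  "Veillonella"),
    denominator = c("Prevotella", "Roseburia", "Faecalibacterium",
                    "Bacteroides"),
    pseudocount = 1e-6, transform = "log10", pseudocount_scope = "per_genus")
}

#' The hepatitis B cirrhosis dysbiosis indicator (HBCDI)
#'
#' Raw (untransformed, no pseudocount) ratio
#' (Escherichia-Shigella + Streptococcus + Lactobacillus) /
#' (Ruminococcus + Prevotella + Bacteroides).  A zero denominator yields a
#' flagged undefined value rather than an error; pass
#' `pseudocount_scope = "per_genus"` to guard division by zero instead.
#'
#' @param pseudocount_scope `"none"` (default, the published formula) or
#'   `"per_genus"`.
#' @param pseudocount used only when `pseudocount_scope = "per_genus"`.
#' @return an [index_definition()].
#' @export
hbcdi_definition <- function(pseudocount_scope = c("none", "per_genus"),
                             pseudocount = 1e-6) {
  pseudocount_scope <- match.arg(pseudocount_scope)
  index_definition(
    name = "HBCDI",
    numerator = c("Escherichia-Shigella", "Streptococcus", "Lactobacillus"),
    denominator = c("Ruminococcus", "Prevotella", "Bacteroides"),
    pseudocount = pseudocount, transform = "none",
    pseudocount_scope = pseudocount_scope)
}

#' Compute a dysbiosis index for every sample
#'
#' Genera named in the definition but absent from the table are treated as
#' abundance 0 (the pseudocount then applies), with a warning: in genus-level
#' 16S tables an absent column is statistically a column of zeros.  With
#' `pseudocount_scope = "none"` and a zero denominator the sample's score is
#' `NA` and flagged, not an error.
#'
#' @param table a normalized, taxon-resolved [abundance_table()].
#' @param definition an [index_definition()].
#' @return an `index_result`: a data frame with columns `sample_id`, `score`,
#'   and `n_zero` (count of zero-abundance index genera in that sample), plus
#'   attributes `definition`, `missing_genera` and `undefined` (logical
#'   vector flagging zero-denominator samples).
#' @examples
#' m <- matrix(c(0.1, 0.9, 0.5, 0.5), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("Klebsiella", "Bacteroides")))
#' compute_index(abundance_table(m), sbpmi_definition())
#' @export
compute_index <- function(table, definition) {
  stopifnot(inherits(definition, "index_definition"))
  needed <- c(definition$numerator, definition$denominator)
  missing <- setdiff(needed, colnames(table))
  if (length(missing)) {
    warning(sprintf("index '%s': genera absent from table treated as 0: %s",
                    definition$name, paste(missing, collapse = ", ")),
            call. = FALSE)
  }
  vals <- unclass(table)
  get_block <- function(genera) {
    block <- matrix(0, nrow = nrow(vals), ncol = length(genera),
                    dimnames = list(rownames(vals), genera))
    present <- intersect(genera, colnames(vals))
    block[, present] <- vals[, present, drop = FALSE]
    block
  }
  num <- get_block(definition$numerator)
  den <- get_block(definition$denominator)
  eps <- if (definition$pseudocount_scope == "per_genus") definition$pseudocount else 0
  num_sum <- rowSums(num + eps)
  den_sum <- rowSums(den + eps)
  undefined <- den_sum == 0
  ratio <- num_sum / den_sum
  ratio[undefined] <- NA_real_
  score <- if (definition$transform == "log10") log10(ratio) else ratio
  n_zero <- rowSums(cbind(num, den) == 0)
  out <- data.frame(sample_id = rownames(vals), score = as.numeric(score),
                    n_zero = as.integer(n_zero), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "definition") <- definition
  attr(out, "missing_genera") <- missing
  attr(out, "undefined") <- unname(undefined)
  class(out) <- c("index_result", "data.frame")
  out
}

#' Paired baseline/follow-up index differences
#'
#' For every subject with exactly one baseline and one follow-up sample,
#' computes delta = follow-up score - baseline score.  Subjects missing a
#' timepoint are excluded and reported in the `"excluded"` attribute; a
#' duplicated timepoint for a subject is a pairing error.
#'
#' @param baseline,followup `index_result` objects (see [compute_index()])
#'   covering the baseline and follow-up samples.
#' @param metadata data frame with columns `sample_id`, `subject_id`,
#'   `timepoint` (`"baseline"`/`"followup"`), and optionally `arm`.
#' @return a `delta_result`: data frame with columns `subject_id`,
#'   `baseline`, `followup`, `delta` and (when available) `arm`.
#' @export
compute_delta <- function(baseline, followup, metadata) {
  stopifnot(is.data.frame(metadata),
            all(c("sample_id", "subject_id", "timepoint") %in% names(metadata)))
  scores <- rbind(
    data.frame(sample_id = baseline$sample_id, score = baseline$score,
               stringsAsFactors = FALSE),
    data.frame(sample_id = followup$sample_id, score = followup$score,
               stringsAsFactors = FALSE))
  md <- merge(metadata, scores, by = "sample_id")
  split_md <- split(md, md$subject_id)
  rows <- list(); excluded <- character()
  for (sid in names(split_md)) {
    s <- split_md[[sid]]
    if (anyDuplicated(s$timepoint)) {
      stop("subject '", sid, "' has a duplicated timepoint", call. = FALSE)
    }
    if (!all(c("baseline", "followup") %in% s$timepoint)) {
      excluded <- c(excluded, sid)
      next
    }
    b <- s$score[s$timepoint == "baseline"]
    f <- s$score[s$timepoint == "followup"]
    rows[[sid]] <- data.frame(
      subject_id = sid, baseline = b, followup = f, delta = f - b,
      arm = if ("arm" %in% names(s)) s$arm[1] else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no subject has both timepoints", call. = FALSE)
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "excluded") <- excluded
  class(out) <- c("delta_result", "data.frame")
  out
}
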