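#' Construct a genus-level relative-abundance table
#'
#' An `abundance_table` is a numeric matrix with samples as rows and genera
#' as columns.  Values are non-negative relative abundances on the
#' proportion scale (each row sums to 1 after [normalize_abundance()]).
#' Orientation is fixed: samples are rows.  Transposed input is never
#' auto-detected silently; transpose explicitly before construction.
#'
#' @param values numeric matrix (samples x genera), no negative entries.
#' @param sample_ids unique sample identifiers; defaults to `rownames(values)`.
#' @param genus_names unique genus labels; defaults to `colnames(values)`.
#' @return an object of class `abundance_table` (a classed numeric matrix).
#' @examples
#' m <- matrix(c(0.6, 0.4, 0.1, 0.9), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("Bacteroides", "Klebsiella")))
#' abundance_table(m)
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            genus_names = colnames(values)) {
  values <- unclass(as.matrix(values))
  if (!is.numeric(values)) stop("abundance values must be numeric", call. = FALSE)
  if (is.null(sample_ids)) stop("sample identifiers are required", call. = FALSE)
  if (is.null(genus_names)) stop("genus names are required", call. = FALSE)
  sample_ids <- as.character(sample_ids)
  genus_names <- as.character(genus_names)
  if (length(sample_ids) != nrow(values) || length(genus_names) != ncol(values)) {
    stop("dimension mismatch between values and labels", call. = FALSE)
  }
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) {
    stop("duplicate sample identifier(s): ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  }
  dup_g <- genus_names[duplicated(genus_names)]
  if (length(dup_g)) {
    stop("duplicate genus column(s): ", paste(unique(dup_g), collapse = ", "),
         call. = FALSE)
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative abundance at sample '%s', genus '%s'",
                 sample_ids[neg[1, 1]], genus_names[neg[1, 2]]), call. = FALSE)
  }
  if (anyNA(values)) stop("missing values in abundance table", call. = FALSE)
  dimnames(values) <- list(sample_ids, genus_names)
  class(values) <- c("abundance_table", "matrix", "array")
  values
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d genera\n", nrow(x), ncol(x)))
  rs <- rowSums(x)
  cat(sprintf("  row sums in [%.4g, %.4g]\n", min(rs), max(rs)))
  invisible(x)
}

#' Sample identifiers and genus names of an abundance table
#' @param table an [abundance_table()].
#' @return character vector of labels.
#' @export
sample_ids <- function(table) rownames(table)

#' @rdname sample_ids
#' @export
genus_names <- function(table) colnames(table)

#' Read a genus-level abundance table
#'
#' Reads a samples-x-genera table from TSV or CSV (first column holds the
#' sample identifier, remaining columns are genus abundances) or from a
#' BIOM v1 (JSON) file via the biomformat package (BIOM stores features as
#' rows, so the matrix is transposed on read).
#'
#' Duplicate sample or genus labels are rejected with the offending label
#' named; negative entries are rejected with coordinates.  Raw values are
#' returned untouched: call [normalize_abundance()] to close rows to 1.
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"csv"`, `"biom"`; default guessed from
#'   the file extension, falling back to `"tsv"`.
#' @return an [abundance_table()].
#' @export
read_abundance <- function(path, format = c("auto", "tsv", "csv", "biom")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", biom = "biom", "tsv")
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("the 'biomformat' package is required to read BIOM files", call. = FALSE)
    }
    b <- biomformat::read_biom(path)
    m <- methods::as(biomformat::biom_data(b), "matrix")
    return(abundance_table(t(m)))
  }
  sep <- if (format == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  if (ncol(raw) < 2) stop("abundance table needs a sample-id column plus genera",
                          call. = FALSE)
  genera <- colnames(raw)[-1]
  dupg <- genera[duplicated(genera)]
  if (length(dupg)) {
    stop("duplicate genus column(s): ", paste(unique(dupg), collapse = ", "),
         call. = FALSE)
  }
  ids <- as.character(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  abundance_table(vals, sample_ids = ids, genus_names = genera)
}

#' Write an abundance table to TSV or CSV
#'
#' First column is `sample_id`; remaining columns are genus names.
#' `read_abundance(write_abundance(x))` is the identity on valid tables.
#'
#' @param table an [abundance_table()].
#' @param path output path.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(table, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  df <- data.frame(sample_id = rownames(table), check.names = FALSE)
  df <- cbind(df, as.data.frame(unclass(table)[, , drop = FALSE],
                                check.names = FALSE))
  utils::write.table(df, path, sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize an abundance table to proportions
#'
#' Divides each row by its total so rows sum to 1; tables on the percent
#' scale are divided by 100 first (`percent_to_proportion`).  All index
#' computations in this package assume the proportion scale, on which the
#' default pseudocount of 1e-6 is negligible relative to typical genus
#' abundances.
#'
#' @param table an [abundance_table()].
#' @param mode `"proportion"` (default) or `"percent_to_proportion"`.
#' @return a normalized [abundance_table()]; every row sums to 1 within 1e-9.
#' @export
normalize_abundance <- function(table,
                                mode = c("proportion", "percent_to_proportion")) {
  mode <- match.arg(mode)
  vals <- unclass(table)
  if (mode == "percent_to_proportion") vals <- vals / 100
  totals <- rowSums(vals)
  zero <- which(totals <= 0)
  if (length(zero)) {
    stop("all-zero abundance row for sample(s): ",
         paste(rownames(table)[zero], collapse = ", "), call. = FALSE)
  }
  abundance_table(vals / totals)
}
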