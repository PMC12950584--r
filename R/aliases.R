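#' Taxon alias map
#'
#' Maps canonical genus names to accepted spelling variants and, separately,
#' to SILVA-style sublineage patterns.  Genus-level 16S tables mix naming
#' conventions: the same genus may appear as "Escherichia-Shigella" (hyphen),
#' "Escherichia–Shigella" (en dash) or "Escherichia_Shigella", and SILVA
#' splits some genera into numbered sublineages ("Prevotella_9").
#'
#' Typographic `variants` are folded under both resolution policies; regex
#' `sublineages` are folded (and summed) only under the `sum_sublineages`
#' policy of [resolve_taxa()], because whether a formula genus means one
#' sublineage or the summed complex is a substantive choice.
#'
#' @param variants named list: canonical name -> character vector of accepted
#'   alternative spellings.
#' @param sublineages named character vector: canonical name -> regular
#'   expression matching its sublineage column labels.
#' @return an object of class `taxon_alias_map`.
#' @seealso [default_alias_map()], [resolve_taxa()]
#' @export
taxon_alias_map <- function(variants = list(), sublineages = character()) {
  stopifnot(is.list(variants))
  all_aliases <- unlist(variants, use.names = FALSE)
  dup <- all_aliases[duplicated(all_aliases)]
  if (length(dup)) {
    stop("alias claimed by two canonical names: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(names(variants))) || (length(sublineages) &&
                                        any(!nzchar(names(sublineages))))) {
    stop("every canonical name must be nonempty", call. = FALSE)
  }
  structure(list(variants = variants, sublineages = sublineages),
            class = "taxon_alias_map")
}

#' Default alias map for the index formula genera
#'
#' Ships dash/underscore/space variants for every genus appearing in the
#' SBP-MI and HBCDI formulas, plus SILVA sublineage patterns for Prevotella
#' and Ruminococcus.  User maps can be loaded from JSON with
#' [read_alias_map()].
#'
#' @return a [taxon_alias_map()].
#' @export
default_alias_map <- function() {
  dash_variants <- function(a, b) {
    c(paste0(a, "–", b),   # en dash
      paste0(a, "_", b),
      paste0(a, ".", b),
      paste0(a, " ", b),
      paste0(a, "/", b))
  }
  taxon_alias_map(
    variants = list(
      "Escherichia-Shigella" = dash_variants("Escherichia", "Shigella"),
      "Prevotella"       = c("g__Prevotella"),
      "Bacteroides"      = c("g__Bacteroides"),
      "Faecalibacterium" = c("g__Faecalibacterium"),
      "Roseburia"        = c("g__Roseburia"),
      "Streptococcus"    = c("g__Streptococcus"),
      "Klebsiella"       = c("g__Klebsiella"),
      "Veillonella"      = c("g__Veillonella"),
      "Lactobacillus"    = c("g__Lactobacillus"),
      "Ruminococcus"     = c("g__Ruminococcus")
    ),
    sublineages = c(
      "Prevotella"   = "^Prevotella_[0-9]+$",
      "Ruminococcus" = "^Ruminococcus_[0-9]+$"
    )
  )
}

#' Read or write an alias map as JSON
#'
#' @param path JSON file path with fields `variants` (object of arrays) and
#'   `sublineages` (object of strings).
#' @return [read_alias_map()] returns a [taxon_alias_map()];
#'   `write_alias_map()` returns `path` invisibly.
#' @export
read_alias_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  taxon_alias_map(variants = as.list(x$variants),
                  sublineages = unlist(x$sublineages) %||% character())
}

#' @rdname read_alias_map
#' @param aliases a [taxon_alias_map()].
#' @export
write_alias_map <- function(aliases, path) {
  jsonlite::write_json(list(variants = aliases$variants,
                            sublineages = as.list(aliases$sublineages)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Resolve taxon-name variants to canonical genus names
#'
#' Renames columns whose labels match an accepted variant of a canonical
#' genus.  Under `policy = "sum_sublineages"`, columns matching a SILVA
#' sublineage pattern are additionally folded in, and multiple source
#' columns mapping to the same canonical genus are summed.  Under
#' `policy = "strict"` only typographic variants are renamed and a
#' many-to-one mapping is an error.
#'
#' Resolution conserves mass exactly: no sample's total abundance changes.
#' The mappings applied, and any `expected` genera still absent after
#' resolution (treated as abundance 0 downstream), are recorded in the
#' `"resolution"` attribute of the result.
#'
#' @param table an [abundance_table()].
#' @param aliases a [taxon_alias_map()]; default [default_alias_map()].
#' @param policy `"strict"` or `"sum_sublineages"`.
#' @param expected optional character vector of genus names required
#'   downstream (e.g. an index's genus sets); absences are reported.
#' @return an [abundance_table()] with canonical column names and attribute
#'   `"resolution"`: a list with `mappings` (data frame: source, canonical,
#'   action) and `missing` (character).
#' @export
resolve_taxa <- function(table, aliases = default_alias_map(),
                         policy = c("strict", "sum_sublineages"),
                         expected = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(aliases, "taxon_alias_map"))
  cols <- colnames(table)

  canon_of <- rep(NA_character_, length(cols))
  for (canonical in names(aliases$variants)) {
    hit <- cols %in% aliases$variants[[canonical]]
    clash <- hit & !is.na(canon_of) & canon_of != canonical
    if (any(clash)) {
      stop("column '", cols[which(clash)[1]],
           "' claimed by two canonical names", call. = FALSE)
    }
    canon_of[hit] <- canonical
  }
  if (policy == "sum_sublineages") {
    for (canonical in names(aliases$sublineages)) {
      hit <- grepl(aliases$sublineages[[canonical]], cols)
      clash <- hit & !is.na(canon_of) & canon_of != canonical
      if (any(clash)) {
        stop("column '", cols[which(clash)[1]],
             "' claimed by two canonical names", call. = FALSE)
      }
      canon_of[hit] <- canonical
    }
  }
  canon_of[is.na(canon_of)] <- cols[is.na(canon_of)]

  changed <- canon_of != cols
  mappings <- data.frame(source = cols[changed],
                         canonical = canon_of[changed],
                         action = rep("rename", sum(changed)),
                         stringsAsFactors = FALSE)

  if (anyDuplicated(canon_of)) {
    if (policy == "strict") {
      d <- canon_of[duplicated(canon_of)][1]
      stop("multiple columns resolve to '", d,
           "' under strict policy; use policy = \"sum_sublineages\"",
           call. = FALSE)
    }
    vals <- unclass(table)
    agg <- t(rowsum(t(vals), group = canon_of, reorder = FALSE))
    out <- abundance_table(agg, sample_ids = rownames(table))
    summed <- unique(canon_of[duplicated(canon_of)])
    mappings$action[mappings$canonical %in% summed] <- "sum"
  } else {
    vals <- unclass(table)
    colnames(vals) <- canon_of
    out <- abundance_table(vals, sample_ids = rownames(table))
  }

  missing <- character()
  if (!is.null(expected)) {
    missing <- setdiff(expected, colnames(out))
  }
  attr(out, "resolution") <- list(mappings = mappings, missing = missing,
                                  policy = policy)
  out
}
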