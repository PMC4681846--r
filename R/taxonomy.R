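#' Canonical taxonomic ranks
#'
#' The fixed seven-rank ladder used throughout: domain, phylum, class,
#' order, family, genus, species. Sub-ranks are out of scope.
#'
#' @return Character vector of the seven rank names, shallowest first.
#' @export
taxonomic_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

rank_index <- function(rank) {
  i <- match(tolower(rank), taxonomic_ranks())
  if (is.na(i)) abort(sprintf("Unknown taxonomic rank '%s'.", rank))
  i
}

#' Parse a semicolon-delimited lineage string
#'
#' Accepts 1-7 fields ordered domain to species, optionally carrying
#' GTDB-style rank prefixes (`d__`, `p__`, ...) which are stripped.
#' A truncated lineage (deeper ranks missing) is legal; a gap (an empty
#' field before a filled one) is not.
#'
#' @param text Lineage string, e.g. `"Bacteria;Proteobacteria;Gammaproteobacteria"`.
#' @return A `lineage` object: a named character vector over the leading
#'   ranks that are set.
#' @export
#' @examples
#' lin <- parse_lineage("d__Bacteria;p__Firmicutes")
#' lineage_depth(lin)
parse_lineage <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    abort("Lineage string is empty.")
  }
  fields <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  if (length(fields) > 7L) {
    abort(sprintf("Lineage has %d fields; at most 7 (domain..species) allowed.",
                  length(fields)))
  }
  fields <- sub("^[a-zA-Z]__", "", fields)
  # drop trailing empties ("Bacteria;" or prefix-only "s__"), then no gaps
  while (length(fields) > 0L && !nzchar(fields[length(fields)])) {
    fields <- fields[-length(fields)]
  }
  if (length(fields) == 0L) abort("Lineage string is empty.")
  if (any(!nzchar(fields))) {
    abort(sprintf("Lineage '%s' has a gap at rank '%s'.",
                  text, taxonomic_ranks()[which(!nzchar(fields))[1]]))
  }
  structure(setNames(fields, taxonomic_ranks()[seq_along(fields)]),
            class = "lineage")
}

#' @export
print.lineage <- function(x, ...) {
  cat("<lineage> ", format_lineage(x), "\n", sep = "")
  invisible(x)
}

#' Format a lineage back to a semicolon-delimited string
#' @param x A `lineage`.
#' @return A single string.
#' @export
format_lineage <- function(x) paste(unclass(x), collapse = ";")

#' Depth of a lineage
#'
#' @param x A `lineage`.
#' @return The name of the deepest rank set.
#' @export
lineage_depth <- function(x) names(x)[length(x)]

#' Deepest rank at which two lineages agree
#'
#' Walks the ladder from domain down and returns the deepest rank at which
#' both lineages are set and (case-insensitively) equal; `NULL` if they
#' already differ at domain. Agreement stops at the first disagreement or
#' at the shallower lineage's depth.
#'
#' @param a,b `lineage` objects.
#' @return A rank name, or `NULL`.
#' @export
agreement_rank <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(NULL)
  eq <- tolower(unclass(a)[seq_len(n)]) == tolower(unclass(b)[seq_len(n)])
  if (!eq[1]) return(NULL)
  taxonomic_ranks()[max(which(cumsum(!eq) == 0))]
}

#' Is a lineage deep enough for the homology path?
#'
#' @param target A `lineage`.
#' @param required A canonical rank name.
#' @return `TRUE` iff the lineage's depth is at or deeper than `required`.
#' @export
is_taxonomy_deep_enough <- function(target, required) {
  rank_index(lineage_depth(target)) >= rank_index(required)
}
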