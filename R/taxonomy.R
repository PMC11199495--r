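# Seven-rank taxonomy strings and placeholder-name handling.
#
# Canonical form: seven semicolon-delimited fields (kingdom;...;species),
# optionally rank-prefixed ("k__Bacteria;p__..."). Placeholder names for
# lineages without official taxonomy follow midas_<r>_<n>, where <r> is the
# single-letter rank code (k/p/c/o/f/g/s) and <n> a numeric identifier.

PLACEHOLDER_RE <- "^midas_([kpcofgs])_([0-9]+)$"

#' Parse a taxonomy string into a seven-rank path
#'
#' Accepts up to seven semicolon-delimited fields, with or without
#' `k__`-style rank prefixes. Missing trailing ranks become empty strings.
#' Placeholder names (`midas_<r>_<n>`) are flagged, and their rank letter
#' must agree with the field position.
#'
#' @param string A single taxonomy string, e.g.
#'   `"Bacteria;Firmicutes;Clostridia"` or
#'   `"k__Bacteria;p__Firmicutes"`.
#' @return A list with `ranks` (named character vector of length 7, names
#'   kingdom..species) and `placeholder` (named logical vector of length 7).
#' @export
#' @examples
#' parse_taxonomy("Bacteria;Firmicutes;Clostridia;;;midas_g_12;midas_s_7")
parse_taxonomy <- function(string) {
  stopifnot(length(string) == 1L)
  fields <- if (is.na(string) || !nzchar(trimws(string))) character(0)
            else strsplit(string, ";", fixed = TRUE)[[1]]
  if (length(fields) > 7L)
    abort_input("taxonomy string has ", length(fields), " fields (max 7): ",
                string)
  fields <- trimws(fields)
  # Strip rank prefixes of the k__ / p__ ... dialect.
  fields <- sub("^[kpcofgsdKPCOFGSD]__", "", fields)
  ranks <- setNames(character(7L), TAX_RANKS)
  ranks[seq_along(fields)] <- fields
  ph <- grepl(PLACEHOLDER_RE, ranks)
  letters_found <- sub(PLACEHOLDER_RE, "\\1", ranks[ph])
  expected <- RANK_LETTERS[TAX_RANKS[ph]]
  if (any(letters_found != expected))
    abort_input("placeholder rank letter inconsistent with position in: ",
                string)
  list(ranks = ranks, placeholder = setNames(ph, TAX_RANKS))
}

#' Format a seven-rank path back to a taxonomy string
#'
#' Inverse of [parse_taxonomy()]; round-trips losslessly (modulo prefixes).
#'
#' @param path A list with `ranks` as returned by [parse_taxonomy()], or a
#'   character vector of up to 7 rank names.
#' @param prefixed Prepend `k__`-style rank prefixes?
#' @return A single taxonomy string with 7 semicolon-delimited fields.
#' @export
format_taxonomy <- function(path, prefixed = FALSE) {
  ranks <- if (is.list(path)) path$ranks else path
  full <- setNames(character(7L), TAX_RANKS)
  full[seq_along(ranks)] <- ranks
  if (prefixed)
    full <- paste0(RANK_LETTERS[TAX_RANKS], "__", full)
  paste(full, collapse = ";")
}

# Taxonomy columns of a reference set data.frame -> matrix of names.
tax_matrix <- function(db) {
  missing <- setdiff(TAX_RANKS, names(db))
  if (length(missing) > 0)
    abort_input("reference set lacks taxonomy column(s): ",
                paste(missing, collapse = ", "))
  as.matrix(db[, TAX_RANKS, drop = FALSE])
}
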