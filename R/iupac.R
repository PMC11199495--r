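# IUPAC nucleotide code handling.
#
# A degenerate code stands for a set of bases; two characters are compatible
# (can base-pair the same template position) iff their base sets intersect.
# This permissive semantics is used consistently for alignment identity,
# duplicate detection and primer-template matching.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_SETS)

# 15 x 15 logical lookup: do the base sets intersect?
IUPAC_COMPAT <- local({
  m <- matrix(FALSE, 15L, 15L, dimnames = list(IUPAC_LETTERS, IUPAC_LETTERS))
  for (a in IUPAC_LETTERS) for (b in IUPAC_LETTERS)
    m[a, b] <- length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) > 0L
  m
})

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", D = "H", H = "D", V = "B", N = "N")

#' Do two IUPAC nucleotide codes match?
#'
#' Two codes match iff the nucleotide sets they stand for intersect, e.g.
#' `R` (A/G) matches `A` but `Y` (C/T) does not; `N` matches everything.
#' Vectorized over both arguments.
#'
#' @param a,b Character vectors of single IUPAC nucleotide codes
#'   (case-insensitive).
#' @return Logical vector.
#' @export
#' @examples
#' iupac_matches("R", "A")
#' iupac_matches(c("Y", "N"), c("A", "G"))
iupac_matches <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  bad <- unique(c(a[!a %in% IUPAC_LETTERS], b[!b %in% IUPAC_LETTERS]))
  if (length(bad) > 0)
    abort_input("invalid IUPAC character(s): ", paste(bad, collapse = ", "))
  IUPAC_COMPAT[cbind(a, b)]
}

# Validate and uppercase a sequence string; error on non-IUPAC characters.
check_sequence <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    abort_input(what, " must be a single non-empty string")
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- unique(chars[!chars %in% IUPAC_LETTERS])
  if (length(bad) > 0)
    abort_input(what, " contains non-IUPAC character(s): ",
                paste(bad, collapse = ", "))
  seq
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Reverse complement of an IUPAC nucleotide string
#'
#' @param seq A single nucleotide string (IUPAC alphabet).
#' @return The reverse complement, uppercase.
#' @export
reverse_complement <- function(seq) {
  seq <- check_sequence(seq)
  paste(rev(IUPAC_COMPLEMENT[seq_chars(seq)]), collapse = "")
}

# Columnwise IUPAC equality of two same-length sequences (used by the
# dedup shortcut: with equal lengths, 100% end-gap-free identity is
# equivalent to every aligned column's code sets intersecting).
iupac_equal <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  if (a == b) return(TRUE)
  all(iupac_matches(seq_chars(a), seq_chars(b)))
}

#' Random DNA sequence
#'
#' Uniform i.i.d. A/C/G/T sequence, deterministic under `seed`.
#'
#' @param length Sequence length in nucleotides.
#' @param seed Optional integer seed.
#' @return A single character string.
#' @export
random_dna <- function(length, seed = NULL) {
  stopifnot(length >= 1)
  with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""))
}
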