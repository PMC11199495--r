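# End-gap-free (semi-global) pairwise alignment and nearest-neighbour
# search over a reference set.
#
# Scoring: match +1 (IUPAC code sets intersect), mismatch -1, gap column -2
# (linear). The shorter sequence must be aligned end to end; terminal
# overhangs of the longer sequence are free and excluded from the aligned
# span. Identity is 100 * matches / alignment columns over the aligned
# span, so internal gap columns count against identity, terminal overhangs
# do not. Requiring full coverage of the shorter sequence keeps identity
# meaningful for unrelated pairs (a free-clipping overlap alignment would
# degenerate to a short all-match island). For equal lengths both
# orientations are evaluated and the larger identity returned, keeping the
# measure symmetric.
#
# Determinism: cell ties resolve diagonal > up > left; the alignment ends
# at the maximum-score cell of the last row, ties towards larger column.

ALIGN_MATCH <- 1
ALIGN_MISMATCH <- -1
ALIGN_GAP <- -2

# +1/-1 substitution lookup over the 15 IUPAC codes (built lazily so file
# load order does not matter).
align_subst <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- ifelse(IUPAC_COMPAT, ALIGN_MATCH, ALIGN_MISMATCH)
    m
  }
})

# One oriented pass: every position of `a` is consumed; `b` may donate free
# leading/trailing overhangs. Returns matches and columns of the optimal
# aligned span.
.semiglobal_pass <- function(ca, cb) {
  SUB <- align_subst()
  n <- length(ca); m <- length(cb)
  H <- matrix(0, n + 1L, m + 1L)
  H[, 1L] <- ALIGN_GAP * 0:n           # consuming `a` against gaps costs
  j_idx <- seq_len(m)
  for (i in seq_len(n)) {
    prev <- H[i, ]
    srow <- SUB[ca[i], cb]
    best <- pmax(prev[j_idx] + srow,              # diagonal
                 prev[j_idx + 1L] + ALIGN_GAP)    # up (gap in b)
    # left moves (gap in a) chain along j:
    # cur[j] = max(best[j], cur[j - 1] + ALIGN_GAP), solved with a
    # cumulative maximum on gap-corrected scores.
    t <- cummax(c(H[i + 1L, 1L], best - ALIGN_GAP * j_idx))
    H[i + 1L, j_idx + 1L] <- t[j_idx + 1L] + ALIGN_GAP * j_idx
  }
  # end in the last row; largest j on ties
  last <- H[n + 1L, ]
  ej <- which.max(rev(last))
  ej <- m + 1L - ej
  i <- n; j <- ej
  matches <- 0L; columns <- 0L
  while (i > 0L) {
    if (j > 0L) {
      h <- H[i + 1L, j + 1L]
      s <- SUB[ca[i], cb[j]]
      if (h == H[i, j] + s) {
        matches <- matches + (s == ALIGN_MATCH)
        i <- i - 1L; j <- j - 1L
      } else if (h == H[i, j + 1L] + ALIGN_GAP) {
        i <- i - 1L
      } else {
        j <- j - 1L
      }
    } else {
      i <- i - 1L                       # a aligned to leading gaps
    }
    columns <- columns + 1L
  }
  list(matches = matches, columns = columns)
}

# Full alignment of two validated uppercase sequences; shorter sequence is
# the fully-consumed one. Returns matches, columns and identity.
semiglobal_align <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  if (length(ca) > length(cb)) {
    tmp <- ca; ca <- cb; cb <- tmp
  }
  r <- .semiglobal_pass(ca, cb)
  if (length(ca) == length(cb)) {
    r2 <- .semiglobal_pass(cb, ca)
    if (r2$matches / r2$columns > r$matches / r$columns) r <- r2
  }
  identity <- if (r$columns == 0L) 0 else 100 * r$matches / r$columns
  list(matches = r$matches, columns = r$columns, identity = identity)
}

#' Percent identity between two nucleotide sequences
#'
#' Identity from an end-gap-free (semi-global) optimal alignment:
#' `100 * matches / alignment columns` over the aligned span. Internal gaps
#' count as non-matching columns; terminal overhangs are excluded. IUPAC
#' ambiguity codes match when their base sets intersect.
#'
#' @param seq_a,seq_b Nucleotide strings (IUPAC alphabet, non-empty).
#' @return Percent identity in `[0, 100]`. Symmetric in its arguments.
#' @export
#' @examples
#' percent_identity("ACGTACGT", "ACGTACGT")
#' percent_identity("ACGTACGTAC", "ACGTTCGTAC")
percent_identity <- function(seq_a, seq_b) {
  a <- check_sequence(seq_a, "seq_a")
  b <- check_sequence(seq_b, "seq_b")
  semiglobal_align(a, b)$identity
}

# ---- k-mer utilities (shared with the bootstrap classifier) ----

# Integer codes (base-4) of all k-mers of a sequence; k-mers containing
# ambiguity codes are dropped. Returns an integer vector (possibly empty).
kmer_codes <- function(seq, k = 8L) {
  v <- match(seq_chars(seq), c("A", "C", "G", "T")) - 1L
  L <- length(v)
  if (L < k) return(integer(0))
  windows <- stats::embed(v, k)  # rows are reversed windows
  codes <- as.integer(windows %*% 4L^(0:(k - 1L)))
  codes[!is.na(codes)]
}

# Shared distinct-k-mer counts between one query and a list of reference
# k-mer sets (used as a candidate prefilter for nearest-neighbour search).
shared_kmer_counts <- function(query_codes, ref_code_sets) {
  q <- unique(query_codes)
  vapply(ref_code_sets, function(r) sum(q %in% r), integer(1))
}

#' Nearest neighbour of a query sequence in a reference set
#'
#' Finds the maximum-identity reference for a query under
#' [percent_identity()]. Ties are broken by lexicographically smallest
#' accession; `tie_count` reports how many references achieve the best
#' identity.
#'
#' @param query A single nucleotide string, or a list/one-row data.frame with
#'   `accession` and `sequence`.
#' @param db A reference set: data.frame with columns `accession` and
#'   `sequence` (accessions unique).
#' @param prefilter Optional integer: align only the `prefilter` candidates
#'   sharing the most distinct 8-mers with the query (plus ties at the
#'   cutoff), a usearch-style heuristic. Default `NULL` aligns against every
#'   reference (exact). With a prefilter, `tie_count` covers scanned
#'   candidates only.
#' @return A one-row data.frame: `query`, `accession` (best hit), `identity`,
#'   `tie_count`.
#' @export
nearest_neighbor <- function(query, db, prefilter = NULL) {
  if (is.list(query) && !is.null(query$sequence)) {
    qseq <- query$sequence[[1]]
    qacc <- query$accession %||% NA_character_
    qacc <- qacc[[1]]
  } else {
    qseq <- query
    qacc <- NA_character_
  }
  qseq <- check_sequence(qseq, "query")
  if (!is.data.frame(db) || nrow(db) == 0)
    abort_input("db must be a non-empty reference set")
  cand <- db
  if (!is.null(prefilter) && prefilter < nrow(db)) {
    sets <- lapply(db$sequence, function(s) unique(kmer_codes(toupper(s))))
    shared <- shared_kmer_counts(kmer_codes(qseq), sets)
    cutoff <- sort(shared, decreasing = TRUE)[prefilter]
    cand <- db[shared >= cutoff, , drop = FALSE]
  }
  ids <- vapply(cand$sequence,
                function(s) semiglobal_align(qseq, toupper(s))$identity,
                numeric(1), USE.NAMES = FALSE)
  best <- max(ids)
  hits <- which(ids >= best - 1e-9)
  accs <- sort(cand$accession[hits])
  data.frame(query = qacc, accession = accs[1], identity = best,
             tie_count = length(hits), stringsAsFactors = FALSE)
}
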