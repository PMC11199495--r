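# Reference-database expansion: novelty classification against per-rank
# identity thresholds, deduplicating merge, placeholder taxonomy and
# before/after taxa inventories.
#
# A reference set is a data.frame with columns `accession` and `sequence`,
# and (where taxonomy is needed) the seven rank columns kingdom..species.

#' Per-rank 16S identity thresholds
#'
#' Minimum percent identity for two 16S rRNA gene sequences to plausibly
#' share a taxon at each rank, after Yarza and co-workers: phylum 75.0,
#' class 78.5, order 82.0, family 86.5, genus 94.5, species 98.7. A query
#' whose best database identity falls below a rank's threshold lacks a
#' homolog at that rank.
#'
#' @param phylum,class,order,family,genus,species Threshold percentages;
#'   must be strictly increasing from phylum to species, all in (0, 100].
#' @return Named numeric vector of length 6 (phylum..species).
#' @export
#' @examples
#' yarza_thresholds()
yarza_thresholds <- function(phylum = 75.0, class = 78.5, order = 82.0,
                             family = 86.5, genus = 94.5, species = 98.7) {
  th <- c(phylum = phylum, class = class, order = order,
          family = family, genus = genus, species = species)
  if (any(th <= 0) || any(th > 100))
    abort_input("thresholds must be in (0, 100]")
  if (any(diff(th) <= 0))
    abort_input("thresholds must strictly increase from phylum to species")
  th
}

#' Classify the sequence novelty of a query from its best-hit identity
#'
#' Returns the most inclusive (highest) taxonomic rank at which the query
#' lacks a homolog: identity strictly below a rank's threshold means no
#' homolog at that rank. At or above the species threshold the query is not
#' novel (`"none"`). Vectorized over `identity`.
#'
#' @param identity Percent identity to the closest database relative, in
#'   `[0, 100]`.
#' @param thresholds Output of [yarza_thresholds()].
#' @return Character vector over
#'   `c("phylum_novel", ..., "species_novel", "none")`.
#' @export
#' @examples
#' classify_novelty(c(100, 93, 74.9))
classify_novelty <- function(identity, thresholds = yarza_thresholds()) {
  if (any(is.na(identity)) || any(identity < 0) || any(identity > 100))
    abort_input("identity must be in [0, 100]")
  out <- rep("none", length(identity))
  # Highest rank first: phylum is the most inclusive novelty call.
  for (rank in names(thresholds)) {
    hit <- out == "none" & identity < thresholds[[rank]]
    out[hit] <- paste0(rank, "_novel")
  }
  out
}

#' Cumulative per-rank novelty summary from precomputed identities
#'
#' Row convention: a sequence below a rank's threshold is counted in that
#' rank's row and in every less inclusive row below it, so counts increase
#' from phylum to species (the species row holds every sequence without a
#' species-level homolog).
#'
#' @param identities Percent identities of each incoming sequence to its
#'   closest database relative.
#' @param thresholds Output of [yarza_thresholds()].
#' @return data.frame with `rank`, `threshold`, `count`, `percentage`
#'   (of incoming, rounded to 2 decimals).
#' @export
novelty_summary_from_identities <- function(identities,
                                            thresholds = yarza_thresholds()) {
  if (length(identities) == 0)
    abort_input("no identities supplied")
  if (any(identities < 0) || any(identities > 100))
    abort_input("identity must be in [0, 100]")
  counts <- vapply(thresholds, function(t) sum(identities < t), integer(1))
  data.frame(rank = names(thresholds),
             threshold = unname(thresholds),
             count = unname(counts),
             percentage = round2(100 * unname(counts) / length(identities)),
             stringsAsFactors = FALSE)
}

#' Per-rank novelty summary of an incoming set against a database
#'
#' Computes each incoming sequence's nearest-neighbour identity in `db`
#' and tabulates cumulative novelty counts per rank
#' (see [novelty_summary_from_identities()]).
#'
#' @param incoming,db Reference sets (data.frames with `accession`,
#'   `sequence`); `incoming` non-empty.
#' @param thresholds Output of [yarza_thresholds()].
#' @param prefilter Passed to [nearest_neighbor()].
#' @return data.frame with `rank`, `threshold`, `count`, `percentage`.
#' @export
summarize_novelty <- function(incoming, db, thresholds = yarza_thresholds(),
                              prefilter = NULL) {
  if (!is.data.frame(incoming) || nrow(incoming) == 0)
    abort_input("incoming set is empty")
  ids <- vapply(seq_len(nrow(incoming)), function(i)
    nearest_neighbor(incoming$sequence[i], db, prefilter = prefilter)$identity,
    numeric(1))
  novelty_summary_from_identities(ids, thresholds)
}

# ---- deduplicating merge ----

#' Merge an incoming reference set into an existing one, dropping duplicates
#'
#' An incoming record is a duplicate iff it has 100% identity with an
#' already-retained record of equal (ungapped) length; with equal lengths
#' and end-gap-free alignment this is exactly per-position IUPAC-set
#' compatibility, which is how it is tested. Existing records are always
#' retained and take precedence; incoming records are scanned in input
#' order. Exact substring containment of an added record in a retained one
#' (or vice versa) is counted as a warning, not collapsed.
#'
#' @param existing,incoming Reference sets (data.frames with `accession`,
#'   `sequence`, accessions unique within each set). Taxonomy columns, if
#'   present, are carried through.
#' @param check_containment Count substring containment warnings
#'   (quadratic scan; disable for large merges).
#' @return A list with `merged` (data.frame; existing rows first, gaining a
#'   `source` column of `"existing"`/`"new"`) and `report`
#'   (`n_existing`, `n_incoming`, `n_duplicates`, `n_added`,
#'   `n_containment_warnings`).
#' @export
merge_dereplicate <- function(existing, incoming, check_containment = TRUE) {
  for (nm in c("existing", "incoming")) {
    s <- get(nm)
    if (!is.data.frame(s) || is.null(s$accession) || is.null(s$sequence))
      abort_input(nm, " must be a data.frame with accession and sequence")
    if (anyDuplicated(s$accession))
      abort_input("duplicate accessions within ", nm, " set")
  }
  existing$sequence <- toupper(existing$sequence)
  incoming$sequence <- toupper(incoming$sequence)

  clash <- intersect(existing$accession, incoming$accession)
  for (acc in clash) {
    a <- existing$sequence[existing$accession == acc]
    b <- incoming$sequence[incoming$accession == acc]
    if (!iupac_equal(a, b))
      abort_input("accession collision with differing sequences: ", acc)
  }

  has_ambig <- function(s) grepl("[^ACGT]", s)
  retained_seqs <- existing$sequence
  retained_len <- nchar(retained_seqs)
  keep <- logical(nrow(incoming))
  inc_len <- nchar(incoming$sequence)
  for (i in seq_len(nrow(incoming))) {
    s <- incoming$sequence[i]
    cand <- retained_seqs[retained_len == inc_len[i]]
    dup <- s %in% cand
    if (!dup && length(cand) > 0 && (has_ambig(s) || any(has_ambig(cand))))
      dup <- any(vapply(cand, iupac_equal, logical(1), a = s))
    if (!dup) {
      keep[i] <- TRUE
      retained_seqs <- c(retained_seqs, s)
      retained_len <- c(retained_len, inc_len[i])
    }
  }

  added <- incoming[keep, , drop = FALSE]
  n_contain <- 0L
  if (check_containment && nrow(added) > 0 && nrow(existing) > 0) {
    for (i in seq_len(nrow(added))) {
      s <- added$sequence[i]
      hit <- grepl(s, existing$sequence, fixed = TRUE) |
             vapply(existing$sequence, grepl, logical(1), x = s, fixed = TRUE)
      n_contain <- n_contain + sum(hit & nchar(existing$sequence) != nchar(s))
    }
    if (n_contain > 0)
      warning(n_contain,
              " added/retained record pair(s) related by substring containment",
              call. = FALSE)
  }

  existing$source <- if (nrow(existing)) "existing" else character(0)
  added$source <- if (nrow(added)) "new" else character(0)
  common <- union(names(existing), names(added))
  for (nm in setdiff(common, names(existing))) existing[[nm]] <- NA
  for (nm in setdiff(common, names(added))) added[[nm]] <- NA
  merged <- rbind(existing[common], added[common])
  rownames(merged) <- NULL
  list(merged = merged,
       report = list(n_existing = nrow(existing),
                     n_incoming = nrow(incoming),
                     n_duplicates = nrow(incoming) - nrow(added),
                     n_added = nrow(added),
                     n_containment_warnings = n_contain))
}

# ---- placeholder taxonomy ----

#' Create a placeholder-name registry
#'
#' Holds the next free integer per rank and the greedy-cluster centroids
#' that make placeholder names reusable across queries. Mutable; pass the
#' same registry to successive [assign_taxonomy()] calls.
#'
#' @param start First integer to mint at every rank.
#' @param prefix Name prefix (default `"midas"`).
#' @return An environment of class `placeholder_registry`.
#' @export
placeholder_registry <- function(start = 1L, prefix = "midas") {
  reg <- new.env(parent = emptyenv())
  reg$prefix <- prefix
  reg$counter <- setNames(rep(as.integer(start), 7L), TAX_RANKS)
  # Per rank: parallel lists of centroid sequences and minted names,
  # in minting order.
  reg$centroids <- setNames(vector("list", 7L), TAX_RANKS)
  reg$names <- setNames(vector("list", 7L), TAX_RANKS)
  class(reg) <- "placeholder_registry"
  reg
}

# Name for a query at one rank: reuse the first greedy cluster whose
# centroid is within the rank threshold, else mint a fresh placeholder
# with the query as the new centroid.
placeholder_name <- function(registry, rank, query_seq, threshold) {
  cents <- registry$centroids[[rank]]
  if (length(cents) > 0) {
    for (ci in seq_along(cents)) {
      if (semiglobal_align(query_seq, cents[[ci]])$identity >= threshold)
        return(registry$names[[rank]][[ci]])
    }
  }
  n <- registry$counter[[rank]]
  registry$counter[[rank]] <- n + 1L
  name <- paste0(registry$prefix, "_", RANK_LETTERS[[rank]], "_", n)
  registry$centroids[[rank]] <- c(cents, list(query_seq))
  registry$names[[rank]] <- c(registry$names[[rank]], list(name))
  name
}

#' Assign a seven-rank taxonomy to a query sequence
#'
#' The query inherits its nearest neighbour's name at every rank whose
#' identity threshold it meets (kingdom is always inherited); from the
#' first failing rank downward it receives placeholder names
#' `midas_<r>_<n>`. Placeholders are reused for later queries falling in
#' the same greedy cluster (first-minting query is the centroid; membership
#' iff identity to centroid >= the rank threshold), so numbering is a
#' deterministic function of query input order.
#'
#' @param query A nucleotide string or list/row with `sequence`.
#' @param db Reference set with complete taxonomy columns kingdom..species.
#' @param thresholds Output of [yarza_thresholds()].
#' @param registry A [placeholder_registry()] (mutated in place).
#' @param prefilter Passed to [nearest_neighbor()].
#' @return A list: `ranks` (named 7-vector), `placeholder` (named logical
#'   7-vector), `identity`, `nearest` (accession of the best hit).
#' @export
assign_taxonomy <- function(query, db, thresholds = yarza_thresholds(),
                            registry = placeholder_registry(),
                            prefilter = NULL) {
  qseq <- if (is.list(query) && !is.null(query$sequence)) query$sequence[[1]]
          else query
  qseq <- check_sequence(qseq, "query")
  tm <- tax_matrix(db)
  hit <- nearest_neighbor(qseq, db, prefilter = prefilter)
  nn_ranks <- tm[match(hit$accession, db$accession), ]
  ranks <- setNames(character(7L), TAX_RANKS)
  ph <- setNames(logical(7L), TAX_RANKS)
  ranks["kingdom"] <- nn_ranks[["kingdom"]]
  for (rank in names(thresholds)) {
    if (hit$identity >= thresholds[[rank]]) {
      ranks[rank] <- nn_ranks[[rank]]
    } else {
      ranks[rank] <- placeholder_name(registry, rank, qseq, thresholds[[rank]])
      ph[rank] <- TRUE
    }
  }
  list(ranks = ranks, placeholder = ph,
       identity = hit$identity, nearest = hit$accession)
}

#' Taxa inventory change between two database versions
#'
#' Distinct (non-blank) names per rank in the updated database, how many of
#' them are absent from the previous version, and the percent increase
#' `100 * new / (total - new)` (undefined, `NA`, when every name is new).
#'
#' @param db_before,db_after Reference sets with taxonomy columns.
#' @return data.frame with `rank`, `total`, `new`, `pct_increase`
#'   (1 decimal).
#' @export
taxa_inventory_delta <- function(db_before, db_after) {
  tb <- tax_matrix(db_before)
  ta <- tax_matrix(db_after)
  rows <- lapply(TAX_RANKS, function(rank) {
    before <- setdiff(unique(tb[, rank]), "")
    after <- setdiff(unique(ta[, rank]), "")
    total <- length(after)
    new <- length(setdiff(after, before))
    pct <- if (total == new) NA_real_ else round1(100 * new / (total - new))
    data.frame(rank = rank, total = total, new = new, pct_increase = pct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
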