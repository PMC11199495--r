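# Database-coverage and classification-rate evaluation of short-read ASV
# sets: per-sample rare-biosphere filtering, high-identity hit fractions,
# a k-mer bootstrap (SINTAX-style) taxonomic classifier, and per-sample
# classification rates.

#' Default evaluation filter parameters
#'
#' @param min_rel_abund Rare-biosphere cutoff: minimum per-sample relative
#'   abundance (fraction) for an ASV to be retained. Default 0.0001
#'   (0.01%).
#' @param high_identity High-identity hit cutoff (percent identity to the
#'   nearest reference). Default 99.
#' @param confidence Bootstrap confidence cutoff for retaining a rank.
#'   Default 0.8.
#' @param min_depth Minimum reads for a sample to be analysed. Default
#'   10000.
#' @return A named list.
#' @export
filter_params <- function(min_rel_abund = 1e-04, high_identity = 99,
                          confidence = 0.8, min_depth = 10000) {
  stopifnot(min_rel_abund >= 0, min_rel_abund <= 1,
            high_identity >= 0, high_identity <= 100,
            confidence > 0, confidence <= 1, min_depth >= 1)
  list(min_rel_abund = min_rel_abund, high_identity = high_identity,
       confidence = confidence, min_depth = min_depth)
}

#' Per-sample relative abundances
#'
#' @param counts Integer matrix, samples x features.
#' @return Numeric matrix of per-sample fractions (rows sum to 1).
#' @export
relative_abundance <- function(counts) {
  counts <- as.matrix(counts)
  totals <- rowSums(counts)
  zero <- totals == 0
  if (any(zero))
    abort_input("zero-total sample(s): ",
                paste(rownames(counts)[zero], collapse = ", "))
  sweep(counts, 1, totals, "/")
}

#' Rare-biosphere filter
#'
#' Masks, per sample, every feature below the minimum relative abundance
#' (strictly below: features at exactly the cutoff are kept). Masking is
#' per sample, not table-wide: a feature can be retained in one sample and
#' removed in another.
#'
#' @param counts Integer matrix, samples x features.
#' @param params [filter_params()].
#' @return A list: `counts` (masked matrix) and `retained_fraction`
#'   (per-sample fraction of reads kept).
#' @export
filter_rare <- function(counts, params = filter_params()) {
  counts <- as.matrix(counts)
  rel <- relative_abundance(counts)
  keep <- rel >= params$min_rel_abund
  out <- counts
  out[!keep] <- 0L
  list(counts = out, retained_fraction = rowSums(out) / rowSums(counts))
}

#' Per-sample percentage of ASVs with a high-identity database hit
#'
#' For each sample, the percentage of retained (post rare-filter) ASVs
#' whose nearest-neighbour identity in the reference database is at least
#' the high-identity cutoff. ASVs are weighted equally, not by abundance;
#' a sample with zero retained ASVs gets `NA`.
#'
#' @param counts Rare-filtered count matrix (samples x ASVs).
#' @param asv_seqs Named character vector: sequence per ASV id (must cover
#'   every ASV with a nonzero count).
#' @param db Reference set (data.frame with `accession`, `sequence`).
#' @param params [filter_params()].
#' @param prefilter Passed to [nearest_neighbor()].
#' @return Named numeric vector of per-sample percentages.
#' @export
high_identity_fraction <- function(counts, asv_seqs, db,
                                   params = filter_params(),
                                   prefilter = NULL) {
  counts <- as.matrix(counts)
  used <- colnames(counts)[colSums(counts) > 0]
  missing <- setdiff(used, names(asv_seqs))
  if (length(missing) > 0)
    abort_input("no sequence for ASV(s): ", paste(missing, collapse = ", "))
  ids <- vapply(asv_seqs[used], function(s)
    nearest_neighbor(s, db, prefilter = prefilter)$identity, numeric(1))
  high <- ids >= params$high_identity
  vapply(rownames(counts), function(s) {
    present <- used[counts[s, used] > 0]
    if (length(present) == 0) return(NA_real_)
    100 * sum(high[present]) / length(present)
  }, numeric(1))
}

# ---- k-mer bootstrap classifier ----

#' Build a k-mer index over a reference database
#'
#' Stores each reference's set of distinct k-mers (default 8-mers) plus
#' its taxonomy, for use by [classify_kmer_bootstrap()].
#'
#' @param db Reference set with taxonomy columns kingdom..species.
#' @param k k-mer size.
#' @return A list of class `kmer_index`.
#' @export
build_kmer_index <- function(db, k = 8L) {
  tm <- tax_matrix(db)
  sets <- lapply(db$sequence, function(s) unique(kmer_codes(toupper(s), k)))
  structure(list(accession = db$accession, taxonomy = tm, sets = sets, k = k),
            class = "kmer_index")
}

#' Bootstrap k-mer taxonomy classification of one ASV
#'
#' SINTAX-style classifier: each of `n_boot` bootstrap iterations draws
#' `subsample` of the query's distinct k-mers with replacement and votes
#' for the reference sharing most of the drawn k-mers (ties resolve to the
#' lexicographically smallest accession). The per-rank confidence is the
#' fraction of bootstraps whose winner carries the top reference's name at
#' that rank; ranks at or above the confidence cutoff are retained, deeper
#' ranks are blanked. Both strands are evaluated and the strand whose best
#' full (non-subsampled) shared k-mer count is larger is classified.
#' Deterministic under `seed`.
#'
#' @param query ASV nucleotide string (length >= k).
#' @param index A [build_kmer_index()].
#' @param params [filter_params()] (supplies the confidence cutoff).
#' @param seed Optional integer seed.
#' @param n_boot Bootstrap iterations (default 100).
#' @param subsample k-mers drawn per iteration (default 32).
#' @return A list: `ranks` (named 7-vector, blanked below the confidence
#'   cutoff), `confidence` (named numeric 7-vector), `strand`
#'   (`"+"`/`"-"`), `best` (winning accession).
#' @export
classify_kmer_bootstrap <- function(query, index, params = filter_params(),
                                    seed = NULL, n_boot = 100L,
                                    subsample = 32L) {
  stopifnot(inherits(index, "kmer_index"))
  query <- check_sequence(query, "query")
  if (nchar(query) < index$k)
    abort_input("query shorter than k = ", index$k)
  fwd <- unique(kmer_codes(query, index$k))
  rvs <- unique(kmer_codes(reverse_complement(query), index$k))
  shared_f <- shared_kmer_counts(fwd, index$sets)
  shared_r <- shared_kmer_counts(rvs, index$sets)
  if (max(shared_r) > max(shared_f)) {
    kmers <- rvs; strand <- "-"
  } else {
    kmers <- fwd; strand <- "+"
  }
  if (length(kmers) == 0)
    abort_input("query contains no unambiguous k-mers")
  n_ref <- length(index$sets)
  # membership[r, q]: is query k-mer q present in reference r?
  membership <- vapply(seq_along(kmers), function(qi)
    vapply(index$sets, function(s) kmers[qi] %in% s, logical(1)),
    logical(n_ref))
  membership <- matrix(membership, nrow = n_ref)
  acc_order <- order(index$accession)  # lexicographic tie-break
  winners <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      draw <- sample.int(length(kmers), subsample, replace = TRUE)
      votes <- rowSums(membership[, draw, drop = FALSE])
      cand <- acc_order[votes[acc_order] == max(votes)]
      cand[1]
    }, integer(1))
  })
  # Deterministic top pick on ties: most bootstrap wins, then accession.
  tab <- table(factor(winners, levels = acc_order))
  best_n <- max(tab)
  top <- as.integer(names(tab)[tab == best_n][1])
  top_ranks <- index$taxonomy[top, ]
  win_tax <- index$taxonomy[winners, , drop = FALSE]
  confidence <- vapply(TAX_RANKS, function(r)
    mean(win_tax[, r] == top_ranks[[r]]), numeric(1))
  ranks <- setNames(character(7L), TAX_RANKS)
  ok <- TRUE
  for (r in TAX_RANKS) {
    ok <- ok && confidence[[r]] >= params$confidence
    if (ok) ranks[r] <- top_ranks[[r]]
  }
  list(ranks = ranks, confidence = confidence, strand = strand,
       best = index$accession[top])
}

#' Classify a set of ASVs
#'
#' Applies [classify_kmer_bootstrap()] to each sequence, with a
#' per-sequence seed derived from `seed` so results do not depend on the
#' order of classification.
#'
#' @param asv_seqs Named character vector of ASV sequences.
#' @param index A [build_kmer_index()].
#' @param params,n_boot,subsample Passed through.
#' @param seed Integer seed.
#' @return data.frame: `asv`, the seven rank columns, `strand`, `best`.
#' @export
classify_asvs <- function(asv_seqs, index, params = filter_params(),
                          seed = 1, n_boot = 100L, subsample = 32L) {
  rows <- lapply(seq_along(asv_seqs), function(i) {
    cl <- classify_kmer_bootstrap(asv_seqs[[i]], index, params,
                                  seed = seed + i, n_boot = n_boot,
                                  subsample = subsample)
    cbind(data.frame(asv = names(asv_seqs)[i], stringsAsFactors = FALSE),
          as.data.frame(as.list(cl$ranks), stringsAsFactors = FALSE),
          data.frame(strand = cl$strand, best = cl$best,
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Per-sample classification rate at a rank
#'
#' Percentage of retained ASVs in each sample with a non-blank name at the
#' requested rank. ASVs are weighted equally. Samples with zero retained
#' ASVs get `NA`.
#'
#' @param counts Rare-filtered count matrix (samples x ASVs).
#' @param classifications Output of [classify_asvs()] covering every ASV
#'   with a nonzero count.
#' @param rank One of kingdom..species.
#' @return Named numeric vector of per-sample percentages.
#' @export
classification_rate <- function(counts, classifications, rank = "genus") {
  rank <- match.arg(rank, TAX_RANKS)
  counts <- as.matrix(counts)
  used <- colnames(counts)[colSums(counts) > 0]
  missing <- setdiff(used, classifications$asv)
  if (length(missing) > 0)
    abort_input("unclassified ASV(s): ", paste(missing, collapse = ", "))
  named <- setNames(nzchar(classifications[[rank]]), classifications$asv)
  vapply(rownames(counts), function(s) {
    present <- used[counts[s, used] > 0]
    if (length(present) == 0) return(NA_real_)
    100 * sum(named[present]) / length(present)
  }, numeric(1))
}
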