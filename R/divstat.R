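# Diversity statistics: rarefaction, alpha metrics, Bray-Curtis
# dissimilarity, principal coordinate analysis and marginal (single
# factor) permutation PERMANOVA. Standard computations delegate to vegan
# and stats; this module adds the contracts used by the rest of the
# pipeline: depth-based sample exclusion, deterministic seeding, a fixed
# PCoA sign convention and per-factor marginal testing.

#' Diversity analysis parameters
#'
#' @param depth Rarefaction depth in reads (default 10000; samples below
#'   it are excluded).
#' @param permutations Label permutations for PERMANOVA (default 999).
#' @param seed Integer seed used by rarefaction and permutation tests.
#' @return A named list.
#' @export
diversity_params <- function(depth = 10000, permutations = 999, seed = 1) {
  stopifnot(depth >= 1, permutations >= 1)
  list(depth = as.integer(depth), permutations = as.integer(permutations),
       seed = seed)
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`.
#' Samples with fewer than `depth` reads are excluded (ids attached as
#' attribute `"excluded"`, with a message). Deterministic under `seed`.
#'
#' @param counts Integer matrix, samples x features.
#' @param depth Target depth.
#' @param seed Integer seed.
#' @return Rarefied integer matrix (possibly fewer rows), attribute
#'   `excluded` naming dropped samples.
#' @export
rarefy_counts <- function(counts, depth = 10000, seed = 1) {
  counts <- as.matrix(counts)
  totals <- rowSums(counts)
  drop <- totals < depth
  if (any(drop))
    message("excluding ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(rownames(counts)[drop], collapse = ", "))
  kept <- counts[!drop, , drop = FALSE]
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(kept, depth),
    # vegan warns when counts contain no singletons (a heuristic for
    # scaled data); simulated tables trip it spuriously.
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  structure(out, excluded = rownames(counts)[drop])
}

#' Alpha diversity: observed richness and inverse Simpson
#'
#' Richness is the number of features with a nonzero count; inverse
#' Simpson is `1 / sum(p_i^2)` over the nonzero features' relative
#' abundances. Counts should be rarefied to a common depth first.
#'
#' @param counts Integer matrix, samples x features; no all-zero samples.
#' @return data.frame: `sample`, `richness`, `inv_simpson`.
#' @export
alpha_diversity <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0))
    abort_input("all-zero sample(s) in alpha diversity input")
  data.frame(sample = rownames(counts),
             richness = unname(rowSums(counts > 0)),
             inv_simpson = unname(vegan::diversity(counts, "invsimpson")),
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = 1 - 2 * sum(min(a_i, b_i)) / sum(a_i + b_i)` on the supplied
#' (typically rank-aggregated, relative) abundances.
#'
#' @param x Numeric matrix, samples x features, >= 2 samples.
#' @return A `dist` object.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort_input("need at least 2 samples")
  vegan::vegdist(x, method = "bray")
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centering plus eigendecomposition via [stats::cmdscale()]. Axes
#' are ordered by eigenvalue; explained variance is relative to the sum of
#' positive eigenvalues; negative eigenvalues are reported, not corrected.
#' Axis signs follow a deterministic convention: the largest-magnitude
#' coordinate on each axis is positive.
#'
#' @param d A `dist` or symmetric matrix of dissimilarities.
#' @param k Number of axes (default all positive-eigenvalue axes).
#' @return A list: `coordinates` (samples x axes), `eigenvalues` (all,
#'   including negatives), `explained` (fraction per returned axis).
#' @export
pcoa_ord <- function(d, k = NULL) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) abort_input("distance matrix not symmetric")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  # k = n - 1 requests every axis; cmdscale warns when some have
  # non-positive eigenvalues, which is expected for semimetric input.
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig > 1e-12)
  coords <- fit$points[, seq_len(min(pos, ncol(fit$points))), drop = FALSE]
  if (!is.null(k)) coords <- coords[, seq_len(min(k, ncol(coords))), drop = FALSE]
  for (a in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, a]))
    if (coords[i, a] < 0) coords[, a] <- -coords[, a]
  }
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig,
       explained = eig[seq_len(ncol(coords))] / sum(eig[eig > 0]))
}

#' Marginal PERMANOVA per factor
#'
#' Tests each metadata factor in isolation against a dissimilarity matrix
#' (Anderson's distance-based pseudo-F, via [vegan::adonis2()]). The
#' p-value uses the `(1 + #{F* >= F}) / (1 + permutations)` estimator.
#' With `exhaustive = TRUE` every label permutation is enumerated instead
#' of sampled (only for small n). Deterministic under the params seed.
#'
#' @param d A `dist` of dissimilarities.
#' @param metadata data.frame with a `sample` column matching the
#'   dissimilarity labels plus the factor columns.
#' @param factors Character vector of factor column names.
#' @param params [diversity_params()].
#' @param exhaustive Enumerate all permutations (requires `n! <= 50000`).
#' @return data.frame: `factor`, `df`, `R2`, `F`, `p`.
#' @export
permanova_marginal <- function(d, metadata, factors,
                               params = diversity_params(),
                               exhaustive = FALSE) {
  labs <- attr(d, "Labels") %||% labels(d)
  meta <- metadata[match(labs, metadata$sample), , drop = FALSE]
  if (any(is.na(meta$sample)))
    abort_input("metadata missing for some samples in the distance matrix")
  n <- length(labs)
  perm <- if (exhaustive) {
    if (factorial(n) > 50000)
      abort_input("exhaustive enumeration infeasible for n = ", n)
    all_permutations(n)
  } else params$permutations
  rows <- lapply(factors, function(f) {
    g <- meta[[f]]
    if (length(unique(g)) < 2) abort_input("constant factor: ", f)
    if (any(table(g) < 2)) abort_input("factor ", f, " has a group of size < 2")
    dat <- data.frame(g = factor(g))
    fit <- with_seed(params$seed,
      vegan::adonis2(d ~ g, data = dat, permutations = perm, by = "terms"))
    data.frame(factor = f, df = fit$Df[1], R2 = fit$R2[1], F = fit$F[1],
               p = fit$`Pr(>F)`[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# All n! permutations of 1..n as a matrix (rows = permutations),
# excluding none; used for exact enumeration at small n.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}
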