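# Independent brute-force oracles. These deliberately use plain nested
# loops and explicit enumeration, no shared code with the package beyond
# the published scoring constants, so agreement is a real check.

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

oracle_compat_tab <- local({
  codes <- names(oracle_iupac)
  m <- matrix(NA, length(codes), length(codes), dimnames = list(codes, codes))
  for (x in codes) for (y in codes)
    m[x, y] <- length(intersect(oracle_iupac[[x]], oracle_iupac[[y]])) > 0
  m
})

oracle_compat <- function(a, b) oracle_compat_tab[a, b]

# Naive semi-global DP oracle: match +1 / mismatch -1 / gap -2; the
# shorter sequence is consumed end to end, the longer donates free
# terminal overhangs. Alignment ends at the best last-row cell (largest
# column on ties); traceback prefers diagonal, then up, then left. For
# equal lengths both orientations are tried and the larger identity wins.
# Returns identity = 100 * matches / columns over the aligned span.
oracle_align_identity <- function(a, b) {
  pass <- function(ca, cb) {
    n <- length(ca); m <- length(cb)
    H <- matrix(0, n + 1, m + 1)
    for (i in 1:n) H[i + 1, 1] <- -2 * i
    for (i in 1:n) {
      for (j in 1:m) {
        s <- if (oracle_compat(ca[i], cb[j])) 1 else -1
        H[i + 1, j + 1] <- max(H[i, j] + s, H[i, j + 1] - 2, H[i + 1, j] - 2)
      }
    }
    best_j <- m
    for (j in m:0) if (H[n + 1, j + 1] > H[n + 1, best_j + 1]) best_j <- j
    i <- n; j <- best_j
    matches <- 0; columns <- 0
    while (i > 0) {
      if (j > 0) {
        s <- if (oracle_compat(ca[i], cb[j])) 1 else -1
        if (H[i + 1, j + 1] == H[i, j] + s) {
          if (s == 1) matches <- matches + 1
          i <- i - 1; j <- j - 1
        } else if (H[i + 1, j + 1] == H[i, j + 1] - 2) {
          i <- i - 1
        } else {
          j <- j - 1
        }
      } else {
        i <- i - 1
      }
      columns <- columns + 1
    }
    c(matches = matches, columns = columns)
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (length(ca) > length(cb)) { tmp <- ca; ca <- cb; cb <- tmp }
  r <- pass(ca, cb)
  if (length(ca) == length(cb)) {
    r2 <- pass(cb, ca)
    if (r2[["matches"]] / r2[["columns"]] > r[["matches"]] / r[["columns"]])
      r <- r2
  }
  if (r[["columns"]] == 0) 0 else 100 * r[["matches"]] / r[["columns"]]
}

# Exhaustive primer scoring oracle: enumerate every ungapped offset and
# every single-gap placement explicitly and return the minimum OWS over
# both strands.
oracle_best_ows <- function(primer, template, weights) {
  p <- strsplit(toupper(primer), "")[[1]]
  lp <- length(p)
  w3 <- weights$three_prime_len
  wt_mm <- function(j) if (j > lp - w3) weights$mismatch_3p else weights$mismatch
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  score_pairing <- function(tpos_of_j, tc, gap_cost) {
    ows <- gap_cost
    for (j in seq_len(lp)) {
      tp <- tpos_of_j[j]
      if (!is.na(tp) && !oracle_compat(p[j], tc[tp])) ows <- ows + wt_mm(j)
    }
    ows
  }
  strand_min <- function(tc) {
    lt <- length(tc)
    best <- Inf
    for (f in 0:(lt - lp)) {
      best <- min(best, score_pairing(f + seq_len(lp), tc, 0))
    }
    if (lp >= 3) {
      for (f in 1:(lt - lp)) {
        for (g in 2:(lp - 1)) {         # gap in template at primer pos g
          tpos <- ifelse(seq_len(lp) < g, f + seq_len(lp),
                         ifelse(seq_len(lp) == g, NA, f + seq_len(lp) - 1))
          cost <- if (g > lp - w3) weights$gap_3p else weights$gap
          best <- min(best, score_pairing(tpos, tc, cost))
        }
      }
    }
    if (lt >= lp + 1) {
      for (f in 0:(lt - lp - 1)) {
        for (g in 1:(lp - 1)) {         # gap in primer after pos g
          tpos <- ifelse(seq_len(lp) <= g, f + seq_len(lp), f + seq_len(lp) + 1)
          cost <- if (g + 1 > lp - w3) weights$gap_3p else weights$gap
          best <- min(best, score_pairing(tpos, tc, cost))
        }
      }
    }
    best
  }
  tc_fwd <- strsplit(toupper(template), "")[[1]]
  tc_rev <- rev(unname(comp[tc_fwd]))
  min(strand_min(tc_fwd), strand_min(tc_rev))
}

# Distance-partition pseudo-F and R2 for one grouping (Anderson).
oracle_permanova_F <- function(D, groups) {
  n <- nrow(D)
  sst <- sum(D[upper.tri(D)]^2) / n
  ssw <- 0
  for (lv in unique(groups)) {
    ii <- which(groups == lv)
    for (i in ii) for (j in ii) if (i < j) ssw <- ssw + D[i, j]^2 / length(ii)
  }
  a <- length(unique(groups))
  ssa <- sst - ssw
  list(F = (ssa / (a - 1)) / (ssw / (n - a)), R2 = ssa / sst)
}

# Exclusive intersection patterns by per-taxon enumeration.
oracle_upset <- function(sets) {
  taxa <- unique(unlist(sets))
  out <- list()
  for (t in taxa) {
    members <- names(sets)[vapply(sets, function(s) t %in% s, logical(1))]
    key <- paste(members, collapse = "&")
    out[[key]] <- (out[[key]] %||% 0L) + 1L
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
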