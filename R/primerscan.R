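# In-silico primer evaluation: IUPAC-aware site scoring with 3'-weighted
# mismatch/gap penalties (overall weighted score, OWS), perfect/partial/
# poor categorisation, per-taxon primer-pair coverage and amplicon
# extraction. Coordinates in all outputs are 0-based half-open on the
# forward strand.

#' A PCR primer pair
#'
#' @param name Pair label.
#' @param forward,reverse Primer sequences 5'->3' (the reverse primer as
#'   given on the opposite strand), IUPAC alphabet, length >= 10.
#' @param region Target region label (e.g. `"V4"`).
#' @return A list of class `primer_pair`.
#' @export
#' @examples
#' primer_pair("V4", "GTGYCAGCMGCCGCGGTAA", "GGACTACNVGGGTWTCTAAT")
primer_pair <- function(name, forward, reverse, region = name) {
  forward <- check_sequence(forward, "forward primer")
  reverse <- check_sequence(reverse, "reverse primer")
  if (nchar(forward) < 10 || nchar(reverse) < 10)
    abort_input("primers must be at least 10 nt")
  structure(list(name = name, forward = forward, reverse = reverse,
                 region = region), class = "primer_pair")
}

#' Primer-template scoring weights
#'
#' Overall weighted score (OWS) components: mismatches and gaps are
#' penalised more heavily when they fall in the primer's 3' window, where
#' polymerase extension is most sensitive.
#'
#' @param mismatch,mismatch_3p Weight of a mismatch outside / inside the
#'   3' window (defaults 0.4, 1.0).
#' @param gap,gap_3p Weight of a gap outside / inside the 3' window
#'   (defaults 1.0, 3.0).
#' @param three_prime_len Length of the 3' window (default last 5 bases).
#' @return A named list.
#' @export
primer_score_weights <- function(mismatch = 0.4, mismatch_3p = 1.0,
                                 gap = 1.0, gap_3p = 3.0,
                                 three_prime_len = 5L) {
  stopifnot(mismatch >= 0, gap >= 0, mismatch_3p >= mismatch,
            gap_3p >= gap, three_prime_len >= 1)
  list(mismatch = mismatch, mismatch_3p = mismatch_3p,
       gap = gap, gap_3p = gap_3p, three_prime_len = as.integer(three_prime_len))
}

#' Categorise an overall weighted score
#'
#' Perfect hit: OWS = 0. Partial hit: 0 < OWS <= 1. Poor hit: OWS > 1.
#' Vectorized.
#'
#' @param ows Non-negative overall weighted score(s).
#' @return Character vector over `c("perfect", "partial", "poor")`.
#' @export
categorize_hit <- function(ows) {
  if (any(ows < 0)) abort_input("OWS must be non-negative")
  ifelse(ows == 0, "perfect", ifelse(ows <= 1, "partial", "poor"))
}

# Weighted-mismatch matrix for one strand: rows = primer positions, cols =
# ungapped offsets (0-based); entry = mismatch weight at that position.
.mismatch_matrix <- function(pchars, tchars, weights) {
  lp <- length(pchars); lt <- length(tchars)
  noff <- lt - lp + 1L
  w <- ifelse(seq_len(lp) > lp - weights$three_prime_len,
              weights$mismatch_3p, weights$mismatch)
  M <- matrix(0, lp, noff)
  for (j in seq_len(lp)) {
    tj <- tchars[j:(j + noff - 1L)]
    M[j, ] <- w[j] * !IUPAC_COMPAT[cbind(rep(pchars[j], noff), tj)]
  }
  M
}

# Best hit of one primer on one strand's character vector. Returns the
# minimum-OWS site over all ungapped offsets and all single-gap variants
# within the primer span. Ties resolve to the ungapped variant, then the
# smallest offset.
.scan_strand <- function(pchars, tchars, weights) {
  lp <- length(pchars); lt <- length(tchars)
  if (lt < lp) abort_input("template shorter than primer")
  M <- .mismatch_matrix(pchars, tchars, weights)
  noff <- ncol(M)
  CS <- apply(M, 2, cumsum)
  if (lp == 1L) CS <- matrix(CS, nrow = 1L)
  ungapped <- CS[lp, ]
  w3 <- weights$three_prime_len
  gap_w <- function(in3p) if (in3p) weights$gap_3p else weights$gap
  best <- list(ows = Inf)
  consider <- function(ows, offset, variant, gap_pos, gap_3p) {
    if (ows < best$ows - 1e-12)
      best <<- list(ows = ows, offset = offset, variant = variant,
                    gap_pos = gap_pos, gap_3p = gap_3p)
  }
  o_best <- which.min(ungapped)
  consider(ungapped[o_best], o_best - 1L, "ungapped", NA_integer_, FALSE)
  # Gap in the template opposite primer position g (template span lp - 1):
  # offsets f = 1..lt-lp; prefix (j < g) reads column f + 1, suffix (j > g)
  # column f.
  if (lp >= 3L && noff >= 2L) {
    for (g in 2L:(lp - 1L)) {
      in3p <- g > lp - w3
      f <- seq_len(noff - 1L)
      ows <- CS[g - 1L, f + 1L] + (CS[lp, f] - CS[g, f]) + gap_w(in3p)
      ob <- which.min(ows)
      consider(ows[ob], f[ob], "template_gap", g, in3p)
    }
  }
  # Gap in the primer between positions g and g + 1 (template span lp + 1):
  # offsets f = 0..lt-lp-1; prefix (j <= g) reads column f + 1, suffix
  # (j > g) column f + 2.
  if (noff >= 2L) {
    for (g in seq_len(lp - 1L)) {
      in3p <- (g + 1L) > lp - w3
      f <- 0:(noff - 2L)
      ows <- CS[g, f + 1L] + (CS[lp, f + 2L] - CS[g, f + 2L]) + gap_w(in3p)
      ob <- which.min(ows)
      consider(ows[ob], f[ob], "primer_gap", g, in3p)
    }
  }
  best
}

# Recount mismatch/gap components at a chosen site.
.site_components <- function(pchars, tchars, weights, site) {
  lp <- length(pchars)
  w3 <- weights$three_prime_len
  is3p <- seq_len(lp) > lp - w3
  o <- site$offset
  tpos <- switch(site$variant,
    ungapped = o + seq_len(lp),
    template_gap = {
      v <- integer(lp); g <- site$gap_pos
      v[seq_len(g - 1L)] <- o + seq_len(g - 1L)
      v[g] <- NA_integer_           # opposite the gap
      if (g < lp) v[(g + 1L):lp] <- o + ((g + 1L):lp) - 1L
      v
    },
    primer_gap = {
      g <- site$gap_pos
      c(o + seq_len(g), o + ((g + 1L):lp) + 1L)
    })
  mm <- !is.na(tpos) & !IUPAC_COMPAT[cbind(pchars, tchars[ifelse(is.na(tpos), 1L, tpos)])]
  mm[is.na(tpos)] <- FALSE
  gaps_3p <- gaps_non3p <- 0L
  if (site$variant != "ungapped") {
    if (site$gap_3p) gaps_3p <- 1L else gaps_non3p <- 1L
  }
  list(mismatch_3p = sum(mm & is3p), mismatch = sum(mm & !is3p),
       gap_3p = gaps_3p, gap = gaps_non3p)
}

#' Best weighted hit of a primer on a template
#'
#' Scans every ungapped offset and every single-gap variant within the
#' primer span, on both strands of the template, and returns the
#' minimum-OWS site. Ties resolve to the forward strand, ungapped variant,
#' smallest offset.
#'
#' @param primer Primer sequence 5'->3' (IUPAC).
#' @param template Template sequence (at least as long as the primer).
#' @param weights [primer_score_weights()].
#' @return A list: `ows`, `category`, `strand` (`"+"`/`"-"`), `offset`
#'   (0-based on the scanned strand), `variant`, and mismatch/gap counts
#'   split by 3' window (`mismatch`, `mismatch_3p`, `gap`, `gap_3p`).
#' @export
best_hit_score <- function(primer, template, weights = primer_score_weights()) {
  p <- seq_chars(check_sequence(primer, "primer"))
  tmpl <- check_sequence(template, "template")
  if (nchar(tmpl) < length(p))
    abort_input("template shorter than primer")
  fwd_chars <- seq_chars(tmpl)
  rev_chars <- seq_chars(reverse_complement(tmpl))
  bf <- .scan_strand(p, fwd_chars, weights)
  br <- .scan_strand(p, rev_chars, weights)
  if (br$ows < bf$ows - 1e-12) {
    site <- br; strand <- "-"; tchars <- rev_chars
  } else {
    site <- bf; strand <- "+"; tchars <- fwd_chars
  }
  comp <- .site_components(p, tchars, weights, site)
  c(list(ows = site$ows, category = categorize_hit(site$ows),
         strand = strand, offset = site$offset, variant = site$variant),
    comp)
}

#' Per-taxon primer-pair coverage of a reference set
#'
#' The percentage of references in each taxon with perfect hits (OWS = 0)
#' for both primers (or for a single primer in single-primer mode, used
#' when the other primer generated the reference sequences themselves).
#' An `Overall` row covers the whole set. Taxa with blank names at the
#' rank are omitted.
#'
#' @param pair A [primer_pair()].
#' @param db Reference set with taxonomy columns.
#' @param weights [primer_score_weights()].
#' @param rank Taxonomic rank for grouping.
#' @param mode `"both"`, `"forward_only"` or `"reverse_only"`.
#' @return data.frame: `taxon`, `n`, `pct_perfect`.
#' @export
pair_coverage <- function(pair, db, weights = primer_score_weights(),
                          rank = "phylum",
                          mode = c("both", "forward_only", "reverse_only")) {
  mode <- match.arg(mode)
  rank <- match.arg(rank, TAX_RANKS)
  tm <- tax_matrix(db)
  ows_of <- function(primer) vapply(db$sequence, function(s)
    best_hit_score(primer, s, weights)$ows, numeric(1), USE.NAMES = FALSE)
  perfect <- switch(mode,
    both = ows_of(pair$forward) == 0 & ows_of(pair$reverse) == 0,
    forward_only = ows_of(pair$forward) == 0,
    reverse_only = ows_of(pair$reverse) == 0)
  taxon <- tm[, rank]
  keep <- nzchar(taxon)
  tab <- tapply(perfect[keep], taxon[keep], function(x)
    c(n = length(x), pct = 100 * mean(x)))
  out <- data.frame(taxon = names(tab),
                    n = vapply(tab, `[[`, numeric(1), "n"),
                    pct_perfect = vapply(tab, `[[`, numeric(1), "pct"),
                    stringsAsFactors = FALSE)
  out <- rbind(data.frame(taxon = "Overall", n = length(perfect),
                          pct_perfect = 100 * mean(perfect),
                          stringsAsFactors = FALSE),
               out[order(out$taxon), , drop = FALSE])
  rownames(out) <- NULL
  out
}

# Offsets (0-based) of ungapped sites with OWS <= max_ows for a primer
# characters vector on a template characters vector.
.perfect_offsets <- function(pchars, tchars, weights, max_ows) {
  if (length(tchars) < length(pchars)) return(integer(0))
  M <- .mismatch_matrix(pchars, tchars, weights)
  which(colSums(M) <= max_ows + 1e-12) - 1L
}

#' Extract the amplicon between a primer pair's binding sites
#'
#' Locates the forward primer on the forward strand and the reverse
#' primer's reverse complement downstream of it (ungapped sites at
#' `max_ows` or better; default perfect only) and returns the inter-primer
#' region, excluding both primer sites, oriented 5'->3' on the forward
#' strand. The first (leftmost) forward site and the first reverse site
#' after it are used.
#'
#' @param template Template sequence.
#' @param pair A [primer_pair()].
#' @param weights [primer_score_weights()].
#' @param max_ows Maximum site OWS accepted (default 0, perfect only).
#' @return A list: `amplicon` (string or `NULL`), `fwd_start`, `fwd_end`,
#'   `rev_start`, `rev_end` (0-based half-open; `NA` when missing) and
#'   `reason` (`NULL` on success).
#' @export
extract_amplicon <- function(template, pair,
                             weights = primer_score_weights(), max_ows = 0) {
  tmpl <- check_sequence(template, "template")
  tchars <- seq_chars(tmpl)
  fchars <- seq_chars(pair$forward)
  rchars <- seq_chars(reverse_complement(pair$reverse))
  miss <- function(reason) list(amplicon = NULL, fwd_start = NA, fwd_end = NA,
                                rev_start = NA, rev_end = NA, reason = reason)
  f_off <- .perfect_offsets(fchars, tchars, weights, max_ows)
  if (length(f_off) == 0) return(miss("missing forward site"))
  f0 <- f_off[1]
  f_end <- f0 + length(fchars)
  r_off <- .perfect_offsets(rchars, tchars, weights, max_ows)
  r_off <- r_off[r_off >= f_end]
  if (length(r_off) == 0) return(miss("missing reverse site"))
  r0 <- r_off[1]
  amp <- if (r0 > f_end) substr(tmpl, f_end + 1L, r0) else ""
  list(amplicon = amp, fwd_start = f0, fwd_end = f_end,
       rev_start = r0, rev_end = r0 + length(rchars), reason = NULL)
}
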