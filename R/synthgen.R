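# Seeded synthetic-data generators. Every downstream stage is exercised
# against data with planted, recorded ground truth: reference sets whose
# pairwise identities are calibrated around the per-rank thresholds,
# survey count tables with planted core/CRAT/rare structure, and primer
# template sets with planted mismatch patterns.

#' Specification for a rank-calibrated synthetic reference set
#'
#' Describes a balanced taxonomy whose leaf (species) sequences have
#' pairwise identities calibrated by the rank of their lowest common
#' ancestor: `divergence[r]` is the target percent divergence of two
#' leaves whose deepest shared rank is the parent of `r` (e.g.
#' `divergence["species"]` separates sister species of one genus).
#' Defaults put each pairwise identity midway between the adjacent
#' per-rank identity thresholds, so threshold classification of the
#' planted structure is unambiguous.
#'
#' @param n_phyla Number of phyla.
#' @param branching Named integer vector: children per node at
#'   `class`, `order`, `family`, `genus`, `species` (species = leaf
#'   sequences per genus).
#' @param divergence Named numeric vector (phylum..species), strictly
#'   decreasing: target leaf-pair percent divergence per LCA rank.
#' @param length Sequence length (nt).
#' @param seed Integer seed.
#' @return A list of class `reference_sim_spec`.
#' @export
reference_sim_spec <- function(n_phyla = 2,
                               branching = c(class = 1, order = 1, family = 2,
                                             genus = 2, species = 3),
                               divergence = c(phylum = 29.0, class = 23.25,
                                              order = 19.75, family = 15.75,
                                              genus = 9.5, species = 3.4),
                               length = 1400, seed = 1) {
  stopifnot(n_phyla >= 1, all(branching >= 1), length >= 100)
  need <- c("class", "order", "family", "genus", "species")
  if (!all(need %in% names(branching)))
    abort_input("branching must name: ", paste(need, collapse = ", "))
  if (!all(names(divergence) == c("phylum", need)))
    abort_input("divergence must name phylum..species in order")
  if (any(diff(divergence) >= 0))
    abort_input("divergence must strictly decrease from phylum to species")
  structure(list(n_phyla = n_phyla, branching = branching[need],
                 divergence = divergence, length = length, seed = seed),
            class = "reference_sim_spec")
}

# Substitute `positions` of `chars` with a uniformly chosen different base.
substitute_bases <- function(chars, positions) {
  bases <- c("A", "C", "G", "T")
  for (p in positions)
    chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  chars
}

#' Simulate a rank-calibrated reference set
#'
#' Builds the taxonomy tree of a [reference_sim_spec()] and evolves one
#' centroid sequence per taxon by substitution-only mutation. Sibling
#' taxa mutate on globally disjoint position sets, so every pairwise leaf
#' divergence is exact by construction. Deterministic under the spec seed.
#'
#' @param spec A [reference_sim_spec()].
#' @return data.frame with `accession`, `sequence` and the seven taxonomy
#'   columns kingdom..species (one row per leaf sequence).
#' @export
simulate_reference_phylogeny <- function(spec) {
  stopifnot(inherits(spec, "reference_sim_spec"))
  L <- spec$length
  div <- spec$divergence
  # Per-rank centroid-to-centroid sibling divergence: what this rank adds
  # beyond the divergence already contributed below it.
  child_div <- diff(rev(c(div, leaf = 0)))        # species..phylum increments
  child_div <- rev(child_div)                      # phylum..species
  names(child_div) <- names(div)
  with_seed(spec$seed, {
    counters <- new.env(parent = emptyenv())
    for (r in TAX_RANKS) assign(r, 0L, envir = counters)
    new_name <- function(rank) {
      n <- get(rank, envir = counters) + 1L
      assign(rank, n, envir = counters)
      paste0(RANK_LETTERS[[rank]], n)
    }
    rows <- list()
    # All mutations tree-wide draw from one shared pool of positions, so
    # no substitution ever overwrites (or collides with) another anywhere
    # in the tree and every pairwise leaf divergence is exact by
    # construction: two leaves differ at precisely the positions mutated
    # on the branches separating them.
    pool <- new.env(parent = emptyenv())
    pool$free <- seq_len(L)
    draw_positions <- function(n, where) {
      if (n > length(pool$free))
        abort_input("tree too dense for sequence length: ran out of ",
                    "mutable positions at ", where,
                    " (reduce branching or divergence, or increase length)")
      pos <- if (n > 0) sample(pool$free, n) else integer(0)
      pool$free <- setdiff(pool$free, pos)
      pos
    }
    recurse <- function(centroid, rank_i, lineage) {
      child_rank <- TAX_RANKS[rank_i + 1L]
      k <- if (child_rank == "phylum") spec$n_phyla
           else spec$branching[[child_rank]]
      m <- round(child_div[[child_rank]] / 100 * L / 2)
      pos <- draw_positions(k * m, child_rank)
      for (ci in seq_len(k)) {
        child_pos <- if (m > 0) pos[((ci - 1L) * m + 1L):(ci * m)] else integer(0)
        child_seq <- substitute_bases(centroid, child_pos)
        lin <- lineage
        lin[[child_rank]] <- new_name(child_rank)
        if (child_rank == "species") {
          rows[[length(rows) + 1L]] <<- c(lin,
                                          sequence = paste(child_seq, collapse = ""))
        } else {
          recurse(child_seq, rank_i + 1L, lin)
        }
      }
    }
    root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    lineage <- setNames(as.list(character(7L)), TAX_RANKS)
    lineage$kingdom <- "Bacteria"
    recurse(root, 1L, lineage)
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    df <- df[c(TAX_RANKS, "sequence")]
    df$accession <- sprintf("REF_%05d", seq_len(nrow(df)))
    df[c("accession", "sequence", TAX_RANKS)]
  })
}

#' Mutate a sequence to a target percent identity
#'
#' Substitutes exactly `round((100 - target) / 100 * length)` positions,
#' drawn without replacement, each to a different base (never silent).
#' Deterministic under `seed`.
#'
#' @param seq Nucleotide string (A/C/G/T).
#' @param target_identity Target percent identity in `(0, 100]`.
#' @param seed Optional integer seed.
#' @return The mutated sequence.
#' @export
mutate_to_identity <- function(seq, target_identity, seed = NULL) {
  seq <- check_sequence(seq)
  if (target_identity <= 0 || target_identity > 100)
    abort_input("target_identity must be in (0, 100]")
  n_sub <- round((100 - target_identity) / 100 * nchar(seq))
  if (n_sub == 0) return(seq)
  with_seed(seed, {
    chars <- seq_chars(seq)
    pos <- sample(length(chars), n_sub)
    paste(substitute_bases(chars, pos), collapse = "")
  })
}

# ---- survey generator ----

#' Specification for a synthetic digester survey
#'
#' Defines metadata groups (substrate x temperature) and the taxa planted
#' in each with a known core/CRAT/rare category. Within a group, a taxon of
#' category strict/general/loose is made abundant (above the 0.1% cutoff)
#' in exactly `round(occupancy * n_samples)` samples; a CRAT taxon spikes
#' above 1% in a single sample; a rare taxon sits below the rare-biosphere
#' cutoff everywhere. Shared log-normal background taxa fill the remaining
#' read mass.
#'
#' @param groups data.frame with columns `substrate`, `temperature`,
#'   `n_samples` (one row per group).
#' @param n_planted Named integer vector: planted taxa per category per
#'   group (`strict`, `general`, `loose`, `crat`, `rare`).
#' @param occupancy Named fractions of group samples in which a planted
#'   core taxon is abundant; must sit safely inside the (0.2, 0.5, 0.8]
#'   occupancy bands.
#' @param abundance Named mean relative abundances: `core` (when present),
#'   `crat` (single-sample spike), `rare` (everywhere).
#' @param n_background Number of shared background taxa.
#' @param depth Sequencing depth per sample (single value, or vector
#'   recycled over samples in metadata order).
#' @param replicate_pairs If `TRUE` each digester contributes two samples
#'   drawn from the same underlying profile.
#' @param seed Integer seed.
#' @return A list of class `survey_sim_spec`.
#' @export
survey_sim_spec <- function(groups = data.frame(
                              substrate = c("Wastewater sludge", "Food waste"),
                              temperature = c("Mesophilic", "Mesophilic"),
                              n_samples = c(20, 20)),
                            n_planted = c(strict = 5, general = 5, loose = 5,
                                          crat = 3, rare = 5),
                            occupancy = c(strict = 0.9, general = 0.65,
                                          loose = 0.35),
                            abundance = c(core = 0.005, crat = 0.03,
                                          rare = 2e-05),
                            n_background = 30, depth = 50000,
                            replicate_pairs = FALSE, seed = 1) {
  stopifnot(is.data.frame(groups),
            all(c("substrate", "temperature", "n_samples") %in% names(groups)))
  if (!(occupancy[["strict"]] > 0.8 && occupancy[["general"]] > 0.5 &&
        occupancy[["general"]] <= 0.8 && occupancy[["loose"]] > 0.2 &&
        occupancy[["loose"]] <= 0.5))
    abort_input("planted occupancies inconsistent with category bands")
  if (abundance[["crat"]] <= 0.01 || abundance[["core"]] <= 0.001)
    abort_input("planted abundances inconsistent with category definitions")
  structure(list(groups = groups, n_planted = n_planted,
                 occupancy = occupancy, abundance = abundance,
                 n_background = n_background, depth = depth,
                 replicate_pairs = replicate_pairs, seed = seed),
            class = "survey_sim_spec")
}

#' Simulate a digester survey count table with planted category truth
#'
#' Per-sample counts are multinomial draws at the sample's depth from the
#' sample's planted relative-abundance profile. Deterministic under the
#' spec seed.
#'
#' @param spec A [survey_sim_spec()].
#' @return A list: `counts` (integer matrix, samples x taxa), `metadata`
#'   (data.frame: `sample`, `digester`, `substrate`, `temperature`,
#'   `continent`, `technology`, `primer_set`), `truth` (data.frame:
#'   `taxon`, `group`, `category`).
#' @export
simulate_survey <- function(spec) {
  stopifnot(inherits(spec, "survey_sim_spec"))
  groups <- spec$groups
  if (nrow(groups) == 0)
    return(list(counts = matrix(integer(0), 0, 0),
                metadata = data.frame(), truth = data.frame()))
  with_seed(spec$seed, {
    bg_taxa <- sprintf("bg_%03d", seq_len(spec$n_background))
    bg_shape <- rlnorm(spec$n_background, meanlog = 0, sdlog = 1.5)
    categories <- c("strict", "general", "loose", "crat", "rare")
    truth <- list(); profiles <- list(); meta <- list()
    sample_i <- 0L; digester_i <- 0L
    continents <- c("Europe", "Asia", "North America", "South America",
                    "Oceania")
    technologies <- c("CSTR", "TSAD", "UASB", "Other")
    for (gi in seq_len(nrow(groups))) {
      gkey <- paste(groups$substrate[gi], groups$temperature[gi], sep = ":")
      n <- groups$n_samples[gi]
      planted <- list()
      for (cat in categories) {
        k <- spec$n_planted[[cat]]
        if (k > 0)
          planted[[cat]] <- sprintf("g%d_%s_%02d", gi, cat, seq_len(k))
      }
      truth[[gi]] <- data.frame(
        taxon = unlist(planted, use.names = FALSE),
        group = gkey,
        category = rep(names(planted), lengths(planted)),
        stringsAsFactors = FALSE)
      # Which samples carry each planted taxon above the relevant level.
      present <- list()
      for (cat in c("strict", "general", "loose")) {
        k_present <- round(spec$occupancy[[cat]] * n)
        present[[cat]] <- lapply(planted[[cat]] %||% character(0),
                                 function(t) sample(n, k_present))
      }
      present$crat <- lapply(planted$crat %||% character(0),
                             function(t) sample(n, 1L))
      all_taxa <- c(unlist(planted, use.names = FALSE), bg_taxa)
      for (si in seq_len(n)) {
        digester_i <- digester_i + 1L
        prof <- setNames(numeric(length(all_taxa)), all_taxa)
        for (cat in c("strict", "general", "loose")) {
          for (ti in seq_along(planted[[cat]] %||% character(0))) {
            if (si %in% present[[cat]][[ti]])
              prof[planted[[cat]][ti]] <-
                spec$abundance[["core"]] * rlnorm(1, 0, 0.3)
          }
        }
        for (ti in seq_along(planted$crat %||% character(0))) {
          if (si %in% present$crat[[ti]])
            prof[planted$crat[ti]] <- spec$abundance[["crat"]] * rlnorm(1, 0, 0.2)
        }
        for (t in planted$rare %||% character(0))
          prof[t] <- spec$abundance[["rare"]]
        remaining <- max(1 - sum(prof), 0.2)
        prof[bg_taxa] <- remaining * bg_shape / sum(bg_shape)
        prof <- prof / sum(prof)
        n_reps <- if (spec$replicate_pairs) 2L else 1L
        for (rep_i in seq_len(n_reps)) {
          sample_i <- sample_i + 1L
          sid <- sprintf("S%04d", sample_i)
          profiles[[sid]] <- prof
          meta[[sample_i]] <- data.frame(
            sample = sid,
            digester = sprintf("AD%04d", digester_i),
            substrate = groups$substrate[gi],
            temperature = groups$temperature[gi],
            continent = continents[1L + (digester_i %% length(continents))],
            technology = technologies[1L + (digester_i %% length(technologies))],
            primer_set = "V4",
            stringsAsFactors = FALSE)
        }
      }
    }
    metadata <- do.call(rbind, meta)
    taxa <- unique(unlist(lapply(profiles, names)))
    depth <- rep_len(spec$depth, nrow(metadata))
    counts <- matrix(0L, nrow(metadata), length(taxa),
                     dimnames = list(metadata$sample, taxa))
    for (si in seq_len(nrow(metadata))) {
      prof <- profiles[[metadata$sample[si]]]
      counts[si, names(prof)] <- as.integer(rmultinom(1, depth[si], prof))
    }
    list(counts = counts, metadata = metadata,
         truth = do.call(rbind, truth))
  })
}

# ---- primer template generator ----

# Pick, for each primer character, one concrete base it matches.
realize_primer <- function(primer) {
  vapply(seq_chars(primer), function(ch) sample(IUPAC_SETS[[ch]], 1L),
         character(1), USE.NAMES = FALSE)
}

# Replace `chars[pos]` with bases incompatible with the primer character.
plant_mismatches <- function(chars, primer_chars, pos) {
  for (p in pos) {
    options <- setdiff(c("A", "C", "G", "T"), IUPAC_SETS[[primer_chars[p]]])
    if (length(options) == 0)
      abort_input("cannot plant a mismatch against N at primer position ", p)
    chars[p] <- sample(options, 1L)
  }
  chars
}

#' Simulate templates with planted primer-site mismatch patterns
#'
#' Each template embeds a forward-primer binding site and (the reverse
#' complement of) a reverse-primer binding site at recorded offsets, with
#' the requested number of mismatches split between the 3' window and the
#' rest of each primer. Deterministic under `seed`.
#'
#' @param pair A [primer_pair()].
#' @param mismatch_spec data.frame, one row per template, columns
#'   `fwd_mm`, `fwd_mm_3p`, `rev_mm`, `rev_mm_3p`: total mismatches per
#'   primer and how many of them fall in the 3' window.
#' @param length Template length (nt).
#' @param three_prime_len 3' window size used for mismatch placement
#'   (match the scoring weights in use).
#' @param seed Integer seed.
#' @return A list: `templates` (data.frame `accession`, `sequence`) and
#'   `truth` (data.frame with the planted offsets, 0-based half-open on
#'   the forward strand, and mismatch counts).
#' @export
simulate_primer_templates <- function(pair, mismatch_spec, length = 1200,
                                      three_prime_len = 5, seed = 1) {
  stopifnot(is.data.frame(mismatch_spec),
            all(c("fwd_mm", "fwd_mm_3p", "rev_mm", "rev_mm_3p") %in%
                names(mismatch_spec)))
  fwd <- check_sequence(pair$forward, "forward primer")
  rev_p <- check_sequence(pair$reverse, "reverse primer")
  lf <- nchar(fwd); lr <- nchar(rev_p)
  if (any(mismatch_spec$fwd_mm > lf) || any(mismatch_spec$rev_mm > lr))
    abort_input("requested mismatches exceed primer length")
  if (any(mismatch_spec$fwd_mm_3p > pmin(mismatch_spec$fwd_mm, three_prime_len)) ||
      any(mismatch_spec$rev_mm_3p > pmin(mismatch_spec$rev_mm, three_prime_len)))
    abort_input("3' mismatch counts inconsistent with totals or window")
  with_seed(seed, {
    fwd_chars <- seq_chars(fwd)
    rev_chars <- seq_chars(rev_p)
    site_positions <- function(L, n_total, n_3p) {
      p3 <- sample((L - three_prime_len + 1L):L, n_3p)
      p5 <- sample(seq_len(L - three_prime_len), n_total - n_3p)
      c(p5, p3)
    }
    n <- nrow(mismatch_spec)
    fwd_off <- 60L
    rev_off <- length - 60L - lr   # 0-based start of the reverse site
    rows <- vector("list", n)
    seqs <- character(n)
    for (i in seq_len(n)) {
      tmpl <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
      fsite <- realize_primer(fwd)
      fsite <- plant_mismatches(fsite, fwd_chars,
                                site_positions(lf, mismatch_spec$fwd_mm[i],
                                               mismatch_spec$fwd_mm_3p[i]))
      rsite <- realize_primer(rev_p)
      rsite <- plant_mismatches(rsite, rev_chars,
                                site_positions(lr, mismatch_spec$rev_mm[i],
                                               mismatch_spec$rev_mm_3p[i]))
      tmpl[(fwd_off + 1L):(fwd_off + lf)] <- fsite
      rsite_fs <- seq_chars(reverse_complement(paste(rsite, collapse = "")))
      tmpl[(rev_off + 1L):(rev_off + lr)] <- rsite_fs
      seqs[i] <- paste(tmpl, collapse = "")
      rows[[i]] <- data.frame(accession = sprintf("TMPL_%03d", i),
                              fwd_start = fwd_off, fwd_end = fwd_off + lf,
                              rev_start = rev_off, rev_end = rev_off + lr,
                              fwd_mm = mismatch_spec$fwd_mm[i],
                              fwd_mm_3p = mismatch_spec$fwd_mm_3p[i],
                              rev_mm = mismatch_spec$rev_mm[i],
                              rev_mm_3p = mismatch_spec$rev_mm_3p[i],
                              stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    list(templates = data.frame(accession = truth$accession, sequence = seqs,
                                stringsAsFactors = FALSE),
         truth = truth)
  })
}
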