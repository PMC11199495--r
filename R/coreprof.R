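# Core-community profiling: strict/general/loose core and conditionally
# rare or abundant taxa (CRAT) per metadata group, the aggregated
# "most wanted" list, shared-core intersection patterns and accumulated
# abundance per category.

CORE_CATEGORIES <- c("strict", "general", "loose", "CRAT", "other")

#' Core / CRAT classification thresholds
#'
#' @param abundant Relative-abundance fraction above which a taxon counts
#'   as abundant in a sample (default 0.001, i.e. 0.1%; strictly above).
#' @param loose,general,strict Occupancy fractions: a taxon abundant in
#'   strictly more than this fraction of a group's samples is loose,
#'   general or strict core (defaults 0.2, 0.5, 0.8).
#' @param crat Single-sample relative-abundance fraction above which a
#'   non-core taxon is CRAT (default 0.01, i.e. 1%; strictly above).
#' @return A named list.
#' @export
core_thresholds <- function(abundant = 0.001, loose = 0.2, general = 0.5,
                            strict = 0.8, crat = 0.01) {
  stopifnot(loose < general, general < strict,
            abundant > 0, abundant < 1, crat > 0, crat < 1,
            loose > 0, strict < 1)
  list(abundant = abundant, loose = loose, general = general,
       strict = strict, crat = crat)
}

#' Partition samples into metadata groups
#'
#' Samples whose value in any grouping key is missing, empty or
#' `"unknown"` are excluded (their ids are attached as attribute
#' `"excluded"`). Groups smaller than `min_size` are kept but flagged.
#'
#' @param metadata data.frame with a `sample` column plus grouping fields.
#' @param keys Character vector of metadata column names to group by.
#' @param min_size Minimum group size below which a group is flagged.
#' @return Named list of sample-id vectors (names are `key1:key2` group
#'   labels), with attributes `excluded` (sample ids) and `small`
#'   (logical per group).
#' @export
group_samples <- function(metadata, keys = c("substrate", "temperature"),
                          min_size = 2L) {
  bad <- setdiff(keys, names(metadata))
  if (length(bad) > 0)
    abort_input("unknown metadata key(s): ", paste(bad, collapse = ", "))
  if (nrow(metadata) == 0)
    return(structure(list(), excluded = character(0), small = logical(0)))
  vals <- metadata[keys]
  drop <- Reduce(`|`, lapply(vals, function(v)
    is.na(v) | !nzchar(v) | tolower(v) == "unknown"))
  kept <- metadata[!drop, , drop = FALSE]
  key <- do.call(paste, c(kept[keys], sep = ":"))
  groups <- split(kept$sample, key)
  structure(groups,
            excluded = metadata$sample[drop],
            small = vapply(groups, length, integer(1)) < min_size)
}

#' Classify taxa of one group into core categories
#'
#' Occupancy is the fraction of the group's samples in which the taxon is
#' abundant (relative abundance strictly above the abundant cutoff).
#' Category: strict if occupancy > 0.8, else general if > 0.5, else loose
#' if > 0.2, else CRAT if the taxon exceeds 1% in at least one sample,
#' else other. All comparisons are strict. Taxa absent from every group
#' sample are omitted.
#'
#' @param rel Relative-abundance matrix (samples x taxa, fractions)
#'   restricted to one group; at least 2 samples.
#' @param thresholds [core_thresholds()].
#' @param group Optional group label carried into the output.
#' @return data.frame: `taxon`, `group`, `category`, `occupancy`,
#'   `max_abund`, `boundary` (occupancy exactly on a cutoff).
#' @export
classify_core <- function(rel, thresholds = core_thresholds(), group = NA) {
  rel <- as.matrix(rel)
  if (nrow(rel) < 2)
    abort_input("a group needs at least 2 samples")
  present <- colSums(rel) > 0
  rel <- rel[, present, drop = FALSE]
  occupancy <- colMeans(rel > thresholds$abundant)
  max_abund <- apply(rel, 2, max)
  category <- ifelse(occupancy > thresholds$strict, "strict",
              ifelse(occupancy > thresholds$general, "general",
              ifelse(occupancy > thresholds$loose, "loose",
              ifelse(max_abund > thresholds$crat, "CRAT", "other"))))
  data.frame(taxon = colnames(rel), group = group,
             category = factor(category, levels = CORE_CATEGORIES),
             occupancy = unname(occupancy), max_abund = unname(max_abund),
             boundary = unname(occupancy %in%
               c(thresholds$loose, thresholds$general, thresholds$strict)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate core assignments into the most-wanted list
#'
#' Each taxon gets its highest-ranking category across all groups (and
#' primer sets) under the order strict > general > loose > CRAT; taxa that
#' are `other` everywhere are dropped. Output is sorted by category, then
#' taxon name.
#'
#' @param assignments One or more [classify_core()] outputs, row-bound.
#' @return data.frame: `taxon`, `category`, `best_group` (the first group
#'   achieving the best category, in group-name order).
#' @export
most_wanted <- function(assignments) {
  stopifnot(nrow(assignments) >= 1)
  assignments$category <- factor(as.character(assignments$category),
                                 levels = CORE_CATEGORIES)
  rows <- lapply(split(assignments, assignments$taxon), function(d) {
    best <- levels(droplevels(d$category))[1]
    if (best == "other") return(NULL)
    grp <- sort(as.character(d$group[as.character(d$category) == best]))[1]
    data.frame(taxon = d$taxon[1], category = best, best_group = grp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(taxon = character(0), category = character(0),
                      best_group = character(0)))
  out$category <- factor(out$category,
                         levels = setdiff(CORE_CATEGORIES, "other"))
  out <- out[order(out$category, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclusive intersection pattern counts of per-group core sets
#'
#' UpSet semantics: every taxon in the union is counted in exactly one
#' pattern, the exact set of groups whose core contains it. Pattern counts
#' therefore sum to the union size.
#'
#' @param core_sets Named list (>= 2 entries) of taxon character vectors.
#' @return data.frame: `pattern` (group names joined by `&`), `degree`,
#'   `count`, sorted by degree then pattern. Empty patterns are omitted.
#' @export
shared_core_counts <- function(core_sets) {
  if (length(core_sets) < 2)
    abort_input("need at least 2 core sets")
  if (is.null(names(core_sets)) || any(!nzchar(names(core_sets))))
    abort_input("core sets must be named")
  taxa <- unique(unlist(core_sets, use.names = FALSE))
  membership <- vapply(core_sets, function(s) taxa %in% s,
                       logical(length(taxa)))
  membership <- matrix(membership, nrow = length(taxa),
                       dimnames = list(taxa, names(core_sets)))
  pattern <- apply(membership, 1, function(m)
    paste(colnames(membership)[m], collapse = "&"))
  tab <- table(pattern)
  out <- data.frame(pattern = names(tab),
                    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(out$degree, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean accumulated relative abundance per most-wanted category
#'
#' For one group's samples: each taxon's mean relative abundance across
#' samples, summed within its most-wanted category. Taxa not on the list
#' fall into `other`; features with a blank name are pooled as
#' `unclassified`. Percentages sum to 100 (before rounding).
#'
#' @param rel Relative-abundance matrix (samples x taxa, fractions) for
#'   one group. Blank column names mark unclassified features.
#' @param wanted A [most_wanted()] output.
#' @return data.frame: `category`, `pct` (percent of total reads).
#' @export
category_abundance_fractions <- function(rel, wanted) {
  rel <- as.matrix(rel)
  means <- 100 * colMeans(rel)
  taxa <- colnames(rel)
  cat_of <- setNames(as.character(wanted$category), wanted$taxon)
  category <- ifelse(!nzchar(taxa) | is.na(taxa), "unclassified",
                     ifelse(taxa %in% names(cat_of), cat_of[taxa], "other"))
  lv <- c(setdiff(CORE_CATEGORIES, "other"), "other", "unclassified")
  agg <- tapply(means, factor(category, levels = lv), sum, default = 0)
  data.frame(category = lv, pct = as.numeric(agg), stringsAsFactors = FALSE)
}
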