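test_that("sample grouping partitions and excludes unknown metadata", {
  md <- data.frame(
    sample = paste0("s", 1:7),
    substrate = c("Manure", "Manure", "Food waste", "Food waste",
                  "Manure", "Food waste", "Manure"),
    temperature = c("Mesophilic", "Mesophilic", "Mesophilic", "Thermophilic",
                    "unknown", "Mesophilic", "Mesophilic"))
  grp <- group_samples(md)
  expect_equal(attr(grp, "excluded"), "s5")
  all_ids <- unlist(grp, use.names = FALSE)
  expect_setequal(all_ids, setdiff(md$sample, "s5"))
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_true(attr(grp, "small")[["Food waste:Thermophilic"]])
  expect_error(group_samples(md, keys = "reactor_color"), "unknown metadata")
  empty <- group_samples(md[0, ])
  expect_length(empty, 0)
})

test_that("core categories follow strict threshold comparisons", {
  mk_rel <- function(v) matrix(v, length(v), 1,
                               dimnames = list(paste0("s", seq_along(v)), "t"))
  # abundant in 9 of 10 samples: occupancy 0.9 > 0.8 -> strict
  rel <- mk_rel(c(rep(0.02, 9), 0))
  rel <- cbind(rel, filler = 1 - rowSums(rel))
  expect_equal(as.character(classify_core(rel)$category[1]), "strict")
  # exactly 0.1% everywhere: strictly-above rule -> occupancy 0 -> other
  rel <- mk_rel(rep(0.001, 10)); rel <- cbind(rel, filler = 1 - rowSums(rel))
  out <- classify_core(rel)
  expect_equal(out$occupancy[out$taxon == "t"], 0)
  expect_equal(as.character(out$category[out$taxon == "t"]), "other")
  # 2% in one of 10 samples, absent elsewhere -> CRAT
  rel <- mk_rel(c(0.02, rep(0, 9))); rel <- cbind(rel, filler = 1 - rowSums(rel))
  expect_equal(as.character(classify_core(rel)$category[1]), "CRAT")
  # occupancy exactly at a cutoff is NOT promoted (strict ">") and flagged
  rel <- mk_rel(c(rep(0.02, 8), 0, 0)); rel <- cbind(rel, filler = 1 - rowSums(rel))
  out <- classify_core(rel)
  expect_equal(as.character(out$category[out$taxon == "t"]), "general")
  expect_true(out$boundary[out$taxon == "t"])
  expect_error(classify_core(matrix(1, 1, 1)), "2 samples")
})

test_that("category nesting holds: strict implies the weaker predicates", {
  set.seed(10)
  rel <- matrix(runif(20 * 30, 0, 0.01), 20, 30,
                dimnames = list(paste0("s", 1:20), paste0("t", 1:30)))
  rel <- rel / rowSums(rel)
  out <- classify_core(rel)
  th <- core_thresholds()
  for (i in seq_len(nrow(out))) {
    occ <- out$occupancy[i]
    cat <- as.character(out$category[i])
    if (occ > th$strict) expect_equal(cat, "strict")
    else if (occ > th$general) expect_equal(cat, "general")
    else if (occ > th$loose) expect_equal(cat, "loose")
    else expect_true(cat %in% c("CRAT", "other"))
  }
})

test_that("most wanted takes the highest category across groups", {
  asg <- data.frame(
    taxon = c("tA", "tA", "tB", "tB", "tC", "tD", "tD"),
    group = c("g1", "g2", "g1", "g2", "g1", "g1", "g2"),
    category = c("loose", "strict", "CRAT", "loose", "other", "other", "other"),
    occupancy = 0, max_abund = 0, boundary = FALSE)
  mw <- most_wanted(asg)
  expect_equal(mw$category[mw$taxon == "tA"], factor("strict",
    levels = c("strict", "general", "loose", "CRAT")))
  expect_equal(as.character(mw$category[mw$taxon == "tB"]), "loose")
  expect_false("tC" %in% mw$taxon)   # other everywhere: excluded
  expect_false("tD" %in% mw$taxon)
  expect_equal(mw$best_group[mw$taxon == "tA"], "g2")
  # brute-force maximum under the stated order on random assignments
  set.seed(3)
  rnd <- data.frame(
    taxon = sample(paste0("x", 1:8), 40, replace = TRUE),
    group = sample(paste0("g", 1:4), 40, replace = TRUE),
    category = sample(c("strict", "general", "loose", "CRAT", "other"),
                      40, replace = TRUE))
  mw2 <- most_wanted(rnd)
  ord <- c(strict = 1, general = 2, loose = 3, CRAT = 4, other = 5)
  for (t in unique(rnd$taxon)) {
    best <- min(ord[rnd$category[rnd$taxon == t]])
    if (best == 5) expect_false(t %in% mw2$taxon)
    else expect_equal(unname(ord[as.character(mw2$category[mw2$taxon == t])]),
                      best)
  }
})

test_that("shared-core patterns are exclusive and conserve the union", {
  a <- c("t1", "t2", "t3"); b <- c("t4", "t5", "t6", "t7")
  out <- shared_core_counts(list(A = a, B = b))
  expect_equal(out$count[out$pattern == "A"], 3L)
  expect_equal(out$count[out$pattern == "B"], 4L)
  expect_false("A&B" %in% out$pattern)
  same <- shared_core_counts(list(A = a, B = a))
  expect_equal(same$pattern, "A&B")
  expect_equal(same$count, 3L)
})

test_that("shared-core counts match brute-force enumeration on random sets", {
  set.seed(4)
  pool <- paste0("t", 1:40)
  sets <- lapply(1:4, function(i) sample(pool, sample(5:25, 1)))
  names(sets) <- paste0("G", 1:4)
  out <- shared_core_counts(sets)
  expect_equal(sum(out$count), length(unique(unlist(sets))))
  oracle <- oracle_upset(sets)
  for (i in seq_len(nrow(out)))
    expect_equal(out$count[i], oracle[[out$pattern[i]]])
  expect_equal(nrow(out), length(oracle))
})

test_that("category abundance fractions sum to 100 and pool unclassified", {
  rel <- matrix(c(0.6, 0.3, 0.1,
                  0.5, 0.4, 0.1), 2, 3, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("tA", "tB", "")))
  mw <- data.frame(taxon = c("tA", "tB"), category = c("strict", "CRAT"))
  out <- category_abundance_fractions(rel, mw)
  expect_equal(out$pct[out$category == "strict"], 55)
  expect_equal(out$pct[out$category == "CRAT"], 35)
  expect_equal(out$pct[out$category == "unclassified"], 10)
  expect_equal(sum(out$pct), 100, tolerance = 1e-9)
  # single strict taxon at 100%
  one <- matrix(1, 2, 1, dimnames = list(c("s1", "s2"), "tA"))
  o1 <- category_abundance_fractions(one, mw)
  expect_equal(o1$pct[o1$category == "strict"], 100)
  # everything unclassified
  none <- matrix(0.5, 2, 2, dimnames = list(c("s1", "s2"), c("", "")))
  o2 <- category_abundance_fractions(none, mw[0, ])
  expect_equal(o2$pct[o2$category == "unclassified"], 100)
})

test_that("planted survey categories are recovered per group", {
  spec <- survey_sim_spec(
    groups = data.frame(substrate = c("Wastewater sludge", "Manure"),
                        temperature = "Mesophilic", n_samples = c(15, 15)),
    depth = 30000, seed = 12)
  sv <- simulate_survey(spec)
  grp <- group_samples(sv$metadata)
  rel <- relative_abundance(sv$counts)
  asg <- do.call(rbind, lapply(names(grp), function(g)
    classify_core(rel[grp[[g]], ], group = g)))
  truth <- sv$truth
  truth$expected <- c(strict = "strict", general = "general", loose = "loose",
                      crat = "CRAT", rare = "other")[truth$category]
  m <- merge(truth, asg, by = c("taxon", "group"))
  expect_equal(nrow(m), nrow(truth))
  expect_gte(mean(as.character(m$category.y) == m$expected), 0.95)
})
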