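test_that("novelty classification is a monotone step function with strict boundaries", {
  expect_equal(classify_novelty(100), "none")
  expect_equal(classify_novelty(93), "genus_novel")
  expect_equal(classify_novelty(74.9), "phylum_novel")
  # boundary values are NOT novel at that rank (strict "<")
  expect_equal(classify_novelty(94.5), "species_novel")
  expect_equal(classify_novelty(98.7), "none")
  expect_equal(classify_novelty(75.0), "class_novel")
  # monotone: novelty rank order never reverses as identity rises
  order_of <- c(phylum_novel = 1, class_novel = 2, order_novel = 3,
                family_novel = 4, genus_novel = 5, species_novel = 6,
                none = 7)
  grid <- seq(0, 100, by = 0.1)
  codes <- order_of[classify_novelty(grid)]
  expect_true(all(diff(codes) >= 0))
  expect_error(classify_novelty(101), "identity")
  expect_error(classify_novelty(-1), "identity")
})

test_that("novelty summary rows are cumulative and percentages exact", {
  # identities straddling every threshold: 2 below phylum, 1 in each band
  ids <- c(60, 70, 76, 80, 84, 90, 96, 99, 100)
  out <- novelty_summary_from_identities(ids)
  expect_equal(out$count, c(2, 3, 4, 5, 6, 7))   # cumulative by design
  expect_equal(out$percentage, round(100 * out$count / 9, 2))
  expect_true(all(diff(out$count) >= 0))
  expect_error(novelty_summary_from_identities(numeric(0)), "no identities")
})

test_that("novelty summary of sequences recovers the planted design", {
  db <- data.frame(accession = c("A1", "A2"),
                   sequence = c(random_dna(600, seed = 1),
                                random_dna(600, seed = 2)))
  incoming <- data.frame(
    accession = paste0("Q", 1:4),
    sequence = c(db$sequence[1],                                # none
                 mutate_to_identity(db$sequence[1], 97, seed = 3),  # species
                 mutate_to_identity(db$sequence[1], 90, seed = 4),  # genus
                 mutate_to_identity(db$sequence[2], 84, seed = 5))) # family
  out <- summarize_novelty(incoming, db)
  expect_equal(out$count[out$rank == "species"], 3L)
  expect_equal(out$count[out$rank == "genus"], 2L)
  expect_equal(out$count[out$rank == "family"], 1L)
  expect_equal(out$count[out$rank == "order"], 0L)
  # all identical to db -> all zero
  same <- data.frame(accession = "Q", sequence = db$sequence[1])
  expect_true(all(summarize_novelty(same, db)$count == 0))
})

test_that("merge deduplicates on 100% identity + equal length and conserves counts", {
  base <- vapply(1:10, function(i) random_dna(400, seed = 400 + i), "")
  existing <- data.frame(accession = sprintf("E%02d", 1:10), sequence = base)
  # planted: 3 duplicates (2 exact copies + 1 IUPAC-equal), 4 novel
  dup_iupac <- base[3]
  substr(dup_iupac, 100, 100) <- "N"
  incoming <- data.frame(
    accession = c("I1", "I2", "I3", "I4", "I5", "I6", "I7"),
    sequence = c(base[1], base[5], dup_iupac,
                 vapply(1:4, function(i) random_dna(400, seed = 500 + i), "")))
  res <- merge_dereplicate(existing, incoming)
  expect_equal(res$report$n_duplicates, 3L)
  expect_equal(res$report$n_added, 4L)
  expect_equal(nrow(res$merged), 14L)
  # conservation: |merged| - |existing| + dups = |incoming|
  expect_equal(nrow(res$merged) - nrow(existing) + res$report$n_duplicates,
               nrow(incoming))
  # idempotent: re-merging the same incoming adds nothing
  res2 <- merge_dereplicate(res$merged[, c("accession", "sequence")],
                            setNames(incoming, c("accession", "sequence")))
  expect_equal(res2$report$n_added, 0L)
  # same-length different sequence is NOT a duplicate
  near <- data.frame(accession = "X1",
                     sequence = mutate_to_identity(base[1], 99.5, seed = 9))
  expect_equal(merge_dereplicate(existing, near)$report$n_duplicates, 0L)
})

test_that("merge rejects accession collisions and reports containment", {
  existing <- data.frame(accession = "A", sequence = random_dna(300, seed = 1))
  other <- data.frame(accession = "A", sequence = random_dna(300, seed = 2))
  expect_error(merge_dereplicate(existing, other), "collision")
  # a strict substring is added but flagged
  sub <- data.frame(accession = "B",
                    sequence = substr(existing$sequence, 50, 250))
  expect_warning(res <- merge_dereplicate(existing, sub), "containment")
  expect_equal(res$report$n_added, 1L)
  expect_equal(res$report$n_containment_warnings, 1L)
})

test_that("taxonomy assignment inherits above the failing rank and mints below", {
  db <- simulate_reference_phylogeny(reference_sim_spec())
  reg <- placeholder_registry()
  # exact query inherits the full path
  t0 <- assign_taxonomy(db$sequence[4], db, registry = reg)
  expect_equal(unname(t0$ranks), unname(unlist(db[4, c("kingdom", "phylum",
    "class", "order", "family", "genus", "species")])))
  expect_false(any(t0$placeholder))
  # ~90%: family inherited, genus/species fresh placeholders
  q1 <- mutate_to_identity(db$sequence[1], 90, seed = 21)
  t1 <- assign_taxonomy(q1, db, registry = reg)
  expect_equal(t1$ranks[["family"]], db$family[1])
  expect_match(t1$ranks[["genus"]], "^midas_g_[0-9]+$")
  expect_match(t1$ranks[["species"]], "^midas_s_[0-9]+$")
  expect_equal(unname(t1$placeholder),
               c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("placeholder names are reused within greedy clusters and numbering is deterministic", {
  db <- simulate_reference_phylogeny(reference_sim_spec())
  run <- function() {
    reg <- placeholder_registry()
    q1 <- mutate_to_identity(db$sequence[1], 90, seed = 31)
    q2 <- mutate_to_identity(q1, 99.6, seed = 32)       # clusters with q1
    q3 <- mutate_to_identity(db$sequence[10], 90, seed = 33)  # far from q1
    lapply(list(q1, q2, q3), assign_taxonomy, db = db, registry = reg)
  }
  a <- run()
  expect_equal(a[[1]]$ranks[["genus"]], a[[2]]$ranks[["genus"]])
  expect_equal(a[[1]]$ranks[["species"]], a[[2]]$ranks[["species"]])
  expect_false(a[[3]]$ranks[["genus"]] == a[[1]]$ranks[["genus"]])
  # byte-for-byte reproducibility under identical input order
  b <- run()
  expect_identical(lapply(a, `[[`, "ranks"), lapply(b, `[[`, "ranks"))
  # brute-force greedy clustering oracle over queries needing genus names
  qs <- c(mutate_to_identity(db$sequence[1], 90, seed = 41),
          mutate_to_identity(db$sequence[1], 90, seed = 42),
          mutate_to_identity(db$sequence[13], 90, seed = 43))
  reg <- placeholder_registry()
  got <- vapply(qs, function(q)
    assign_taxonomy(q, db, registry = reg)$ranks[["genus"]], "")
  centroids <- character(0); labels <- integer(length(qs))
  for (i in seq_along(qs)) {
    hit <- 0L
    for (ci in seq_along(centroids)) {
      if (percent_identity(qs[i], centroids[ci]) >= 94.5) { hit <- ci; break }
    }
    if (hit == 0L) { centroids <- c(centroids, qs[i]); hit <- length(centroids) }
    labels[i] <- hit
  }
  expect_equal(as.integer(factor(got, levels = unique(got))), labels)
})

test_that("taxa inventory delta reports totals, novelties and percent increase", {
  mk <- function(genera, species) {
    n <- length(species)
    data.frame(accession = paste0("A", seq_len(n)), sequence = "ACGT",
               kingdom = "Bacteria", phylum = "p", class = "c", order = "o",
               family = "f", genus = rep_len(genera, n), species = species)
  }
  before <- mk(c("g1", "g2"), c("s1", "s2", "s3"))
  after <- mk(c("g1", "g2", "g3"), c("s1", "s2", "s3", "s4", "s5"))
  out <- taxa_inventory_delta(before, after)
  expect_equal(out$total[out$rank == "genus"], 3L)
  expect_equal(out$new[out$rank == "genus"], 1L)
  expect_equal(out$pct_increase[out$rank == "genus"], 50.0)
  expect_equal(out$new[out$rank == "species"], 2L)
  expect_equal(out$pct_increase[out$rank == "species"], round(100 * 2 / 3, 1))
  # unchanged database: nothing new
  same <- taxa_inventory_delta(before, before)
  expect_true(all(same$new == 0))
  expect_true(all(same$pct_increase == 0))
  # all-new names at a rank: undefined increase, no exception
  allnew <- taxa_inventory_delta(mk("g1", "s1"), mk("g9", "s9"))
  expect_true(is.na(allnew$pct_increase[allnew$rank == "genus"]))
})
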