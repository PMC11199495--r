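test_that("hit categories follow the OWS boundaries", {
  expect_equal(categorize_hit(0), "perfect")
  expect_equal(categorize_hit(1.0), "partial")
  expect_equal(categorize_hit(1.01), "poor")
  expect_equal(categorize_hit(c(0, 0.4, 1.4)),
               c("perfect", "partial", "poor"))
  expect_error(categorize_hit(-0.1), "non-negative")
})

test_that("weighted site scores match hand-computed mismatch arithmetic", {
  pp <- primer_pair("V4", "GTGYCAGCMGCCGCGGTAA", "GGACTACNVGGGTWTCTAAT")
  ms <- data.frame(fwd_mm = c(0, 1, 2, 1), fwd_mm_3p = c(0, 0, 1, 1),
                   rev_mm = 0, rev_mm_3p = 0)
  sim <- simulate_primer_templates(pp, ms, seed = 13)
  ows <- vapply(sim$templates$sequence, function(t)
    best_hit_score(pp$forward, t)$ows, 0, USE.NAMES = FALSE)
  # defaults: non-3' mismatch 0.4, 3' mismatch 1.0
  expect_equal(ows, c(0, 0.4, 1.4, 1.0))
  expect_equal(categorize_hit(ows), c("perfect", "partial", "poor", "partial"))
  # reverse primer sites are perfect on every template
  rows <- vapply(sim$templates$sequence, function(t)
    best_hit_score(pp$reverse, t)$ows, 0, USE.NAMES = FALSE)
  expect_equal(rows, rep(0, 4))
})

test_that("best hit equals exhaustive enumeration over offsets and gaps", {
  w <- primer_score_weights()
  primer <- "GTGYCAGCMGCC"
  set.seed(14)
  for (i in 1:5) {
    tmpl <- random_dna(120, seed = 700 + i)
    got <- best_hit_score(primer, tmpl, w)
    expect_equal(got$ows, oracle_best_ows(primer, tmpl, w))
  }
  # including a template with a planted near-perfect site
  sim <- simulate_primer_templates(
    primer_pair("p", "GTGYCAGCMGCCGCGGTAA", "GGACTACNVGGGTWTCTAAT"),
    data.frame(fwd_mm = 1, fwd_mm_3p = 0, rev_mm = 1, rev_mm_3p = 1),
    length = 400, seed = 15)
  for (p in c("GTGYCAGCMGCCGCGGTAA", "GGACTACNVGGGTWTCTAAT")) {
    got <- best_hit_score(p, sim$templates$sequence[1], w)
    expect_equal(got$ows, oracle_best_ows(p, sim$templates$sequence[1], w))
  }
})

test_that("a single gap is found and charged with the right weight", {
  w <- primer_score_weights()
  primer <- "ACGTACCGGTACGTAA"
  tmpl0 <- paste0(random_dna(80, seed = 16), primer, random_dna(80, seed = 17))
  expect_equal(best_hit_score(primer, tmpl0, w)$ows, 0)
  # delete one internal primer base from the template: one non-3' gap
  site <- paste0(substr(primer, 1, 5), substr(primer, 7, 16))
  tmpl1 <- paste0(random_dna(80, seed = 16), site, random_dna(80, seed = 17))
  got <- best_hit_score(primer, tmpl1, w)
  expect_equal(got$ows, w$gap)
  expect_equal(got$variant, "template_gap")
  expect_equal(got$gap, 1L); expect_equal(got$gap_3p, 0L)
  expect_equal(got$ows, oracle_best_ows(primer, tmpl1, w))
  # insert an extra template base inside the site: one primer gap
  site2 <- paste0(substr(primer, 1, 8), "A", substr(primer, 9, 16))
  tmpl2 <- paste0(random_dna(80, seed = 18), site2, random_dna(80, seed = 19))
  got2 <- best_hit_score(primer, tmpl2, w)
  expect_equal(got2$ows, w$gap)
  expect_equal(got2$variant, "primer_gap")
  expect_equal(got2$ows, oracle_best_ows(primer, tmpl2, w))
})

test_that("adding mismatches never decreases the score", {
  pp <- primer_pair("p", "GTGYCAGCMGCCGCGGTAA", "GGACTACNVGGGTWTCTAAT")
  prev <- -1
  for (k in 0:4) {
    sim <- simulate_primer_templates(
      pp, data.frame(fwd_mm = k, fwd_mm_3p = 0, rev_mm = 0, rev_mm_3p = 0),
      seed = 20)
    ows <- best_hit_score(pp$forward, sim$templates$sequence[1])$ows
    expect_gte(ows, prev)
    prev <- ows
  }
})

test_that("pair coverage reproduces the planted per-template design", {
  pp <- primer_pair("p", "GTGYCAGCMGCCGCGGTAA", "GGACTACNVGGGTWTCTAAT")
  ms <- data.frame(fwd_mm = c(0, 0, 0, 1), fwd_mm_3p = c(0, 0, 0, 0),
                   rev_mm = c(0, 0, 0, 0), rev_mm_3p = 0)
  sim <- simulate_primer_templates(pp, ms, seed = 21)
  db <- cbind(sim$templates,
              kingdom = "Bacteria", phylum = c("P1", "P1", "P2", "P2"),
              class = "", order = "", family = "", genus = "", species = "")
  cov <- pair_coverage(pp, db, rank = "phylum")
  expect_equal(cov$pct_perfect[cov$taxon == "Overall"], 75)
  expect_equal(cov$pct_perfect[cov$taxon == "P1"], 100)
  expect_equal(cov$pct_perfect[cov$taxon == "P2"], 50)
  expect_equal(cov$n, c(4, 2, 2))
  # single-primer mode ignores the forward mismatch
  cov_r <- pair_coverage(pp, db, rank = "phylum", mode = "reverse_only")
  expect_equal(cov_r$pct_perfect[cov_r$taxon == "Overall"], 100)
  # relaxing perfect-only to OWS <= 1 can only increase coverage
  ows_f <- vapply(db$sequence, function(s)
    best_hit_score(pp$forward, s)$ows, 0, USE.NAMES = FALSE)
  ows_r <- vapply(db$sequence, function(s)
    best_hit_score(pp$reverse, s)$ows, 0, USE.NAMES = FALSE)
  relaxed <- 100 * mean(ows_f <= 1 & ows_r <= 1)
  expect_gte(relaxed, cov$pct_perfect[cov$taxon == "Overall"])
})

test_that("coverage is invariant to reverse-complementing the templates", {
  pp <- primer_pair("p", "GTGYCAGCMGCCGCGGTAA", "GGACTACNVGGGTWTCTAAT")
  ms <- data.frame(fwd_mm = c(0, 1), fwd_mm_3p = 0, rev_mm = c(0, 0),
                   rev_mm_3p = 0)
  sim <- simulate_primer_templates(pp, ms, seed = 22)
  db <- cbind(sim$templates, kingdom = "Bacteria", phylum = "P",
              class = "", order = "", family = "", genus = "", species = "")
  db_rc <- db
  db_rc$sequence <- vapply(db$sequence, reverse_complement, "",
                           USE.NAMES = FALSE)
  expect_equal(pair_coverage(pp, db, rank = "kingdom"),
               pair_coverage(pp, db_rc, rank = "kingdom"))
})

test_that("amplicon extraction returns the inter-primer region or a reason", {
  pp <- primer_pair("p", "GTGYCAGCMGCCGCGGTAA", "GGACTACNVGGGTWTCTAAT")
  sim <- simulate_primer_templates(
    pp, data.frame(fwd_mm = 0, fwd_mm_3p = 0, rev_mm = 0, rev_mm_3p = 0),
    length = 1000, seed = 23)
  tr <- sim$truth
  amp <- extract_amplicon(sim$templates$sequence[1], pp)
  expect_null(amp$reason)
  expect_equal(amp$fwd_start, tr$fwd_start)
  expect_equal(amp$fwd_end, tr$fwd_end)
  expect_equal(amp$rev_start, tr$rev_start)
  expect_equal(nchar(amp$amplicon), tr$rev_start - tr$fwd_end)
  expect_equal(amp$amplicon,
               substr(sim$templates$sequence[1], tr$fwd_end + 1, tr$rev_start))
  # template lacking the reverse site
  broken <- substr(sim$templates$sequence[1], 1, tr$rev_start - 5)
  miss <- extract_amplicon(broken, pp)
  expect_null(miss$amplicon)
  expect_equal(miss$reason, "missing reverse site")
  # extracting from the amplicon again finds no sites
  again <- extract_amplicon(amp$amplicon, pp)
  expect_null(again$amplicon)
  expect_match(again$reason, "missing")
})
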