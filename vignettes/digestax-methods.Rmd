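---
title: "Methods: reference-database expansion and community profiling for anaerobic digester 16S surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-database expansion and community profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digestax)
```

## Scope

digestax implements the computational core of an ecosystem-specific 16S
rRNA gene survey workflow for anaerobic digesters: expanding a full-length
reference database with new amplicon sequence variants (ASVs) and a
placeholder taxonomy for unnamed lineages; evaluating short-read ASV sets
against that database; scoring PCR primer pairs in silico; classifying
taxa into core and conditionally rare or abundant (CRAT) categories per
metadata group; and the usual diversity statistics. A seeded
synthetic-data generator provides planted ground truth for every stage,
so the whole pipeline is testable without sequencing data.

## Pairwise identity and nearest-neighbour search

Identity between two sequences is computed from an end-gap-free
(semi-global) optimal alignment: `100 * matches / alignment columns` over
the aligned span. Internal gap columns count against identity; terminal
overhangs of the longer sequence are free and excluded. IUPAC ambiguity
codes match whenever their base sets intersect, consistently with primer
matching.

Three numerical choices matter here:

* **Scoring** is match +1, mismatch −1, gap column −2 (linear). With gap
  cost equal to mismatch cost the optimizer pads diverged alignments with
  cheap gaps and inflates identity by several points at 20–30%
  divergence; at −2 the mapping from substitution divergence to aligned
  identity is near-exact down to roughly 74% identity, which keeps
  planted identities inside their intended threshold bands.
* **Coverage**: the shorter sequence must be aligned end to end. A fully
  free overlap alignment degenerates on unrelated pairs to a short
  all-match island (identity ≈ 100% over a dozen columns), which would
  make novelty detection meaningless. Requiring full coverage of the
  shorter sequence removes the degeneracy while preserving the free
  terminal overhangs needed to map short ASVs inside full-length
  references. For equal lengths both orientations are evaluated and the
  larger identity returned, so the measure stays symmetric.
* **Determinism**: cell ties resolve diagonal > up > left, the alignment
  ends at the best last-row cell (largest column on ties), and
  nearest-neighbour ties resolve to the lexicographically smallest
  accession. Tests compare the implementation against an independent
  naive-DP oracle, which is only possible because every tie-break is
  pinned down.

`nearest_neighbor()` scans the whole database by default; an optional
k-mer prefilter (shared distinct 8-mers, usearch-style) restricts the
alignment to the top candidates for large databases. The prefilter is a
heuristic: tests verify it reproduces the exact result on planted data,
and the exhaustive mode remains the reference behaviour.

## Novelty thresholds and placeholder taxonomy

Sequence novelty uses the per-rank identity thresholds of Yarza and
co-workers (phylum 75.0, class 78.5, order 82.0, family 86.5, genus 94.5,
species 98.7 percent): a query whose best database identity falls
*strictly below* a rank's threshold lacks a homolog at that rank.
Boundary values are therefore not novel at that rank. Novelty summaries
use the cumulative row convention: a sequence below the genus threshold
is counted in the genus row and in the species row, so counts increase
monotonically towards species. (The printed tables this convention
mirrors have species counts larger than genus counts, which is only
consistent with cumulative rows.)

`assign_taxonomy()` inherits the nearest neighbour's name at every rank
whose threshold the query meets — kingdom is always inherited — and mints
placeholder names `midas_<rank letter>_<integer>` below the first failing
rank. Placeholders are reused through greedy star clustering, per rank:
the first query to mint a name becomes the cluster centroid, and a later
query joins the cluster iff its identity to the centroid meets that
rank's threshold, scanning centroids in minting order. This is
deliberately order-dependent but exactly reproducible: identical input
order gives byte-identical numbering, which the tests assert. Exact
published clustering pipelines for placeholder taxonomies involve
guide-alignment and tree steps that are out of scope here; greedy
first-come clustering is the simplest order-stable approximation.

## Deduplicating merge

An incoming record is a duplicate iff it has 100% identity with an
already-retained record *and* equal ungapped length. With equal lengths
and end-gap-free alignment, 100% identity is equivalent to per-position
IUPAC-set compatibility, so the merge uses that linear-time check rather
than a full alignment (an exact shortcut, not an approximation). Existing
records always take precedence; incoming records are scanned in input
order; substring containment of one record in another is reported as a
warning count, never collapsed, because "non-redundant" is ambiguous for
containment. The merge satisfies, and tests assert,
`|merged| = n_existing + n_added` and idempotence on re-merging.

## Short-read evaluation

The rare-biosphere filter masks, per sample, every ASV below 0.01%
relative abundance (features at exactly the cutoff are kept). Masking is
per sample rather than table-wide because retained-read percentages are
reported per sample. High-identity coverage is the percentage of retained
ASVs whose nearest-neighbour identity is at least 99%, with ASVs weighted
equally — not by abundance — matching a "percentage of ASVs" reading;
duplicating a sample's counts does not change it.

The taxonomic classifier is a SINTAX-style k-mer bootstrap: 100
iterations each draw 32 of the query's distinct 8-mers with replacement
and vote for the reference sharing most drawn k-mers (ties to the
smallest accession). Per-rank confidence is the fraction of bootstrap
winners carrying the top reference's name at that rank; ranks at or above
the 0.8 confidence cutoff are retained and deeper ranks blanked. Because
the reference taxonomy is a tree, confidence is non-increasing with
depth. Both strands are evaluated; the strand with the better full
(non-subsampled) shared k-mer count is classified, a deterministic rule.
`k = 8`, 32 subsampled k-mers, 100 bootstraps and the 0.8 cutoff are the
published defaults of the tool this re-implements and are all exposed as
arguments.

## In-silico primer evaluation

Primer–template sites are scored with an overall weighted score (OWS):
mismatches weigh 0.4 (1.0 in the 3′ window, default last 5 bases), gaps
1.0 (3.0 in the 3′ window). Categories follow the fixed rule perfect
(OWS = 0), partial (0 < OWS ≤ 1), poor (OWS > 1). The published tool this
mirrors does not print its weights, so the defaults here are configurable
and every coverage report should state the weights used. The site search
enumerates every ungapped offset plus every single-gap variant within the
primer span on both strands — single gaps cover the dominant indel case
while keeping the search exhaustive and oracle-checkable; multi-gap
alignments are out of scope. Pair coverage is the percentage of
references with perfect hits for *both* primers, per taxon at a chosen
rank; a single-primer mode supports pairs where one primer generated the
reference sequences themselves. Amplicon extraction takes the leftmost
perfect forward site and the first reverse site after it, returning
0-based half-open coordinates.

## Core and CRAT profiling

Within a metadata group (substrate × temperature by default), a taxon's
occupancy is the fraction of samples where it exceeds 0.1% relative
abundance. Categories: strict core (occupancy > 0.8), general core
(> 0.5), loose core (> 0.2), else CRAT if the taxon exceeds 1% in at
least one sample, else other. All comparisons are strict, following the
">" wording of the definitions; taxa sitting exactly on an occupancy
boundary are flagged in the output so an inclusive reading can be
audited. Samples with unknown grouping metadata are excluded before
occupancy denominators are formed. The most-wanted list takes each
taxon's highest category across groups under strict > general > loose >
CRAT, dropping taxa that are other everywhere. Shared-core counts use
exclusive (UpSet) intersection patterns, which partition the union.
Replicate samples are treated as independent samples by default, matching
the survey design this models; per-digester averaging can be done
upstream of the profiler.

## Diversity statistics

Rarefaction subsamples without replacement to exactly 10,000 reads,
excluding shallower samples, and is applied to alpha diversity only: the
methods this follows rarefy in the alpha-diversity step but compute beta
diversity from relative abundances of full samples, and that asymmetry is
preserved deliberately. Alpha metrics are observed richness and inverse
Simpson (`1 / sum(p_i^2)`). Bray–Curtis, rarefaction and inverse Simpson
delegate to vegan; PCoA is classical scaling via `cmdscale` with
explained variance relative to the sum of positive eigenvalues, negative
eigenvalues reported rather than corrected, and a deterministic sign
convention (largest-magnitude coordinate positive per axis).

PERMANOVA tests each factor in isolation (marginal), matching a
per-variable R² presentation; no sequential partitioning is attempted.
The permutation p-value uses the `(1 + #{F* >= F}) / (1 + n)` estimator,
which is unbiased and never zero; with 999 permutations the smallest
attainable p is 0.001. For small n an exhaustive mode enumerates every
label permutation, and tests verify agreement with a hand-computed
distance-partition oracle at n = 6 as well as the nominal 5% size of the
test under the null.

## The synthetic-data generator

`simulate_reference_phylogeny()` emulates the rank-calibrated structure
the thresholds assume: a balanced taxonomy whose leaf pairs have target
divergences midway between adjacent rank thresholds (species 3.4%, genus
9.5%, family 15.75%, order 19.75%, class 23.25%, phylum 29%), so each
relationship lands unambiguously inside its threshold band. Mutations are
substitution-only and drawn from one globally disjoint position pool, so
every pairwise divergence is exact by construction; the generator errors
out if branching × divergence exceeds the sequence length. Substitution-
only mutation keeps planted identity analytically controllable; indel
robustness is exercised separately with dedicated alignment fixtures.

`simulate_survey()` plants taxa of known category per group: core taxa
are made abundant (0.5% mean, log-normal noise, σ = 0.3) in exactly
`round(occupancy × n)` samples (defaults 0.9 / 0.65 / 0.35 — safely
inside the strict/general/loose bands), CRAT taxa spike at 3% in one
sample, rare taxa sit at 0.002% everywhere, and ~30 shared log-normal
background taxa (σ = 1.5) fill the remaining mass, giving a realistic
rank-abundance shape. Counts are multinomial at each sample's depth
(default 50,000 reads), so marginal totals are exact. What this does
*not* emulate: compositional sequencing biases, chimeras, PCR and primer
bias, overdispersion between replicates beyond multinomial noise, and
phylogenetically structured abundances — so passing recovery tests show
the classifier logic is correct under the stated model, not that real
digester surveys are free of those artefacts.

`simulate_primer_templates()` embeds both primer binding sites at
recorded offsets with requested mismatch counts split between the 3′
window and the rest, choosing mismatch bases outside the primer's IUPAC
set so a planted mismatch can never be silently compatible.

## Problem sizes

Tests run the alignment oracle on sets up to 30–50 sequences of 400–500
nt, core-recovery at 20 samples per group and 50,000 reads depth across
three groups, and the PERMANOVA null calibration over 500 simulated
16-sample datasets at 99 permutations each (the p-value estimator's test
size is exact for any permutation count, so 99 suffices for the
size check). The acceptance script runs the full pipeline on a
24-reference database of 1,400-nt sequences with a 22-sequence incoming
batch, 16 evaluation ASVs over 6 samples, 20 primer templates, and a
60-sample survey. These sizes were chosen so the planted effects are
comfortably detectable while the whole suite remains quick to run.

## Known limitations

* The greedy placeholder clustering depends on query order (reproducibly
  so); a different input order can mint different numbers.
* Identity semantics differ in detail from any specific aligner
  (usearch, BLAST); the definition used here is stated exactly above and
  embedded in the tests instead.
* The k-mer bootstrap classifier over-classifies moderately novel
  queries (a 96%-identity query is still confidently assigned its
  nearest species), a known property of this classifier family; novelty
  calls should come from identity thresholds, not classifier confidence.
* Occupancy boundary handling (strict ">") follows the written
  definitions; datasets with many taxa exactly on a boundary are flagged
  rather than silently decided.
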