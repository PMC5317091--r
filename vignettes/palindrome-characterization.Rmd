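---
title: "Methods: characterizing short palindromic repeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing short palindromic repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palcore)
```

This vignette is the package's own account of its methods: the matching
model and its assumptions, the statistics behind "overrepresented", the
design decisions that were genuinely open, what the synthetic-data
generator does and does not emulate, and the numerical conventions that
matter when reproducing results.

## The matching model

A pattern is a string over `A/C/G/T/N`. Two annotations ride on it:

* **`N` is a wildcard.** It matches any base and never contributes to the
  mismatch count. This keeps the model two-valued per position — match,
  mismatch, or "don't care" — which is all the repeat-family analyses here
  need.
* **Case marks conservation.** Upper-case positions are the highly
  conserved ones; lower-case are weakly conserved. Case never affects
  matching, only reporting (e.g. `conserved_palindromic_count()` intersects
  the palindromic positions with the upper-case set). For the 18-nt
  consensus `aAACCGTTgaAACGGTTt`, 16 positions are palindromic (each base
  complementary to its mirror) and 14 of them — positions 2–8 and 11–17 —
  are the conserved palindromic set.

The distance between a pattern and an equally long window is wildcard-aware
Hamming distance: the number of non-wildcard positions where the window
base differs. Three conventions are deliberate:

* **No gaps.** Short palindrome cores do not meaningfully indel; an
  ungapped model keeps counts exact and scanning linear.
* **An `N` in the genome at a non-wildcard position is a mismatch.** Masked
  or ambiguous regions must not produce phantom exact hits.
* **Overlapping occurrences all count.** Raw occurrence counts are the
  quantity of record for repeat families; no greedy masking is applied.

`scan_genome()` scans the forward strand only when the pattern equals its
own reverse complement: for such patterns a reverse-strand scan is provably
identical (the mismatch count of a self-reverse-complementary pattern
against a window equals its count against the window's reverse complement —
an involution argument the test suite also verifies by exhaustive
enumeration over all 4^6 windows of a length-6 self-complementary pattern).
Non-palindromic consensi, such as the Rex operator consensus
`TTGTGAANNNNTTCACAA` used for transcription-factor site searches, go
through `consensus_site_search()`, which runs both strands and reports hits
in forward coordinates with a strand mark; the Rex consensus itself happens
to be self-reverse-complementary, so its second pass is suppressed.

**Orientation.** For an even-length core, the two central bases carry the
motif's directionality. `classify_orientation()` assigns the
Hamming-nearest of `GA` (forward) and `TC` (reverse); equidistant
dinucleotides are reported `ambiguous` rather than broken arbitrarily,
because an arbitrary tie-break would manufacture strand signal exactly
where the data are least informative.

**Circularity.** Bacterial chromosomes are circular by default; windows
wrapping the coordinate origin are scanned once and reported with
`end < start`. Whether wrap-around windows were counted in any published
occurrence count is rarely stated; including them is the physically correct
choice and changes nothing when no site straddles the arbitrary origin.

## Conservation profiles

`conservation_profile()` tallies per-position base counts over the matched
sequences of a mismatch stratum (all sites within a budget) and flags a
position "conserved" when its modal base reaches a threshold. The default
threshold is 0.75 modal frequency: "highly conserved" has no canonical
quantification, 0.75 cleanly separates a position drifting at one-in-four
from one under constraint at the copy numbers involved (tens of sites), and
it is a parameter, not a constant. Comparing strata is the point: wildcard
flank positions of a repeat core typically stay conserved among clean sites
but dissolve once the stratum admits several mismatches.

## Overrepresentation statistics

"Overrepresented" requires a null. The package's choice — made explicitly,
since ad-hoc repeat analyses rarely state one — is an **order-k Markov
background fitted to the analyzed genome itself**, default k = 2 with
pseudocount 1 per transition cell. Order 2 controls for dinucleotide and
codon-adjacent composition without modeling genes; order 0 is available for
closed-form checks, and `markov_background_order0()` builds a uniform or
GC-parameterized null directly.

The expected count of a pattern in a genome of length L is
`(L − w + 1) · P(window consistent with pattern)`, with the probability
summed over every concrete word within the mismatch budget (wildcards
marginalize over the four bases; under an order-0 background they
marginalize analytically). The enumeration is capped at 4^10 words; beyond
that, the probability is estimated by Monte Carlo from the background
(default 10^6 windows, seeded by the caller, 2×10^5 inside the pipeline
where the estimate only feeds a z-score). Two approximations are
acknowledged:

* **Stationarity** — word probabilities use the fitted initial distribution
  rather than position-specific chemistry.
* **No self-overlap correction.** The Poisson model below assumes
  occurrences are rare and nearly independent; a pattern that can overlap
  itself violates this. `expected_count()` checks every pattern for shifted
  self-compatibility and warns; the 18-nt core analyzed here cannot overlap
  itself.

Significance is the upper-tail Poisson probability `P(X ≥ observed)` at
mean equal to the expected count, with `z = (obs − exp)/sqrt(exp)` reported
alongside, and Benjamini–Hochberg adjustment across the batch.

**De novo discovery.** `discover_palindromes()` enumerates occurrences of
`X · N^s · revcomp(X)` for all arms X of lengths 6–8 and spacers 2–4 in one
rolling-hash pass per (arm, spacer) combination. Those ranges bracket the
repeat geometry this family of analyses targets (14 fixed positions, 2–4
unconstrained centers) while keeping the hypothesis family enumerable. The
BH adjustment runs against the **full** family — every possible arm at
every spacer (about 2.6×10^5 hypotheses), unobserved candidates carrying
p = 1 — not just the observed candidates; adjusting only observed
candidates would overstate significance under the null. Candidates whose
cores are sub- or super-patterns of a more significant candidate (the same
genomic signal seen through a narrower or wider window) are merged, keeping
the most significant. The default significance level is 0.01.

**Spatial statistics.** "Weak clustering" has no canonical statistic, so
`spacing_uniformity()` reports two and thresholds neither: the one-sample
Kolmogorov–Smirnov distance and p-value of positions/L against uniform, and
the coefficient of variation of circular gaps (CV = 1 is the Poisson
expectation; larger means clumping).

## Genomic context

Context classification is pure interval geometry, and the conventions are
stated because every one of them can change a published count:

* **Coding overlap means ≥ 1 shared bp** with a CDS. Only CDS features
  count as coding; rRNA/tRNA genes do bound intergenic gaps (a gap next to
  a tRNA is still a genuine gap), so flanks are resolved against the
  per-locus envelopes of CDS+rRNA+tRNA. Compound (join) locations collapse
  to their envelope per locus_tag.
* **Flank strands, read left to right**: `(−,+)` divergent (start-to-start,
  the regulatory-rich interval type), `(+,−)` convergent (stop-to-stop),
  otherwise co-directional. Flanks resolve circularly, so on a circular
  genome every intergenic site has both; linear genomes can yield `edge`.
* **Upstream distances are gaps, not offsets**: the number of bases
  strictly between the site boundary and the gene's strand-aware 5'
  coordinate, 0 when adjacent. Published distances rarely say which
  convention they used, so `upstream_distance(convention = "offset")`
  provides the other reading.
* **Replichore halves** are `[ori, ori + ⌈L/2⌉)` versus the rest —
  half-open, so exactly `⌈L/2⌉` positions are "first" for any origin. The
  origin is a required input: `cumulative_gc_skew()` offers the standard
  min/max hint, but the package never silently guesses an origin, because
  every replichore statistic downstream inherits that choice.

The half × central-dinucleotide association is tested with Fisher's exact
test (chi-square fallback when the exact network algorithm is infeasible);
degenerate tables (a single half or single dinucleotide) report p = 1.

## What the synthetic generator emulates

`sim_config()` defaults define the package's reference study conditions — a
desk-scale version of a finished bacterial chromosome carrying a REP-like
family:

| parameter | default | why |
|---|---|---|
| length | 100 kb | large enough for ~100 genes and stable statistics, small enough that the full pipeline runs in seconds |
| gc_target | 0.451 | a mid-range bacterial G+C typical of the genomes this analysis targets |
| n_sites / mismatch_spec | 38 exact + 5 one-mismatch | a realistic copy-number profile for a short repeat family: most copies exact, a thin one-mismatch fringe |
| gene_density | 0.88 | typical CDS coverage of a compact bacterial genome |
| context_mix | 13/38 coding, 9/38 convergent, 2/38 divergent, 14/38 co-directional | intergenic preference with convergent enrichment and divergent avoidance — the signature that distinguishes a structural repeat from a transcription-factor site. The divergent/co-directional split is the one free choice; divergent intervals are kept rare |
| dinuc_bias | first half GA/AA-heavy, second half TC/TT-heavy | a leading/lagging-strand preference: GA-oriented copies on one replichore, their complement on the other, with the one-substitution neighbours (AA, TT, TA) as minor classes |
| orientation_mix | uniform over strand pairs | no reason to bias gene-pair orientation |
| ori | 1 | the generator's coordinate origin doubles as the replication origin |

Generation is one seeded stream per run: genome, feature tiling, strand
chain, placements, instantiations and mutations all consume from it, so a
single integer reproduces a fixture byte-for-byte (`emit_fixture()` writes
the manifest). Planted sites avoid feature boundaries by default so the
context truth is unambiguous, keep a pattern-length buffer from each other,
and after planting the background is scanned at the scrub budget (default
4 mismatches) and accidental matches are re-rolled locally — never touching
planted bases — so the truth table is exhaustive, not merely a subset.

What the generator does **not** emulate: real gene-length and gap-length
distributions (it uses a normal around 900 bp and density-tracking gaps),
operon structure, compositional strand skew, genomic islands,
rearrangements, or sequencing error. Passing the end-to-end tests therefore
shows the pipeline recovers planted truth under a clean Markov background —
it does not certify behaviour on the messier composition of a real genome,
where the Markov background itself absorbs some repeat signal.

Two generator-specific conventions: central dinucleotides are drawn from
the half-specific bias only when both central positions are wildcards in
the core (otherwise the core's own bases stand); non-central wildcard
positions draw from a weak A-flank / T-flank consensus (0.70/0.20 split),
mirroring how real repeat flanks decay from their core.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive everywhere at the interface (GFF3
  convention); GenBank `complement`/`join` locations are converted on read.
* IUPAC ambiguity codes other than `N` in a genome are mapped to `N` with a
  warning; characters outside the IUPAC alphabet are an error.
* `gc_content()` excludes `N` from numerator and denominator and errors on
  an all-`N` sequence.
* Empty site lists produce empty profiles (`n_sites = 0`), empty summaries,
  and p = 1 association tables rather than errors; an empty feature table
  degrades every context call to `edge` with a warning.
* `spacing_uniformity()` requires ≥ 2 positions; ties in positions are
  tolerated (KS with ties warns internally and is suppressed).
* BH adjustment is computed against an explicit hypothesis-family size so
  discovery and targeted enrichment use the same machinery.

## Problem sizes used by the test suite

The suite validates against independent oracles at sizes chosen to finish
in minutes on one core: naive-enumeration scan equivalence on 200 random
genome/pattern/budget triples (L ≤ 3000, w ≤ 10, budgets 0–3); exhaustive
4^6 window enumeration for the strand-symmetry proof; order-1 background
recovery at L = 10^5; the full end-to-end study at the 100 kb reference
conditions; discovery null calibration over 100 seeded 50 kb genomes; and
KS calibration over 100 uniform draws of 100 positions. Planted-core
recovery at rank 1 is checked across 20 seeds at 20 kb with 25 copies.

## Known limitations

* Expected counts ignore overlap autocorrelation; for self-overlapping
  patterns the Poisson p-values are anticonservative (a warning is raised).
* The scanner is exact-window, not index-based; genomes are scanned in
  O(L · d) vectorized passes, fine for bacterial chromosomes, not designed
  for metagenome-scale input or multi-chromosome batching.
* Degeneracy is limited to `N`; the two-letter IUPAC codes are not matched
  as partial wildcards but mapped to `N` on input.
* Replichore assignment is a coordinate split; it does not model the
  asymmetry of an origin that is not diametrically opposite its terminus.
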