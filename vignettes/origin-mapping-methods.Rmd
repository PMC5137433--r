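---
title: "Methods: calling and characterising replication origins from nascent-strand enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and characterising replication origins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oriscan)
```

## The measurement model

In a cell-free replication assay, late-G1 template nuclei initiate DNA
replication near-synchronously after a firing lag of up to ~10 min, and
newly replicated DNA is labelled for a 15 min window. Replication forks in
this system progress at roughly 300 ± 200 bp/min, so each fired origin
produces two labelled tracts extending bidirectionally a few kilobases from
the initiation site. After sonication (100–1000 bp fragments) and
immunoprecipitation of the labelled DNA, sequencing reads pile up in broad
domains around fired origins, superimposed on two backgrounds: a dispersed
elongation signal from the small fraction (~3.5%) of contaminating S-phase
nuclei whose pre-existing forks also incorporate label, and ordinary
sampling noise. An input (pre-IP) library is approximately uniform.

`oriscan` treats origin calling as broad-domain enrichment detection
against a Poisson background, in the tradition of window/island callers
rather than point-summit callers, because the enrichment unit is a
multi-hundred-bp replicated tract rather than a protein footprint.

## Island calling

Reads are deduplicated to at most `redundancy_threshold` (default 1) tags
per (chromosome, start, strand), filtered against an excluded-regions
track, shifted to the presumed fragment midpoint (`fragment_size/2`,
default 100 bp, strand-aware; unstranded tags use their own midpoint) and
counted in non-overlapping `window_size` = 150 bp windows anchored at
coordinate 0 (the trailing partial window is kept and clipped).

The background rate is λ = N·w / (f·G) with N retained tags, w the window
size, G the genome length and f the effective (mappable) genome fraction,
default 0.793 for human-like genomes. On fully synthetic genomes every
base is mappable and analyses use f = 1, so λ equals the realised tag
density. A window is *eligible* when P(X ≥ c; λ) < `eligibility_p`
(default 0.2). Islands are maximal runs of eligible windows allowing up to
`gap_size` (default 0) ineligible windows internally; the island score is
Σ −log P(cᵢ; λ) over eligible member windows (natural log; the base only
rescales thresholds and the calibration uses the same base).

**E-value calibration (no-input mode).** The score threshold s\* is the
smallest s for which the expected number of background islands scoring ≥ s
over the genome's n windows is at most the E-value. For gap size 0 this
expectation is computed by dynamic programming: under the iid Poisson null
a run of eligible windows starts at a given window with probability
(1−p)p (p the eligibility probability), run length is geometric, and the
run score is the corresponding mixture of k-fold convolutions of the
single-window score distribution. Scores are discretised on a 0.01-nat
grid and convolved by FFT; the truncation keeps mass above 10⁻¹⁷ and run
lengths contribute until their geometric weight falls below 10⁻¹³, so
discretisation error in s\* is far below one tag's score contribution. For
`gap_size > 0` — a configuration the default workflow does not use — the
function falls back to the Monte-Carlo null (simulated Poisson genomes),
which is also available explicitly (`null_method = "monte_carlo"`) and
serves as the independent check of the recursion in the test suite.
Islands scoring exactly s\* are retained (≥ comparison).

**With-input mode.** Candidate islands are found in the IP library exactly
as above; each is then tested with a Poisson tail on its IP tag count with
mean equal to the input tag count in the same window span — floored at a
pseudocount of 1 to avoid zero means in shallow input — scaled by the
IP/input library-size ratio, followed by Benjamini–Hochberg control at
`fdr`. Both modes are exposed because they behave differently on real
data; the no-input mode is the default for this assay (input libraries
contain replicated origin-proximal DNA and can mask true calls).

Called islands separated by at most one window (150 bp) are merged, with
scores and tag counts summed; the merge is idempotent.

## Catalogue, nulls and analytics

The origin catalogue is the base-pair intersection (≥1 nt) of the two
replicate island sets, with book-ended pieces merged. The published
wording for this step is ambiguous between strict intersection and
merge-of-union; intersection was chosen because the catalogue is defined
as regions "present in both" replicates, and the reciprocal-overlap
counter reports the element-wise Venn quantities either way.

Two width-preserving randomisations provide the control distributions:

* **chromosome mode** — each origin keeps chromosome and width, its start
  is re-drawn uniformly; destroys both clustering and timing structure;
* **timing jitter** — the start is shifted by a uniform integer in
  ±`jitter_halfwidth` (default 240 kb, half the ~480 kb average early
  timing window), preserving the replication-timing profile while
  destroying fine-scale position.

Placements that would extend past the chromosome end are redrawn (bounded
retries, then an error naming the origin); the source procedure's
spreadsheet randomisation could emit out-of-bounds peaks, and redrawing is
this package's convention for keeping every control interval a valid
genomic range while preserving the width multiset exactly. Null origins
may overlap each other; no joint permutation is attempted.

Analytics follow the conventions of the field: inter-origin distances are
successive midpoint differences per chromosome in 5 kb half-open bins
(edge-to-edge available via `measure = "edge"`); timing profiles count an
origin in every S1–S6 window class it overlaps, so percentages may sum
above 100 where classes overlap; genic annotation assigns one category per
origin with priority TSS > exon > intron > intergenic (promoter-first,
matching the TSS-centric biology; a ±500 bp TSS window by default);
skew-jump overlap uses a nested set of windows {2, 4, 6, 10, 20, 30, 40} kb
centred on the jump nucleotide (wider jump intervals are collapsed to
midpoints), reported separately for positive and negative polarity.

## Sequence features

The G-quadruplex scanner implements the canonical motif — `n_runs` = 4
runs of ≥ `min_run` = 3 guanines separated by loops of `loop_min` = 1 to
`loop_max` = 7 bases — as maximal leftmost chains over maximal G-runs:
consecutive qualifying runs are chained while their gap is a legal loop
(no `N`), and every maximal chain of ≥ 4 runs is one non-overlapping
motif from first-run start to last-run end. The C-strand pattern is
reported as minus-strand motifs at plus-strand coordinates. Loop bounds
are configurable; genome-wide motif counts shift with this choice, which
is why exact reproduction of any particular published motif tally is not
attempted. Greedy non-overlapping intervals were chosen over enumerating
all alternative overlapping motifs because the motif track is consumed by
overlap counting.

Compositional skew is S = (T−A)/(T+A) + (G−C)/(G+C) per non-overlapping
1 kb window on the plus strand; a term with zero denominator contributes
0, which makes an all-T window score exactly 1 and preserves the
antisymmetry S(revcomp) = −S. The trailing partial window is computed on
the remaining bases and flagged. Skew-jump *detection* is out of scope:
jump coordinates are consumed as a BED track.

## The synthetic generator

`sim_config()` encodes the study conditions: forks at 300 ± 200 bp/min
(normal, truncated at 1 bp/min, one rate per fork, constant over the
run), firing time uniform on [0, 10] min within a 15 min labelling window,
fragments uniform 100–1000 bp, 3.5% of IP fragments uniform genome-wide
(the elongation background; the real background is heterogeneous, but a
uniform model is the simplest that is testable), input uniform, and
IP-A at half the per-origin depth of IP-B (`ip_efficiency_A = 0.5`),
mirroring the observed replicate asymmetry. The default genome is
4 × 5 Mb with 400 genes and 250 origins — large enough for stable
calibration statistics, small enough that a full run takes well under a
minute — with timing domains tiled as 400 kb blocks cycling S1…S6 plus a
20 kb overlap between adjacent blocks (timing windows overlap in real
annotations). Within strata, placement weights decline from S1 to S6, so
planted catalogues show the early-skewed density the assay observes.

Choices the experimental literature does not pin down, decided here once:

* **Per-origin firing probability.** No in-vitro per-origin efficiency is
  quantified; the configured value (default 0.3) is the mean of a uniform
  spread (0.05–0.55 at the default), so efficient (p ≥ 0.3) and weak
  origins coexist and recall can be reported as a function of efficiency.
* **TSS and timing structure.** Defaults plant ~50% of origins in ±500 bp
  TSS windows and 75% in S1∪S2, the catalogue-level structure the method
  is expected to recover; each origin draws its TSS and early flags
  independently, and placement guarantees the flags geometrically, so the
  planted fractions are exactly binomial.
* **Clusters and jumps.** 15% of origins are planted < 5 kb from an
  earlier origin of the same kind; 10% are flagged germline and emit a
  positive skew jump at their position, while negative jumps are planted
  ≥ 50 kb from any origin — giving the clustering and jump-overlap
  analyses planted structure with known direction.

What the generator does *not* emulate: sequencing error and base
qualities, mappability variation, GC bias, copy-number structure,
fork stalling or fusion of converging forks, and heterogeneous
backgrounds. Passing tests therefore demonstrate that the computational
pipeline recovers the statistical structure it assumes, not that the assay
itself is unbiased on real chromatin.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open on disk (BED) and 1-based closed in
  memory (`GRanges`); the readers and writers are exact inverses.
* Window partitions anchor at coordinate 0; trailing partial windows are
  kept.
* `eligibility_p ≥ 1` makes every window eligible; thresholds that no
  candidate can fail return 0 with a warning rather than an error.
* Empty libraries yield empty island sets; with-input calling requires a
  non-empty input. Chromosomes with fewer than two origins contribute no
  inter-origin distances; empty catalogues summarise with flagged `NA`
  quantiles.
* All stochastic stages take explicit seeds; the generator splits its seed
  deterministically per stage (genome / origins / libraries) so
  regenerating one stage does not shift another's stream. Fixed seeds give
  byte-identical outputs, which the run manifest (MD5 checksums) records.

## Problem sizes used in validation

The shipped validation suite calibrates the caller on 200 signal-free
10 Mb genomes with 10⁵ tags each and checks the recursion against a
500-replicate Monte-Carlo null; caller/oracle equivalence is exhaustive on
100 random ≤ 100-window genomes; recovery and asymmetry run on the default
4 × 5 Mb conditions; interval analytics are checked against quadratic
brute-force implementations at 1000 elements. These sizes give stable
statistics for every directional claim while keeping a full validation run
in the minutes range on one CPU.

## Known limitations

* The with-input mode implements scaled-Poisson testing with a pseudocount
  of 1; published island callers differ in their input smoothing, so
  with-input results are comparable in kind but not bit-for-bit with any
  specific implementation.
* The E-value recursion assumes iid Poisson windows; real tag fields are
  multinomial given the library size and weakly autocorrelated, which
  makes the threshold very slightly conservative at genome scale.
* G4 scanning is motif-based, not thermodynamic; no scoring of quadruplex
  stability is attempted.
* Multi-replicate (> 2) intersection is iterated pairwise application, not
  a joint model.
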