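# oriscan

Mapping DNA replication origins from nascent-strand enrichment sequencing.

In a cell-free replication system, newly initiated DNA near origin firing
sites is labelled, immunoprecipitated and sequenced. Origins then appear as
broad read-enrichment domains (hundreds of bp to a few kb) over a dispersed
elongation background. `oriscan` implements the full downstream workflow for
such data, for genomicists who have aligned read tags (BED) and want a
reproducible origin catalogue plus its standard characterisation:

1. **Island calling.** Deduplicated tags (redundancy threshold 1) are
   shifted to their fragment midpoints (fragment size 200 bp) and binned
   into 150 bp windows. Window counts are scored against a Poisson
   background with rate λ = N·w/(f·G) (N tags, window w, effective genome
   fraction f = 0.793, genome length G). Windows with counts whose Poisson
   upper tail falls below 0.2 are *eligible*; maximal runs of eligible
   windows (gap size 0) form candidate islands with score
   Σ −log P(cᵢ; λ). In no-input mode, islands are kept when the expected
   number of background islands with equal or larger score genome-wide is
   at most the E-value (default 10⁻⁵); the null is computed exactly by
   dynamic programming or by Monte-Carlo simulation. In with-input mode,
   each candidate's IP count is tested against the scaled input count in
   the same span with Benjamini–Hochberg control at the FDR. Called islands
   separated by at most one window (150 bp) are merged.
2. **Replicate intersect.** The origin catalogue is the base-pair
   intersection (minimum overlap 1 nt) of the two replicate island sets.
3. **Randomised controls.** Width-preserving nulls: uniform re-placement
   within each chromosome, or positional jitter within ±240 kb (half the
   average early replication-timing window), which approximately preserves
   the catalogue's timing profile.
4. **Characterisation.** Per-chromosome counts and width quantiles,
   inter-origin distance histograms (5 kb bins), S1–S6 replication-timing
   profiles, TSS/exon/intron/intergenic annotation (TSS priority, ±500 bp
   windows), pairwise Venn overlap counts with external origin sets,
   G-quadruplex motif scanning (four runs of ≥3 G, loops 1–7 nt, both
   strands), compositional skew S = (T−A)/(T+A) + (G−C)/(G+C) in 1 kb
   windows, and nested-window (up to 40 kb) overlap profiles around
   positive and negative skew jumps.
5. **Synthetic experiments.** A generator emulates the labelling assay —
   bidirectional forks at 300 ± 200 bp/min, firing lags up to 10 min in a
   15 min labelling window, 100–1000 bp sonication fragments, 3.5%
   S-phase elongation background, replicate A at half the per-origin depth
   of replicate B — with a truth table, so recall/precision of the whole
   pipeline can be measured.

## Worked example

```r
library(oriscan)

sim <- sim_config(seed = 1)            # default synthetic study conditions
ev  <- simulate_and_run(sim, caller_config(),
                        analyses = c("distances", "venn"))
ev
#> SimEvaluation: 214 called / 250 planted origins
#> recall (efficient) = 1.000, recall (all) = 0.888, precision proxy = 1.000
#> replicate overlap: A->B 0.991, B->A 0.892
```

Reading: of 250 planted origins, every origin with per-nucleus firing
probability ≥ 0.3 was recovered by the replicate-intersect catalogue
(recall 1.0); weakly firing origins bring overall recall to 0.888; every
called origin lies within labelled-tract reach of a planted origin
(precision proxy 1.0). Because replicate A has half of B's per-origin
depth it calls fewer islands, but 99% of them are confirmed in B, versus
89% the other way round — the expected direction of replicate asymmetry.

Calling real libraries directly:

```r
genome <- read_chrom_sizes("hg.chrom.sizes")
ip_a <- read_library("IP_A.bed", "IP-A", genome)
ip_b <- read_library("IP_B.bed", "IP-B", genome)
cfg  <- run_config(genome, ip_a, ip_b, caller = caller_config(e_value = 1e-5),
                   out_dir = "results")
res  <- run_pipeline(cfg)
```

A thin shell wrapper with `simulate`, `call`, `intersect`, `shuffle`,
`distances`, `g4`, `skew` and `evaluate` subcommands is installed at
`system.file("scripts", "oriscan", package = "oriscan")`.

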