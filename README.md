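# genomescars

Tumour whole-genome sequencing leaves quantitative scars: read depth
steps at copy-number breakpoints, chromosome arms shattered into dozens
of amplicons, fold-back junctions where breakage–fusion–bridge (BFB)
cycles amplified an oncogene, and discordant read pairs at structural
variants. `genomescars` is an R package plus analysis workflow that
turns those signals into estimates, for people who study tumour genome
architecture (HER2-amplified breast cancer being the motivating
setting) and need every step testable without access to protected
patient data.

The pipeline covers, as one coherent model:

- **Copy number from binned read depth.** Expected bin counts follow
  the tumour/normal mixture `level(c) = (2α + (1−α)c)/(2α + (1−α)Q)`
  with contamination α and tumour mean ploidy Q. GC bias is removed
  with an empirical per-GC-stratum model; the relative read-count (rRC)
  distribution is Kalman-smoothed and fitted with an evenly spaced
  Gaussian comb whose spacing `s = (1−α)/(2α+(1−α)Q)` and baseline
  `b0 = 2α/(2α+(1−α)Q)` invert in closed form to `α = r/(r+2)`
  (`r = b0/s`) and `Q = (1−b0)/s`. A Gaussian HMM with means pinned at
  the comb levels segments the genome; states map to the rCN scale
  (rCN > 3 amplification, 3 ≥ rCN > 1 gain, rCN < 1 loss, rCN = 0
  homozygous deletion) and to the fraction of genome altered (FGA).
- **Genome scars.** Firestorm arms (≥ 20 segments, ≥ 10 copy levels,
  ≥ 5 amplifications), large-scale state transitions (breaks between
  adjacent ≥ 10 Mb regions after smoothing away variation < 3 Mb, the
  genome-wide count being a BRCAness score), and minimal common regions
  of amplification across samples.
- **Structural variants** from discordant read pairs and soft-clipped
  reads, with orientation-based typing, base-pair breakpoint
  resolution, matched-normal germline subtraction, and the four support
  filters (≥ 2 pairs, ≥ 2 clips per cluster, ≥ 15 aligned clipped
  bases, ≥ 1 mappable breakpoint).
- **BFB compatibility.** An exact decision for whether a per-segment
  copy-count vector is reachable by breakage–fusion–bridge cycles, with
  a witness folding pattern, the longest compatible stretch, a
  constant-shift mode for extra homologous-chromosome copies, and
  verification of the fold pattern against clipped-read orientations
  (left fold ⇒ right-clipped reads, and conversely).
- **Expression subgroups.** Variance filtering (χ² test against the
  median variance plus top-5‰ relative standard deviation),
  Ward/Pearson hierarchical clustering into four groups, single-sample
  centroid classification with an unassigned "O" outcome, cluster
  stability scoring, and single-sample ECDF gene-set enrichment.
- **Synthetic data generators** for every input above, so the whole
  pipeline runs end to end from seeds.

## Worked example

The numbered scripts under `analysis/` form the workflow. The first
simulates a four-tumour cohort (50,000 one-kilobase bins each) plus SV
evidence and a 99-sample expression cohort; the second runs the
copy-number model:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_cnv_profiles.R
```

```
T01: alpha 0.00->0.00, Q 2.0->1.97, 29 segments, FGA 40%, acc 99.5%
T02: alpha 0.20->0.20, Q 2.0->1.99, 23 segments, FGA 40%, acc 99.8%
T03: alpha 0.30->0.32, Q 3.4->3.34, 68 segments, FGA 50%, acc 97.4%
T04: alpha 0.40->0.40, Q 2.0->1.99, 21 segments, FGA 40%, acc 99.8%
```

Each line compares the configured contamination/ploidy with the comb
fit's estimate, then reports the segment count, fraction of genome
altered, and the share of bins decoded to their true copy state. The
scars script works the minimal-common-region arithmetic on GRCh37
coordinates, refining a shared amplicon to

```
refined amplicon: chr17:37818020-37924454 (106 kbp; prior aCGH region 248 kbp)
```

and the BFB script validates a simulated amplification history from its
copy counts alone:

```
simulated per-segment counts: 2 2 10 8 12 0
BFB-compatible: TRUE
BFB fold pattern: 4 fold(s) over 6 segment(s)
 order boundary  fold clip_side
     1        5  left     right
     2        2 right      left
     3        4 right      left
     4        3  left     right
clip-orientation consistency: 4 consistent, 0 inconsistent, 0 unmatched observation(s), 0 missed fold(s)
with +2 homologous copies: direct test FALSE, after shift-2 TRUE
```

The fold pattern's clip sides are exactly what the clipped reads at
those boundaries show, and the same counts sitting on two extra copies
of the homologous chromosome validate only after subtracting the
constant shift — the behaviour expected when one homologue is intact.

See `vignettes/genomescars-methods.Rmd` for the models, parameter
choices and limitations.

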