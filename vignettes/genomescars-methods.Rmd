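---
title: "Models and methods behind genomescars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind genomescars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomescars)
```

`genomescars` re-implements, as one tested pipeline, the computational
core of a tumour whole-genome study: read-depth copy-number modelling
with contamination and ploidy estimation, arm-level instability scores,
structural-variant calling from paired-end evidence, breakage–fusion–
bridge (BFB) compatibility testing, and expression-subgroup discovery.
This vignette explains each model, the tunable parameters that matter,
and the choices made where the design was genuinely open. Nothing here
states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The read-count mixture model

A tumour sample is a mixture of tumour cells and normal (diploid) cells.
With contamination $\alpha \in [0,1]$ and tumour mean ploidy $Q > 0$,
the expected GC-corrected relative read count (rRC) of a region with
tumour copy number $c$ is

$$\mathrm{level}(c) \;=\; \frac{2\alpha + (1-\alpha)\,c}
                               {2\alpha + (1-\alpha)\,Q},$$

so levels are evenly spaced with spacing
$s = (1-\alpha)/(2\alpha+(1-\alpha)Q)$ and baseline
$b_0 = 2\alpha/(2\alpha+(1-\alpha)Q)$ (the level of a homozygous
deletion, carried entirely by contaminating normal DNA). The inverse map
is closed-form: $\alpha = r/(r+2)$ with $r = b_0/s$, and
$Q = (1-b_0)/s$. A frequently quoted alternative writes the spacing as
$1/(Q + 2\alpha(1-\alpha))$; that form agrees with the mixture model
only at $\alpha = 0$, and we treat it as a typographical variant — the
mixture-derived form is the one consistent with the linear relation
between absolute copy number and rRC that the rest of the pipeline
relies on.

`simulate_cn_genome()` realizes exactly this model: expected bin counts
are `depth * gc_bias(gc) * level(c)`, with Poisson noise by default
(negative-binomial overdispersion optional). Poisson is the simplest
model consistent with read-count data; the real study's count noise is
unknown, so this choice is a stand-in, not a claim about the data. The
default GC-bias curve is a unimodal quadratic in GC fraction — the
qualitative shape an empirical GC correction has to remove.

## GC correction and smoothing

`build_gc_model()` implements an empirical GC model: mappable bins are
sampled, bins with extreme counts (outside the 1st–99th percentile by
default — "extreme" is not otherwise defined, so this is our
operational definition) are ignored, counts are stratified by GC
percent (101 strata), summarised by the per-stratum median and smoothed
with loess. The predictor is then calibrated so that the mean of
raw/predicted over the sampled bins is 1; this puts rRC on a
genome-average scale, which the ploidy inversion above requires
(otherwise $\hat Q$ would be relative to the modal rather than the mean
copy number).

`smooth_rrc()` is a fixed-interval (local-level) Kalman smoother run
per chromosome, with process-to-observation variance ratio 0.01 by
default. No smoothing parameters are prescribed by the source method
("Kalman filter" is all it says); the ratio trades bin-level
resolution against level separation and 0.01 resolves 1-kb bins into
clean comb peaks at depth ~100× while still following segments a few
hundred bins long. Smoothing never crosses a chromosome boundary and
returns constant series unchanged.

## The Gaussian comb and its identifiability limit

`fit_gaussian_comb()` locates peaks of a kernel density estimate of the
smoothed rRC distribution (bandwidth 0.02 rRC units), merges peaks
closer than `min_spacing` (0.12 — sub-resolution structure such as a
wide amplified level splitting the kernel estimate is one level, not
two), and estimates the spacing by scoring integer-fraction candidates
of the observed peak gaps: each candidate is ranked by the
height-weighted squared fractional distance of all peaks to its grid,
and among candidates that fit comparably well the **largest** spacing
wins, because any fit at spacing $s$ is matched by $s/2$ but never the
reverse. Copy numbers are then assigned to peaks, and $(b_0, s)$ are
refined by regressing every bin on its assigned copy state.

Peak positions alone cannot distinguish $(\alpha, Q)$ from the solution
with every copy number shifted by one — the likelihood is identical.
The original analysis resolved this with SNP allele frequencies, which
are out of scope here; we anchor the fit with the documented assumption
that the lowest observed level is copy `lowest_peak_copy` (default 0,
i.e. the profile contains a homozygous deletion). The default synthetic
genome plants an HD segment, which heavily rearranged tumour genomes
realistically carry; a profile without one should be fitted with
`lowest_peak_copy = 1`. This is a genuine limitation, not a bug: purity
and ploidy estimation from total depth alone is degenerate in every
tool of this kind.

## HMM segmentation and state labels

`segment_copy_number()` decodes the most likely copy-state path with a
univariate Gaussian HMM whose state means are pinned at
$\mathrm{level}(c)$, $c = 0..c_{\max}$ ($c_{\max} = 20$ by default —
high-level amplicons exceed modest grids, and the final state absorbs
anything higher), a shared emission variance estimated from the data,
and a uniform self-transition probability $1-\varepsilon$ with
$\varepsilon = 10^{-5}$ (no transition parameters are prescribed; this
value makes segment switches cost roughly ten bins of emission evidence
at the default SNR). Viterbi decoding is used rather than posterior
decoding because the object of interest is the segmentation itself.
Both the Viterbi decoder and the Kalman smoother are written in the
package: no maintained HMM package is available in the deployment
environment, and both are short textbook algorithms.

Segment states follow the relative copy-number (rCN) scale, with
rCN = 1 the tumour mean ploidy: rCN > 3 amplification,
3 ≥ rCN > 1 gain, rCN = 1 neutral, rCN < 1 loss, rCN = 0 homozygous
deletion. Decoded integer states sit exactly on 1 only when $Q$ is
integral, so the pipeline widens the neutral band to half a copy
(`neutral_tol = 0.5/Q`); `classify_segment_states()` applies the exact
printed rule when `neutral_tol = 0`. The fraction of genome altered
(FGA) is the length fraction of segments with rCN ≠ 1, measured on
mappable extent — neither the denominator nor "altered" is defined
precisely by the source, so these are our operational choices.

## Firestorms, LSTs and minimal common regions

A chromosome arm is in *firestorm* when it has at least 20 segments
reaching at least 10 distinct copy levels, at least 5 of them
amplifications (rCN > 3). Levels are counted on decoded integer states,
not raw rRC floats — the states are the discrete levels the model
describes.

Large-scale state transitions (LSTs) are copy-number breaks between
adjacent regions of ≥ 10 Mb each, counted per arm after removing all
variation shorter than 3 Mb and ignoring breaks at annotated
centromeric/unmappable gaps. The smoothing rule absorbs each
sub-threshold segment into its longer flanking neighbour (ties merge
left — the absorption direction is unspecified in the source) and
iterates to a fixed point; total arm coverage is conserved.

`minimal_common_region()` computes the maximal interval contained in at
least one gained/amplified interval of every sample. Abutting intervals
of a sample are merged first (they are one contiguous gained region);
per-sample merged sets are intersected and the longest surviving
interval is reported, leftmost on ties. A sample contributing no
qualifying interval is an explicit error naming the sample.

## Structural variants

Discordant pairs (wrong FR orientation, mates on different chromosomes,
or insert beyond mean + 4 sd — the multiplier is unspecified in the
source and configurable here) are clustered when both ends co-locate
within `insert_mean + 3 sd`; soft-clipped reads cluster by shared clip
position (± 5 bp) and side. A candidate is a discordant cluster plus
attached clip clusters; its type follows from the pair orientations
(long-insert FR: deletion; everted RF: duplication; same-strand:
inversion; cross-chromosome: inter-chromosomal), and clip clusters
resolve its breakpoints to the base pair. Candidates whose breakpoints
match a matched-normal candidate of the same type within 300 bp are
germline; somatic calls must pass all four support filters (≥ 2
discordant pairs; ≥ 2 soft-clipped reads per attached clip cluster;
≥ 15 aligned clipped bases; ≥ 1 breakpoint in a mappable region). The
evidence model carries the *aligned* clipped-base count per read, so
the clipped-base filter consumes that field directly; sequence-level
realignment of clipped bases is outside the evidence representation.

## Breakage–fusion–bridge testing

The BFB model: a chromosome arm is a run of segments with the stable
(centromere-proximal) end first. A cycle breaks the chromatid at a
segment boundary, keeps the proximal part, and fuses the sister
chromatids head-to-head; the first break may lose only the telomere.
The observed chromosome is any proximal prefix of a cycle product (the
final break is healed without fusion), which is what makes odd copy
counts observable.

The decision algorithm `is_bfb_count_vector()` rests on a canonical-path
argument: any observable chromosome is a prefix of $q\,\overline{q}$
(where $\overline{q}$ is the mirrored half) for a half-word $q$ built by
the chain $q_1 = (1..k)$,
$q_{i+1} = q_i\,\overline{q_i}[1..t]$ with $1 \le t \le |q_i|-1$.
Rewriting an arbitrary cycle path into this form never increases the
number of cycles and keeps every intermediate per-segment count below
the observed count — so a breadth-first search over canonical
half-words, pruned against the target counts, is sound *and* complete,
with no cap on intermediate chromosome sizes needed. The same argument
justifies the count cap in the exhaustive enumerator
`enumerate_bfb_vectors()`. The two routes share this theory, so the
test suite keeps a third, theory-free oracle: literal uncapped replay of
raw break–fusion cycles at tiny bounds, which the enumerator must
reproduce exactly. Accepted vectors return a witness fold pattern that
replays to the input counts; "longest compatible sequence" means the
longest contiguous subvector (segments are physically contiguous), ties
broken leftmost. Because the retained end of a real amplicon is
unknown, the decision can be run in either orientation or both
(`orientation = "unspecified"`).

Fold orientation ties the pattern to read evidence: where the fold
occurs to the left, reads spanning the junction align on their left
part and are soft-clipped on their right (3') side, and conversely.
`check_clip_orientation_consistency()` matches observed breakpoints to
folds within a tolerance and applies exactly this rule; a boundary can
host folds of both directions, so an observation is consistent if any
fold within tolerance matches its clip side.

Two consequences of the model worth knowing: a vector with a positive
count distal to a zero count is never accepted (every break truncates
the distal end), and not every single-entry vector is valid — with one
segment the only reachable counts are 1 and 2. A constant baseline
shift (extra copies of the homologous chromosome) is an explicit
integer parameter of `collapse_acn_segments()`; a shift that would make
any count negative is an error, not a clamp.

## Expression groups

`filter_probesets()` keeps features passing both criteria: a variance
test against the median feature variance — implemented as
$(n-1)s_g^2/s^2_{\mathrm{median}}$ referred to the upper tail of
$\chi^2_{n-1}$, the usual form of this filter; the exact statistic of
the original tool is not public, so this is flagged as our reading —
and membership in the top 5‰ by relative standard deviation. The two
criteria are intersected; with these data sequential application is
equivalent. Clustering is agglomerative with $1-$Pearson dissimilarity
and Ward linkage (`ward.D2`); centroids are computed on the per-feature
centred-reduced matrix; the single-sample predictor assigns each
profile to the centroid with the largest Spearman correlation, or to
"O" below 0.1, ties broken in fixed label order A–D. Cluster stability
is the size-weighted fraction of the modal label per cluster (weighting
is our choice; unweighted aggregation is not meaningfully different at
these cluster sizes). Single-sample enrichment uses unweighted ECDFs of
the set and complement genes along the expression-ranked list — the
source method mentions no weighting exponent, so this deliberately
diverges from weighted variants of single-sample GSEA.

The expression generator plants four groups: three quarters of the
informative genes are group markers (one quarter per group) and one
quarter form two disjoint gradient sets running in opposite directions
across the group order — emulating opposed luminal-differentiation
programs. Defaults (20,000 genes, 160 informative, 99 samples in groups
of 25/25/25/24, shifts of 3 noise sd) mirror array-scale data where the
5‰ filter retains on the order of 100 features.

## What the synthetic data does and does not show

The generators reproduce the statistical *structure* the analyses
assume: evenly spaced depth levels under contamination, GC bias of a
smooth unimodal shape, discordant/clip signatures with a configurable
background rate, BFB count vectors with oriented folds, and
well-separated expression groups. They do not emulate mappability
artefacts correlated with GC, replication-timing waves, subclonal copy
number, microhomology at breakpoints, or cross-platform batch effects.
Passing tests therefore demonstrate correctness of the algorithms under
the stated models, not performance on real tumour genomes.

## Problem sizes and numerical choices

The standard synthetic profile used throughout is two 25-Mb chromosomes
at 1-kb bins (50,000 bins) at depth 100, ten equal truth segments per
chromosome including a homozygous deletion and one high-level
amplification, with the length-weighted mean copy equal to the
configured ploidy exactly. Contamination/ploidy recovery is evaluated
on the grid $\alpha \in \{0, 0.2, 0.4\} \times Q \in \{2, 3.4\}$;
segmentation accuracy on the $\alpha = 0.3, Q = 2$ profile. SV calling
is benchmarked at 4 supporting pairs per event over 1 noise pair/Mb
across 20 seeds; BFB closure over 200 random histories; the exhaustive
BFB grid covers all vectors of length ≤ 5 with entries ≤ 6 under ≤ 8
cycles. These sizes keep the whole suite in the low tens of seconds
while leaving every estimate's error an order of magnitude inside its
tolerance. All generators take explicit integer seeds and restore the
caller's RNG state; identical seed and configuration give bit-identical
output. Midpoint rounding in the rRC-to-aCN map is performed after a
9-decimal round so that exact midpoints round away from the baseline
despite floating-point division.
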