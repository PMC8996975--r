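---
title: "Methods: dual-cohort enrichment, panel scoring and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-cohort enrichment, panel scoring and validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`crosspath` discovers a gene panel shared between two diseases by running
the same enrichment pipeline on two independent case-control expression
cohorts and intersecting the results. This vignette documents the models,
the tunable parameters, the numerical conventions, and what the synthetic
benchmark does and does not establish.

## Input model

Each cohort arrives as one probe-level matrix in two normalizations of the
same hybridizations: a strictly positive linear-intensity track (MAS5-style
scaled intensities) and a log2 track (gcRMA-style model-based values). The
package treats the normalizations as given — producing them from raw array
images is out of scope — and assumes log2 values are approximately Normal
per probe, the standard microarray noise approximation. Phenotypes are
two-class (disease vs control, first factor level = disease), with at least
two samples per class for any ranking operation.

## Nonspecific filtering

A probe passes when (a) its linear-track mean intensity across all samples
reaches `intensity_floor` (default 50) and (b) its log2-track coefficient
of variation, CV = 100·sd/mean with the sample (n−1) standard deviation
computed over both classes pooled, lies in the closed window
`[cv_low, cv_high]` (default [10, 100] percent). Both predicates are
evaluated per probe and intersected.

Conventions worth stating explicitly:

* CV is sd/mean. The inverse ratio (mean/sd) is sometimes written in
  informal descriptions of this filter, but a 10–100% window is only
  meaningful for sd/mean; we treat the inversion as an erratum.
* "Intensity at least 50 across all cases" is ambiguous between *every*
  sample and an aggregate. The default compares the mean (the common
  nonspecific-filter convention, robust to single dropouts);
  `strict_floor = TRUE` demands every sample clear the floor.
* The window is closed: CV exactly 10% or 100% passes.
* A zero-mean log2 row has an undefined CV and is reported as not passing
  rather than raising an error.

## Probe collapse

For each gene the probe with the highest mean expression across all
samples is selected and its entire row becomes the gene's row; unmapped
probes are dropped. Ties break to the lexicographically smallest probe ID,
making the collapse deterministic. The selection is made once, on the log2
(analysis) track, and the same probe indexes the linear track, so the
fold-change and ranking stages describe one physical probe per gene.
Genes keep the input's first-appearance order, which makes collapsing an
already gene-level matrix the identity.

## Absolute GSEA

Genes are scored by signal-to-noise
s_g = (μ_D − μ_C)/(σ_D + σ_C), with each class σ floored at 0.2·|μ| (0.2
when μ = 0) — the classical variance floor that keeps near-constant genes
from dominating the ranking. The metric is configurable (`"s2n"`, a
floored Welch-type `"t"`, or `"diff"` of class means); signal-to-noise is
the default because it is the convention of the established desktop
implementations of this method. In absolute mode (default) genes are
ranked by |s_g| so up- and down-regulated set members both enrich at the
list top; classic signed ranking remains available.

The enrichment score of a set S (n_S members in an N-gene universe) is the
extremum of the running sum with hit increments |s_i|^p/N_R (default
p = 1, N_R = Σ_S |s_i|^p) and miss increments 1/(N − n_S). The running sum
always closes at zero; maxima can only occur at hit positions and minima
just before hits (or at the end), which the permutation engine exploits to
evaluate ES from member positions alone in O(n_S) per set. A tie between
the positive and negative extremum resolves to the positive one. Sets
with n_S = 0 or n_S = N have a degenerate miss denominator and are
skipped with a recorded reason, as are sets outside the size window
(default 15–500 after intersection with the universe).

### Permutation statistics

The default null permutes phenotype labels (`n_permutations = 1000`).
When the number of distinct label splits C(n, n_D) − 1 does not exceed the
request, the engine enumerates all splits except the identity and reports
exact permutation statistics. A `gene_set` mode (random same-size member
sets on the observed ranking) is provided for cohorts too small for label
permutation to have resolution.

* Nominal p = (1 + #{same-sign |ES_π| ≥ |ES|}) / (1 + n_permutations) —
  the +1 smoothing avoids zero p-values. Exceedance counting allows a
  1e−9 slack so permutations that tie the observed ES in real arithmetic
  (the complementary label split in absolute mode is an exact tie) are not
  broken by floating-point summation order.
* NES = ES / mean(same-sign |ES_π|), per set; permuted NES are normalized
  the same way.
* FDR q for a set with NES\* is the fraction of pooled same-sign permuted
  NES at least as extreme as NES\* divided by the fraction of observed
  same-sign NES at least as extreme, clipped to 1; coherence is enforced
  per sign by a cumulative minimum from the least extreme end, so a more
  extreme NES never carries a larger q.
* FWER p is the fraction of permutations whose same-sign extreme NES
  beats the observed NES.
* Leading edge: members at or before the peak (positive ES), or at or
  after it (negative ES); tag% = |leading edge|/n_S, gene% = peak/N
  (mirrored for negative ES), signal = tag%·(1 − gene%)·N/(N − n_S).

Significance uses nominal p strictly below `alpha_nom` (default 0.05) and
FDR q at or below `fdr_cut` (default 0.25, inclusive).

## Panel scoring and intersection

Each gene's frequency is the number of significant sets whose leading edge
contains it. No universal numeric threshold exists for "high frequency",
so both selection modes are offered and recorded: `top_k` (default 10,
keeping all ties at the boundary count) and `min_count`. Fold change is
the ratio of linear-track class means — deliberately not re-exponentiated
log2 means — and classification is strict (`fc > up_cut` up,
`fc < down_cut` down), so an up-cutoff of 1.0 means "any increase" and a
fold change exactly at a cutoff is `neither`. Default cutoffs are 1.0/0.75
for cohort A and 1.5/0.5 for cohort B, the conventions for airway-epithelium
and tumor cohorts respectively; both are per-cohort arguments. The final
panel is the intersection of the two cohorts' selections whose calls agree
and are not `neither`. Pathway-name intersection is case-insensitive after
whitespace normalization because two runs may stylize set names
differently; gene intersection is exact.

## Validation statistics

**qPCR.** Replicate Ct wells more than one cycle from their replicate
median are discarded (standard triplicate QC; at least two usable wells
per assay), then ΔCt = mean Ct(target) − mean Ct(reference) per sample.
The calibrator is a *group*: ΔΔCt subtracts the calibrator group's mean
ΔCt per gene, matching a design that compares groups rather than naming a
calibrator sample. rq = 2^−ΔΔCt and log2 rq = −ΔΔCt exactly; shifting all
Ct values by a constant leaves rq unchanged. Ct values outside (0, 45) are
rejected as physically impossible. Amplification-efficiency correction and
multiple-testing adjustment across genes are intentionally not applied.

**Mann–Whitney.** Exact enumeration when the combined sample is ≤ 12 and
untied (all the target use cases, with 3–8 samples per group, fall here),
otherwise the normal approximation with midrank ties and continuity
correction; two-sided throughout; three observations per group minimum.
The rank-sum machinery is `stats::wilcox.test`; the package's test suite
checks it against an independent brute-force enumeration of label
assignments.

**Survival.** The median split assigns values strictly above the sample
median to the high group (median-tied values go low). Best-cutoff scanning
is deliberately not offered: optimizing a split against the log-rank
statistic inflates significance unless corrected. Kaplan–Meier estimation
and the log-rank test are computed via the `survival` package (events
precede censorings at tied times); the hazard ratio is the O/E
approximation (O_h/E_h)/(O_l/E_l) with CI exp(log HR ± 1.96·√(1/E_h+1/E_l)),
which matches the log-rank machinery without a model fit and slightly
attenuates large ratios relative to a Cox fit — users needing covariate
adjustment should fit a Cox model instead. A group with zero events yields
an unbounded HR, flagged, with the test still reported.

## Synthetic benchmark

The generator draws the log2 track per probe from
Normal(baseline + shift, σ) with shift = ±delta_log2 for planted genes in
diseased samples, and derives the linear track as 2^log2 times unit-median
multiplicative noise, so the two tracks measure the same simulated RNA.
Defaults — baseline mean 7, σ = 1, linear noise σ = 0.1 on the log2 scale
— put typical CVs near 14%, inside the filter window, and linear
intensities near 128, above the floor, emulating post-QC arrays. Decoy
sets are size-matched to planted sets and drawn from unplanted genes so
FDR behaves meaningfully at small scale. A gene planted in several sets is
shifted once, and conflicting planted effects are rejected. All
randomness derives from one user seed through a fixed documented
seed-splitting map, so a single integer reproduces any run.

The benchmark condition (`shared_panel_design()`) plants five 20-gene
up-regulated sets per cohort that all contain the same 7-gene shared panel
plus cohort-specific members drawn from separate pools — the situation the
leading-edge frequency score is designed for, where true panel genes recur
across many enriched pathways. Cohorts use 20 vs 20 samples, 600 genes ×
3 probes, delta_log2 = 2, and 20 decoy sets; pipeline-level tests scale
the universe down (200–400 genes, 100–150 permutations) to keep the suite
fast, and the null-calibration check uses a 1000-gene, 100-decoy
exchangeable cohort with 500 permutations. These sizes are the package's
benchmark choices, not statements about real cohorts.

What passing these tests shows: the statistics are computed correctly
(exact agreement with brute-force oracles), the permutation test is
calibrated under exchangeability, and the pipeline recovers a strongly
planted shared panel with few false positives. What it does not show:
robustness to batch effects, correlated genes, probe-level artifacts,
GC-content bias, or annotation errors — none of which the generator
simulates — nor anything about the biological validity of panels derived
from real cohorts.

## Known limitations

* Two-class designs only; no continuous phenotypes or >2 classes.
* Gene symbols are the identity; isoform- or probe-variant-level analysis
  is out of scope.
* The permutation FDR is the pooled-permutation estimate, not a
  closed-form procedure; with very few sets it is coarse.
* The O/E hazard ratio attenuates for large effects (a planted ratio of 3
  is typically recovered around 2.3–2.7 at n = 500 with 10% censoring, as
  the acceptance run reports).
* With `top_k` selection and flat frequency counts, the tie-keeping rule
  can select many genes; the cross-cohort intersection and direction
  agreement are then the effective filters.
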