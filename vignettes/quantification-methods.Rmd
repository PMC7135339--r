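---
title: "Quantification methods for mitochondrial stress phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for mitochondrial stress phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`wormupr` reimplements, as tested R code, the quantitative analyses used
to study how autophagy suppresses the mitochondrial unfolded protein
response (UPR^mt^) in *C. elegans*: whole-animal fluorescence-reporter
quantification, mitochondrial TMRE segmentation with an
intensity-per-area readout, a gated statistical decision procedure,
an LC-MS lipidomics feature pipeline with triacylglycerol (TG)
sum-composition analytics, single-worm qPCR variability analysis, and
the bookkeeping of a genome-wide suppressor screen. Every pipeline is
exercised on seeded synthetic data with exact ground truth; no raw
micrographs or instrument files are required.

## Whole-animal reporter quantification

Animals expressing a stress-reporter GFP are imaged as groups of 15–20
larvae per field. Segmentation applies the Triangle automatic threshold
to the 8-bit histogram (the bin maximizing perpendicular distance to the
line from the histogram peak to the far tail, with mirroring when the
peak sits in the upper half of the occupied range), keeps the bright
side, removes particles under 10 px, and accepts an explicit exclusion
list in place of interactive object removal so runs are reproducible.
The mean intensity under the mask is the per-image measurement; the mean
outside the mask is recorded as background.

Group normalization follows the study's convention:

```
normalized(x) = (x - mean(wt control)) / (mean(mutant control) - mean(wt control))
```

so the unstressed wild type sits at 0 and the stressed mutant control at
1, and `percent_suppression = 100 * (1 - mean(normalized))`. The
normalization is invariant under common affine changes of the raw
intensities (gain and offset), which is why per-image background
subtraction is available (`subtract_background`) but off by default:
the shared baseline cancels in the group normalization. A second scheme,
`normalize_to_control()`, divides by a single control-group mean for
designs with no stressed reference.

## Mitochondrial TMRE workflow

TMRE is a potentiometric dye: in non-quenching mode its mitochondrial
fluorescence is proportional to membrane potential, so the mean raw
intensity over the mitochondrial area is the potential proxy. The mask
is built by a fixed operator chain:

1. linear min–max conversion to 8-bit (round half-up; a constant image
   maps to zero),
2. rolling-ball background subtraction, radius 15 px, implemented as a
   true grayscale opening by a spherical-cap structuring element (no
   downsampling shortcut — the radius is small),
3. minimum filter, radius 1 (the full 3×3 square),
4. mean filter, radius 2 (discrete disk: pixel centers within radius),
5. tubeness at scale σ = 1.0: Gaussian-derivative Hessian, eigenvalues
   ordered by magnitude, response σ²·|λ₂| where λ₂ < 0 and zero
   elsewhere,
6. min–max requantization of the floating-point response to 8-bit,
7. IsoData (Ridler–Calvard intermeans) threshold, foreground strictly
   above the returned level,
8. removal of components under 10 px (areas of exactly 10 survive).

Intensities are always measured on the raw image under the final mask —
filtered intensities would depend on the normalization chain. Numerical
conventions: all neighborhood operators replicate edges (avoiding dark
rims that would bias masks); threshold ties resolve to the first bin
achieving the optimum, and IsoData starts from the overall mean and
stops at the first integer fixed point (a two-cycle resolves to the
smaller level); the second-derivative kernel is re-centered to an exact
zero sum and the image is mean-centered before convolution, so constant
fields give an exactly zero response; 8-connectivity is the default for
particle analysis. Because step 1 rescales to the observed range, the
mask is bit-identical under affine intensity rescaling of noise-free
input — a property the test suite asserts exactly.

Two parameters deserve comment. The original acquisition tool converts
16-bit to 8-bit by a display range that is not recoverable; we fix the
range to the image min/max for determinism and expose explicit `lo`/`hi`
as the deviation knob. And the requantization of the tubeness response
(step 6) is likewise min–max, recorded here because results are
sensitive to it: a fixed-scale alternative would turn structure-free
images into a degenerate-histogram error instead of a noise mask (see
Limitations).

## Gated group statistics

Comparisons follow one decision procedure throughout. Two groups:
Shapiro–Wilk on each at the gate level (0.05; the gates' levels are a
package choice, recorded in the output); if both pass, an F-test decides
between the pooled-variance t-test and Welch's correction. When a
normality gate fails in a two-group design the procedure stays in the
t-family and uses Welch's test as the robust fallback — rank-based
routing is reserved for many-group designs, matching how the original
analyses were reported. Three or more groups: Shapiro–Wilk per group
plus Brown–Forsythe (ANOVA on absolute deviations from group medians);
all gates passing routes to one-way ANOVA with Dunnett's many-to-one
post hoc test, any failure to Kruskal–Wallis with Dunn's many-to-one
rank tests, Bonferroni-adjusted over the family (the original analyses
name Dunn's test but not its adjustment).

Dunnett p-values use the equicorrelated multivariate-t formulation with
correlations √(nᵢnⱼ/((nᵢ+n₀)(nⱼ+n₀))); the quasi-Monte-Carlo
integration runs under a fixed internal RNG stream so repeated calls are
reproducible, and a unit test cross-checks the values against an
independent reference implementation. Constant-variance degenerate input
is decided on the means alone (t = 0, p = 1 for equal means). The test
suite calibrates the full gated procedure under an all-null Gaussian
design (5 groups × 15, 2,000 simulations) and checks the family-wise
error stays near the nominal 0.05.

## Lipidomics feature pipeline

The pipeline starts from an exported feature-intensity table (vendor
peak detection and alignment are upstream and out of scope). Steps:

- **QC presence/RSD filter.** Keep features detected in *every* pooled
  QC injection with QC RSD = 100·SD/mean strictly below 30%. The SD is
  the sample (n−1) standard deviation — QC counts are small.
- **Protein normalization.** Biological samples are divided by their
  protein content (µg); QCs are untouched, so the filter and the
  normalization commute on the surviving feature set.
- **Drift normalization.** Per feature, a locally weighted regression
  (lowess, span 0.75) of QC intensity on injection order estimates the
  instrument drift; every sample is divided by the trend at its own
  order and rescaled to preserve the QC median. The original vendor
  algorithm is unspecified; lowess is our choice and is recorded in the
  output. With fewer than four QC anchors no trend is identifiable and
  the correction falls back to a per-feature QC-median level alignment
  (logged). With five or fewer anchors lowess effectively interpolates
  the QC points, so the post-correction QC RSD is near zero by
  construction — the informative check is the bio-sample correction.
- **Welch differential tests.** Per feature, two-sided Welch t between
  groups on normalized intensities, missing values excluded pairwise and
  never imputed; a feature with fewer than 3 values per group is flagged
  rather than fatal. Direction calls use the raw p < 0.05 with no
  multiplicity correction — deliberately matching the original
  analysis — while a Benjamini–Hochberg column is emitted for reference.
- **Annotation filter.** Spectral-match annotations are kept only when
  forward *and* reverse scores are strictly above 0.75.
- **TG landscape.** Features parsed as sum compositions (`"TG 52:3"` →
  class, total acyl carbons, total double bonds) are grouped into
  carbon × double-bond cells with isomer and up/down counts. A cell is
  *called* up or down only when a strict majority of its detected
  isomers is significantly in that direction: with ~5% false positives
  per feature, an any-significant rule would recolor multi-isomer cells
  far too often. Class totals sum QC-passing features only (the
  alternative — all annotated features — is not what the filter chain
  produces) and `set_overlaps()` provides exact Venn-region counts for
  two or three differential sets.

## Single-worm qPCR variability

Wells flagged as failed PCRs or wrong melting peaks are blanked (the
melting-peak judgment is upstream and arrives as a flag) and worms with
no surviving well are dropped. Expression is plain ΔCt — each gene's Ct
minus the worm's mean housekeeping Ct, expression `2^-ΔCt` — assuming
perfect doubling; efficiency-corrected quantification is deliberately
out of scope, but primer quality is tracked through standard curves:
`efficiency% = 100 · 10^(−1/slope) / 2`, with the optimal slope −3.3
giving an amplification factor of 10^(1/3.3) ≈ 2. Inter-individual
variability is the sample CV (SD/mean, n−1) of relative expression
across worms, normalized so a designated reference record (the highly
variable *nlp-29* locus in wild type) equals 1. The original wording is
ambiguous about whether CVs were taken on the expression scale or on
normalized Ct values; the package defaults to the expression scale and
exposes `delta_ct()` for the cycle-scale alternative. Missing wells are
excluded pairwise; nothing is imputed.

## Synthetic data and what passing tests mean

The generators produce every input with exact ground truth: worm-shaped
Bezier tubes on a gently textured autofluorescent background; tubular
(long, low-curvature filaments, 2–4 px wide) versus fragmented
(ellipses of 10–60 px) mitochondrial fields whose in-structure intensity
is `potential_scale × amplitude` — the fragmented condition plants
0.37, mirroring the 63% potential reduction of fusion-deficient
animals; lipid tables with lognormal baselines, planted fold changes,
multiplicative linear drift and a pooled QC leading every block of ten
injections; and 36-worm Ct tables with planted per-gene CVs over three
near-invariant housekeeping genes. Noise is Poisson shot noise
(counts = gain × signal) plus Gaussian read noise, applied last — the
simplest model with fluorescence-like variance scaling. Identical seed
and parameters give byte-identical output.

Default image size is 512×512 (16-bit); the test suite and the
acceptance script run at 192–256 px with 12–20 images per group and
200–2,000 simulation replicates, sizes at which every planted effect in
this document is comfortably detectable. The generators do not model
optics (no PSF, no depth structure), worm anatomy, pharyngeal
autofluorescence, or vendor-side peak-picking artifacts — so passing
tests demonstrate that the *computational* chain recovers planted
truth, not that the workflows are robust to everything real microscopes
and mass spectrometers produce.

## Known limitations

- **Small-fragment resolution.** The 3×3 minimum filter erodes a
  10–15 px blob to one or two pixels; its tubeness response is then dim
  relative to larger structures and falls below the relative IsoData
  threshold or the 10-px particle cutoff. Fragments under roughly 20 px
  are routinely missed — an inherent resolution floor of the published
  operator chain, not a tunable defect.
- **Structure-free fields.** On images with no real structures, min–max
  requantization stretches residual noise and IsoData then splits the
  unimodal response near its middle, leaving a large spurious
  foreground. The workflow presupposes structures are present; a
  perfectly constant field raises a degenerate-histogram error instead.
- **Conversion sensitivity.** Results depend on the 16→8-bit display
  range; the min/max default is deterministic but not necessarily what
  the original interactive sessions used.
- **Dunn adjustment and gate levels** are conventions (Bonferroni,
  0.05) where the original description is silent; both are surfaced in
  the result object rather than hidden.
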