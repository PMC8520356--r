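---
title: "Methods: hybrid threshold segmentation, ventricular morphometry, and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid threshold segmentation, ventricular morphometry, and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoventry)
```

## Scope

`neoventry` quantifies lateral-ventricle morphology on single axial brain
MR slices of newborns and compares index distributions between a diseased
group (congenital septal defects, CHD) and controls. It contains four
cooperating parts: a threshold-segmentation family, a morphometry module,
a statistics module, and a synthetic-data layer (phantom slices and
simulated cohorts) that provides ground truth for all of them. This
vignette records the model, the concrete conventions adopted where the
method family is loosely specified in the literature, the tunable
parameters, and the known limitations.

## Segmentation model

Let *f* be an M×N image with L gray levels. Global threshold segmentation
picks one threshold T and maps the image to a binary map; the
multi-threshold variant uses ascending thresholds T₁ < … < Tₙ and assigns
class *k* to pixels with T_k < f ≤ T_{k+1}. T is chosen by the Otsu
criterion: maximize the between-class variance

σ²_B(t) = ω₀(t) ω₁(t) (μ₀(t) − μ₁(t))²,  class 0 = {g ≤ t},

over t ∈ [0, L−2]. At every t the identity σ²_B(t) + σ²_W(t) = σ²_total
holds; the test suite asserts it to 1e−9 on normalized histograms.

A single global threshold ignores local contrast. The human visual system
is most sensitive to contrast changes at edges, so the hybrid method
treats edge-adjacent pixels separately:

1. **Gradient map.** Sobel magnitudes S(i,j) = √(Gx² + Gy²) with the
   standard 3×3 kernels and replicate-padded borders, the global mean
   S_avg, and 3×3 window means S_μ(i,j).
2. **Pixel classification.** A pixel is *detail* (label l₁) iff
   min(S, S_μ) > S_avg, else *remainder* (l₂). The published descriptions
   of this rule state only its ingredients (S, S_μ, S_avg) and its purpose
   (noise suppression); the concrete form here is this package's own
   choice. It uses all three quantities, is noise-suppressing (an isolated
   spike has a high S but a diluted S_μ), and the *strict* inequality
   makes constant images all-remainder, so the pipeline degrades
   gracefully to plain Otsu. The rule is isolated behind
   `classify_pixels()` so alternates can be swapped.
3. **Decomposition.** I₁ = detail pixels, I₂ = complement. The masks
   always partition the image — no overlap between segmented areas.
4. **Per-sub-image thresholds.** T₁ and T₂ are Otsu thresholds computed
   over the member pixels of I₁ and I₂ only; a sub-image with ≤ 1 distinct
   gray value falls back to the whole-image T_otsu (an empty one yields an
   empty map and a warning).
5. **Merge.** B = B₁ on I₁ and B₂ on I₂, bitwise; `merge_masks()` refuses
   non-partitioning masks.

Polarity: foreground is f > T by default (bright target). On T2-weighted
acquisitions CSF is bright; rather than guessing an acquisition, both
polarities are exposed via the `foreground` argument (`"above"` /
`"below"`) throughout.

Tie-breaks and determinism: the smallest maximizing threshold is returned,
`which.max` semantics, so results are bit-reproducible across platforms;
`hvs_segment()` on identical input is bit-identical. A fixed-tiling local
Otsu (`tiled_segment()`, default 32 px tiles) is included purely as the
classical comparison baseline, not as part of the hybrid pipeline.

## Morphometry conventions

Four dimensionless indices are measured per slice from a ventricle mask
and a brain mask. Widths are horizontal (along image rows), outer-edge to
outer-edge: a pixel run from column l to r spans (r − l + 1) × spacing mm.

Clinically, a radiologist picks the measurement level by eye. Here the
levels are explicit windows over the ventricle row extent (first row with
ventricle pixels to last): the anterior **horn segment** is the first
`horn_frac` (default 1/3) of rows, the **caudate band** the next
`caudate_frac` (default 0.1), and the **body segment** the remainder.
Then:

- **F/F′**: F is the widest ventricle outer span within the horn segment
  (ties resolved to the most anterior row); F′ the brain width at that row.
- **D/D′**: D is the *minimal* outer span over the body segment; D′ the
  brain width at the minimizing row. The body window deliberately excludes
  the caudate band: the caudate-level waist is narrower than the bodies
  and would otherwise capture the minimum.
- **C/C′**: C is the ventricle outer span at the caudate row (middle of
  the caudate band — the level where the caudate head borders the
  ventricle). The operational definition of this index is not standardized;
  this row-selection strategy is the package's reconstruction and is
  configurable through `caudate_frac`.
- **Evans**: maximal ventricle outer span over all rows ÷ maximal brain
  width over all rows. Since the maximal frontal-horn width is by
  definition the widest ventricle span on a normal slice, the Evans
  numerator coincides with the horn landmark; in the phantom the two are
  tied explicitly (`max_frontal_width = frontal_horn_span`).

Measurement is 2-D and single-slice throughout; no volumetry.

## The phantom generator

`phantom_spec()` / `make_phantom()` render a single axial slice: a bright
brain ellipse (semi-axes in mm) on a dark background with dark ventricle
structures — paired anterior-horn wedges whose span tapers linearly from
`horn_tip_frac × F` at the tip to F at the horn level, a narrow
caudate-level waist of span C, and parallel body bands of span D. The
shapes are chosen so that every landmark of the morphometry module is
well defined and analytically computable; real ventricular anatomy is more
curved, but the measured quantities are row spans, which the phantom
reproduces exactly.

Degradations: a smooth multiplicative radial bias field of relative
amplitude `bias_amplitude` (left-right symmetric, so symmetry tests stay
meaningful) and additive zero-mean Gaussian noise of SD `noise_sigma` gray
levels, seeded. Gaussian noise (not Rician) is a deliberate
simplification: the purpose is to stress thresholding, and at the SNR of
structural neonatal MRI the difference is immaterial for that purpose; the
noise model sits behind a single code path and could be swapped. Masks and
true indices are computed from the noise-free geometry and are invariant
to `noise_sigma`, `bias_amplitude`, and `seed`.

Default geometry (chosen as plausible for a term newborn at 1.5 T):
192×192 px at 0.5 mm/px, brain semi-axes 42 × 45 mm (84 mm biparietal),
tissue/CSF/background intensities 180/60/20, ventricle extent from −0.60
to +0.30 of the AP semi-axis. What the phantom does **not** emulate:
partial-volume effects, sequence-dependent contrast (TE/TR), motion,
3-D continuity across slices. Passing phantom tests therefore demonstrates
correctness of the algorithmic chain, not clinical segmentation accuracy
on real scans.

## Cohort simulation and statistics

`sample_cohort()` draws each subject's four indices independently from
per-group normal distributions; `table1_groups()` carries the reference
parameters (CHD n = 150: F/F′ 0.301 ± 0.035, D/D′ 0.261 ± 0.039, C/C′
0.138 ± 0.018, Evans 0.239 ± 0.052; control n = 50: 0.296 ± 0.031,
0.234 ± 0.032, 0.124 ± 0.015, 0.233 ± 0.025). Draws are clipped to (0,1)
because the indices are ratios; at the reference parameters clipping is
rarer than 1 in 10⁵ draws and is counted in the `n_clipped` attribute.
Indices are drawn independently within subject — real indices correlate
(they share the brain diameter denominator), which matters for none of the
per-index statistics computed here but would matter for multivariate
extensions.

Statistical conventions:

- **t-tests**: both pooled (default) and Welch forms; one-tailed tests
  take the direction group 1 > group 2, appropriate for D/D′ and C/C′
  where the diseased group is expected to be larger. Computed through
  `stats::t.test()`; the summary-statistic form (`t_from_summary()`)
  evaluates the same formulas from means/SDs/counts directly.
- **χ²**: Pearson on 2×2 tables via `stats::chisq.test()`, Yates optional
  and off by default.
- **ICC**: the reliability of two human raters measuring the same
  subjects is modelled as ICC(2,1) — two-way random effects, absolute
  agreement, single measurement:
  (MS_R − MS_E) / (MS_R + (k−1)MS_E + (k/n)(MS_C − MS_E)), k = 2.
  Absolute agreement (rather than consistency) is the defensible default
  for interchangeable clinical raters because it penalizes systematic
  bias. Mean squares come from `stats::aov()`; the test suite checks the
  combination against a definitional sums-of-squares oracle.
- **ROC**: empirical, cutoffs at the distinct observed scores, positive
  call = score above the cutoff (direction configurable); AUC is the
  Mann–Whitney probability with ties at half credit, which equals the
  trapezoidal area of the tie-corrected curve. The Youden-optimal cutoff
  maximizes J = sens + spec − 1, ties to the smallest cutoff. For two
  normal classes the closed form Φ(Δμ/√(σ₁²+σ₂²)) (`binormal_auc()`)
  serves as the analytic oracle: 0.704 for the D/D′ parameters and 0.725
  for C/C′.
- **Multiplicity**: no multiple-testing correction is applied to the four
  indices; consumers comparing many indices should adjust externally.
- p-values come from exact distribution functions (`pt`, `pchisq`), never
  simulation.

A note on internal consistency of the reference statistics: the group
summaries above imply pooled t = 4.42 (Welch 4.88) for D/D′ and a sex-
distribution χ² of 0.169 (82/68 vs 29/21), and these recomputed values are
what the package reports; they are the quantities the test suite asserts.

## Problem sizes and reproducibility

Simulation-backed checks use: 1000 random histograms for the Otsu oracle,
100 seeded phantoms for the segmentation invariants and the
hybrid-vs-global comparison (noise SD 15, 10% bias), 200 random phantom
geometries spanning index ratios 0.1–0.4 for morphometric recovery, 200
replicate cohorts for the AUC reproduction, and 500 replicates for
simulator calibration and ICC(2,1) recovery (rater noise SD 0.0172,
chosen so the generating ICC at the D/D′ between-subject SD is 0.837).
These sizes keep every Monte-Carlo standard error well below the
corresponding tolerance. All stochastic entry points take an explicit
integer seed and restore the caller's RNG state; identical config + seed
reproduces every output byte-for-byte.

## Limitations

- Segmentation separates tissue from non-tissue by intensity only; no
  morphological post-processing, atlas priors, or learned models. On real
  scans, skull stripping / brain outlining must come from elsewhere — the
  pipeline uses the phantom's brain outline when reconstructing the
  ventricle mask from a segmented slice.
- The caudate index's operational definition (row selection) is a
  reconstruction; different window choices shift C/C′ systematically.
- PNG output is 8-bit (`png::writePNG` limitation); use NIfTI for deeper
  gray scales. 16-bit PNG is supported on read.
- Index ratios are quantized by pixel size: expect absolute errors up to
  roughly spacing/denominator (~0.006 at 0.5 mm on an 84 mm brain).
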