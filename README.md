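# neoventry

Adaptive threshold segmentation and lateral-ventricle morphometry for
neonatal brain MRI, with the cohort-level statistics used to compare a
congenital-heart-disease (CHD) group against controls.

Newborns with congenital septal defects show subtle delays in brain
development that are visible on axial MR slices as relative enlargement of
the lateral ventricles. Quantifying this requires three steps, all
provided here:

1. **Segmentation** of the slice into tissue and non-tissue by a hybrid
   global/local Otsu method guided by edge information,
2. **Morphometry**: four dimensionless ventricular indices measured on the
   segmented slice,
3. **Cohort statistics**: inter-rater reliability (ICC), group
   comparisons (t, χ²), and diagnostic performance (empirical ROC, AUC,
   Youden-optimal cutoffs).

Because no clinical images are distributed with the package, a synthetic
**phantom generator** renders axial slices with known ventricular geometry
(analytic ground truth), and a **cohort simulator** draws per-subject index
values from the per-group normal distributions of a 150-CHD / 50-control
study, so every stage is testable end to end.

## The method

**Segmentation.** For an image *f* with gray levels 0..L−1, the Otsu
threshold maximizes the between-class variance
σ²_B(t) = ω₀(t)ω₁(t)(μ₀(t) − μ₁(t))² over candidate thresholds *t*
(class 0 = {g ≤ t}; ties broken toward the smallest *t*). The hybrid
method first computes the Sobel gradient magnitude S(i,j), its global mean
S_avg, and the 3×3 local window means S_μ(i,j); a pixel is labelled
*detail* when min(S, S_μ) > S_avg (requiring the window mean suppresses
isolated noise spikes). The detail pixels form sub-image I₁, the rest I₂;
each sub-image receives its own Otsu threshold (T₁, T₂; degenerate
sub-images fall back to the whole-image T_otsu) and the two binary maps
are merged: B = B₁ on I₁, B₂ on I₂. With no detail pixels the result
reduces exactly to global Otsu.

**Morphometry** (per axial slice, widths along image rows in mm):

| Index | Definition |
|---|---|
| F/F′ | widest outer span of the anterior horns ÷ same-level brain transverse diameter |
| D/D′ | minimal outer span of the ventricle bodies ÷ same-level brain diameter |
| C/C′ | ventricle wall span at the caudate level ÷ same-level brain diameter |
| Evans | maximal frontal-horn width ÷ maximal biparietal diameter |

**Statistics.** Two-rater ICC(2,1) (two-way random effects, absolute
agreement, single measurement), pooled or Welch two-sample t (one- or
two-tailed), Pearson χ² on 2×2 tables, the empirical (Mann–Whitney) ROC
with ties at half credit, and the cutoff maximizing Youden's
J = sensitivity + specificity − 1.

## Worked example

```r
library(neoventry)

## a noisy, bias-shaded phantom slice with known geometry
ph  <- make_phantom(phantom_spec(noise_sigma = 15, bias_amplitude = 0.10,
                                 seed = 42))
seg <- hvs_segment(ph$image)
seg
#> <hvs_segmentation> 192 x 192; T_otsu = 102, T1 = 102 (detail, 3892 px), T2 = 101
#> foreground ('above' threshold): 22570 px (61.2%)
dice(seg$B, ph$tissue_mask)
#> [1] 0.9999114

## measure the ventricular indices on the segmented slice
m <- measure_indices(!seg$B & ph$brain_mask, ph$brain_mask, spacing = 0.5)
m$indices
#> F/F' = 0.300  D/D' = 0.244  C/C' = 0.123  Evans = 0.286
ph$true_indices
#> F/F' = 0.300  D/D' = 0.237  C/C' = 0.128  Evans = 0.286

## a simulated 150 CHD vs 50 control cohort, compared per index
co <- sample_cohort(table1_groups(), seed = 1)
st <- cohort_stats(co, positive_group = "CHD", tails = "one")
st$d_ratio$t
#> pooled test: statistic = 5.821, df = 198, p (one-tailed) = 1.165e-08
st$d_ratio$roc
#> <roc_result> AUC = 0.759 over 200 cutoffs (positive = high); Youden J = 0.413 at cutoff 0.2421

## inter-rater reliability with simulated raters
rated <- simulate_raters(co, "d_ratio", rater_noise_sd = 0.0172, seed = 2)
icc_two_rater(cbind(rated$rater1, rated$rater2))
#> ICC(2,1) = 0.848  (n = 200 subjects, 2 raters, absolute agreement)
```

The Dice overlap shows the hybrid segmentation recovers the tissue mask
almost perfectly despite noise and shading; the measured indices agree
with the analytic truth to within one-pixel quantization; and on the
simulated cohort the body index D/D′ separates the groups (one-tailed
p ≈ 10⁻⁸, AUC ≈ 0.76 in this replicate).

A thin command-line front end with the same capabilities lives at
`inst/cli/neoventry.R` (subcommands `simulate-phantom`, `simulate-cohort`,
`segment`, `measure`, `stats`, `run`), and `run_pipeline()` ties the whole
chain — simulate → segment → measure → statistics — into one reproducible
JSON report.

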