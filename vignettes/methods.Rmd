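---
title: "Methods: image-derived knee phenotyping and association power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-derived knee phenotyping and association power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Knee osteoarthritis (OA) is diagnosed radiographically, yet biobank
association studies usually ascertain cases from billing codes, which
under-report disease and discard severity. This package studies — entirely
in simulation, with known ground truth — the consequences of three ways of
phenotyping the same cohort:

1. a **quantitative endophenotype**, the minimum joint space width (mJSW)
   measured from bone segmentation masks;
2. its **dichotomization** at a target case fraction (a stand-in for an
   image-based case classifier: both threshold the same latent severity);
3. an **EHR-style record** that observes the dichotomization through a
   sensitivity filter (under-diagnosis).

The central claim examined is that, at equal sample size, the quantitative
analysis yields more genome-wide significant loci and stronger polygenic
prediction than either binary analysis, even though the phenotypes are
highly genetically correlated.

## Knee phantoms and the mJSW measurement

`generate_knee_phantom()` draws filled femur/tibia/fibula polygons into an
8-bit raster plus a label mask (0 background, 1 femur, 2 tibia, 3 fibula).
The femoral condyle is a shallow parabola, the tibial plateau flat, and the
fibula a lateral polygon kept out of the femur–tibia overlap so it can
never contaminate the gap. The per-column femur–tibia gap is the quadratic
through the requested lateral/center/medial gaps (in mm) placed at the
midpoints of the three thirds of the overlap; it is discretized by rounding
to whole pixels and the rounded profile is stored as ground truth. A
requested gap below one pixel at the given spacing is rejected as
unresolvable.

Measurement (`gap_profile()`, `nine_point_leg_jsw()`, `subject_mjsw()`)
works purely on the mask: in every column containing both bones the gap is
the count of rows strictly between the lowest femur pixel and the highest
tibia pixel, floored at zero (adjacent bones measure 0; the `-1` makes
"touching" and "one row apart" distinguishable). Gaps are vertical within a
column rather than nearest-neighbour Euclidean distances: this matches an
index-matrix implementation, is deterministic, and admits an exhaustive
row-scan oracle that the test suite applies to every fixture mask. The leg
value is the mean of nine sampled gaps — the overlap is split into three
equal contiguous thirds (lateral/center/medial, resolved from the scan's
side metadata; the fibula side is lateral) and each third is sampled at the
columns nearest its 25/50/75% positions. Where the field's convention says
only "three points each", fixing the sample positions makes the measurement
deterministic and resolution-stable. The subject's mJSW is the smaller of
the two leg averages, or the single available leg.

### Quality control and standardization

Scans are zero-padded to a standard 800 x 1000 frame with content centered
(ties toward the top-left); anything larger is a *resolution outlier* and
is rejected, not resized. Rasters come in three pixel spacings
(0.20 / 0.25 / 0.30 mm/px — `knee_resolutions()`), and raw pixel
measurements are not comparable across them. Normalization regresses raw
pixel mJSW on subject height within each resolution group: a physical slope
of s mm/cm appears as s / spacing in pixel units, so the ratio
`slope_reference / slope_group` maps each group onto the reference group's
pixel scale, and multiplying by the reference spacing yields mm. The
reference group is configuration; factors from non-positive slopes are
flagged invalid. This slope-ratio construction is the package's explicit
choice for turning height-regression estimates into scaling factors.

Two error scales matter and are reported separately by `run_experiment()`:
the *raw* error (measurement at the group's true spacing; bounded by pixel
rounding, about half a spacing) and the *normalized* error, which adds the
sampling noise of the estimated slopes. The latter shrinks only with the
number of imaged subjects; with height explaining a minority of mJSW
variance, slope ratios are noisy below a few hundred subjects per group,
which is why the geometry test suite ties gaps exactly to height (isolating
the measurement machinery) while the end-to-end experiment reports both
numbers honestly.

## Synthetic cohort, genotypes and traits

`generate_cohort()` draws sex (P(male) = 0.502) and sex-stratified age,
height and BMI with the motivating study's table moments (male age
64.6 (7.6) y, height 176.2 (6.6) cm; female 63.0 (7.3), 162.8 (6.2));
the implied overall age mean is 63.8, which that table prints rounded as
64. Body-fat percentage has no published moment there; we use
DXA-realistic sex-specific values (25 (6) / 36 (7) %), chosen once.
Steroid-use and knee-trauma flags use the table rates (424 and 351 of
29,257).

`simulate_genotypes()` produces hard-call dosages {0,1,2} by thresholding a
block-exchangeable Gaussian copula at each SNP's Hardy–Weinberg genotype
probabilities. Blocks are contiguous runs of (default) 10 SNPs spaced
10 kb apart; each block's latent correlation is drawn from a range
(default 0–0.9) so LD — and therefore LD scores — varies across the genome,
which is what makes the LD-score regression slope identifiable. Between
blocks, dosages are independent. The dosage-scale r² implied by a latent
correlation is attenuated by discretization; the test suite pins it against
a Monte-Carlo oracle of the same copula law.

`simulate_traits()` builds the quantitative trait as a standardized genetic
value (sample variance exactly h², from `m_causal` random SNPs with
Gaussian effects) plus standardized environmental noise (variance 1 − h²).
The trait is its own disease liability with *low* values diseased: a
subject is a true case when the trait falls in the lower-K tail
(threshold `qnorm(1 − K)` on the negated trait). Defaults follow the
motivating counts: K = 3016/29257 ≈ 0.103, EHR sensitivity
1085/3016 ≈ 0.36, EHR specificity 1.0 (the record documents
under-diagnosis; a false-positive rate is not documented, so 1.0 is the
default and exposed as configuration). Pain items are conditionally
independent given case status with the published case/control rates
(past-month 0.494/0.272; 3-month 0.804/0.706; 0–10 rating means
3.33/2.58, sd 2.2 before rounding and truncation); fracture is drawn from
a logistic model in mJSW (−0.5 per mm by default), height, sex, age and
body fat, with the intercept anchored to a 6% marginal rate.

## Association, clumping, LDSC and PRS

Per-SNP linear association is OLS of the trait on dosage plus covariates,
computed for all SNPs at once by Frisch–Waugh residualization; logistic
association is a per-SNP IRLS warm-started from the covariate-only fit.
Both are Wald-tested (the simplest consistent choice) and floored at the
smallest positive double rather than reporting p = 0. Monomorphic,
non-converged or separated SNPs are excluded with reasons. Genomic
inflation is `median(chi2) / qchisq(0.5, 1)`.

Greedy clumping follows the standard tool behavior: index SNPs in
ascending p (ties broken by position then id) among SNPs with p ≤ 5e-8;
each index absorbs unassigned SNPs with p ≤ 1e-4 within 250 kb and dosage
r² ≥ 0.1, with r² computed in the analysis sample. A deliberately plain
`reference_clump()` transcription exists solely to validate the production
path; the acceptance suite requires exact agreement on 100 random
instances. Note that the locus count *rises* with the r² threshold (a
stricter threshold absorbs fewer SNPs) and with p1.

LD scores sum r² over a physical window (kb stands in for cM — the
simulation has no genetic map; the default window comfortably covers the
simulated blocks). Heritability is the unweighted OLS slope of per-SNP chi²
on LD scores, scaled by M/N, with a free intercept and a
leave-one-block-out jackknife SE; genetic correlation is the analogous
slope of the z-score product, normalized by the two heritabilities. Two
numerical choices matter at desk scale and are used by the recovery
studies: LD scores come from an *independent reference sample* (in-sample
LD scores share sampling noise with the chi² statistics and inflate the
slope noticeably at M of a few thousand), and the replicate design fixes
one genome (variant map and reference LD) while redrawing cohorts.
Genetic correlation is estimated by cross-trait LD score regression
rather than a variance-component (GREML) fit: it keeps the module
self-contained, needs no individual-level cross-trait model, and is
validated by parameter recovery.

PRS uses clumping and thresholding: one clump at the loosest threshold,
then nested selections of index SNPs at the seven standard p-value
thresholds (1 down to 1e-6), weighted by GWAS betas. Scores are z-scored
in the hold-out sample and evaluated by covariate-adjusted logistic
regression against the hold-out EHR diagnosis, Bonferroni-corrected at
0.05/21 (3 phenotypes x 7 thresholds).

## Study conditions and problem sizes

The simulation studies are single-CPU sized; their conditions are:

* **Geometry**: 200 noiseless two-leg phantom subjects across the three
  resolutions, gaps tied exactly linearly to height; every normalized
  value must sit within 2 pixel spacings of the generator truth.
* **Calibration**: h² = 0, N = 2000, M = 5000 independent SNPs; genomic
  inflation in [0.95, 1.05] and nominal type-I error.
* **h² recovery**: N = 5000, M = 5000, 1500 causal SNPs, h² = 0.24,
  50 replicates, reference sample 2000.
* **rg recovery**: N = 5000, M = 2000, 500 shared causal SNPs with effect
  correlation −0.9, h² = 0.5 each, 25 replicates.
* **Power ordering**: N = 4000, M = 2000, 20 causal SNPs, h² = 0.25,
  K = 0.10, EHR sensitivity 0.36, hold-out 2000, 25 replicates.

The default end-to-end experiment (`run_experiment()`) uses n = 1500
subjects, 1000 SNPs and a 300-subject imaging stage.

## What the generator does and does not emulate

The phantoms reproduce the *geometry* that the measurement consumes —
labelled bones, per-column gaps, resolution heterogeneity, padding — not
DXA physics: no beam hardening, scanner artifacts, weight-bearing
positioning or osteophytes. The genotypes have analyzable block LD, not
real human LD; MAFs are uniform on [0.05, 0.5]; there is no population
structure, so GWAS covariates adjust phenotype composition only, not
confounding. Passing tests therefore demonstrate that the *pipeline* is
correct and that the power ordering holds under a liability-threshold
world; they do not certify segmentation quality or LD handling on real
images or genomes. With dense causal signal and small M, genome-wide
lambda legitimately exceeds 1 for the heritable trait (polygenicity, not
bias); the null calibration study is the bias check.

## Degenerate inputs and tie-breaks

Quantile dichotomization includes all values tied with the cutoff and
reports the realized fraction (an all-equal input becomes all cases).
Clumping ties on p break by position then id, making outputs
deterministic. Bones touching in a column measure gap 0; inverted labels
floor at 0 rather than going negative. A single resolution group
normalizes with factor 1. Zero-variance PRS scores (e.g. an empty
selection) are flagged and skipped, never entered into a regression.
Every generator is a pure function of (configuration, seed); one master
seed expands to per-stage seeds by a fixed affine map modulo 2^31 − 1.

## Known limitations

* Observed-scale heritability only; no liability-scale transformation for
  the binary traits.
* The EHR false-positive rate is assumed zero by default.
* The imaging stage validates measurement on a subset; the GWAS consumes
  the generator's per-subject mJSW (which the measurement recovers within
  2 pixel spacings) rather than re-measuring every subject's phantom,
  since rendering adds no statistical information at equal ground truth.
* Slope-ratio normalization degrades gracefully but noisily below a few
  hundred imaged subjects per resolution group; the reported normalized
  RMSE makes this visible.
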