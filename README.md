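# oapower

Knee osteoarthritis (OA) is diagnosed from radiographs, but biobank genetic
studies usually ascertain cases from billing codes — which under-report the
disease and throw away severity. `oapower` is a desk-scale, fully synthetic
study of what that costs. It implements, with known ground truth at every
stage:

* a **knee phantom generator**: AP-view rasters with femur/tibia/fibula
  label masks, known per-column joint gaps, several pixel spacings, plus a
  covariate cohort, LD-blocked genotypes, and a heritable quantitative
  trait with liability-threshold disease status and an under-reporting
  EHR record;
* the **minimum joint space width (mJSW)** measurement from segmentation
  masks: per-column femur–tibia gaps, nine-point per-leg averages, the
  two-leg minimum, and height-regression normalization across image
  resolutions;
* **case ascertainment analytics**: quantile dichotomization (the stand-in
  for an image-based classifier), inter-rater confusion tables,
  EHR-vs-model case comparison, pain and fracture associations;
* **association genetics**: covariate-adjusted per-SNP linear and logistic
  GWAS, genomic inflation λ = median(χ²)/qchisq(0.5, 1), greedy LD
  clumping (p1 = 5×10⁻⁸, p2 = 1×10⁻⁴, r² ≥ 0.1, 250 kb), LD-score-regression
  heritability (slope of χ² on LD scores × M/N) and cross-trait genetic
  correlation, and clumping-and-thresholding polygenic scores evaluated by
  Bonferroni-corrected logistic regression on a hold-out sample.

The headline comparison: at equal N, a quantitative endophenotype GWAS
finds more independent loci and predicts better than a case–control GWAS
of its own dichotomization, which in turn beats the EHR-thinned record.

## Worked example

```r
library(oapower)

cfg <- experiment_config(n = 400, n_image = 36, n_snps = 300,
                         n_holdout = 300, seed = 5)
report <- run_experiment(cfg)
print(report)
```

Output from this exact call:

```
== Synthetic knee-OA phenotyping experiment ==
cohort n = 400 (seed 5)
measurement on imaged subset (n = 36): raw RMSE 0.022 mm, normalized RMSE 2.608 mm
cases: EHR 14, model 42 (overlap 14); 28 new cases (200% increase) of 400 subjects

GWAS:
    phenotype n_cases   lambda loci
         mjsw      NA 1.968293    1
 model_binary      42 1.546266    0
   ehr_binary      14 1.448917    0

LDSC h2 = 0.548 (SE 0.516), intercept 0.566
LDSC rg = -0.975 (SE 0.965)

PRS Bonferroni-significant thresholds (of 7 ):
    phenotype significant
   ehr_binary           1
         mjsw           5
 model_binary           2

fracture ~ mJSW: estimate -0.574 (SE 0.455), p = 0.207
```

Reading it: the mask-based measurement recovers the generator's joint gaps
to 0.02 mm at the true pixel spacing; the *normalized* RMSE is large here
because 12 subjects per resolution group cannot estimate the
height-regression scaling factors (it falls with `n_image`; the
measurement itself is exact). The model ascertains 42 cases where the
thinned EHR holds 14 — the same kind of case-count gap the dichotomizer is
built to expose. Even at n = 400, the quantitative trait yields the only
genome-wide locus and 5 of 7 significant PRS thresholds against 1–2 for
the binary phenotypes; λ > 1 for the heritable trait reflects dense
polygenic signal at M = 300, not bias (the null-calibration study pins
λ at 1). The h²/rg estimates carry desk-scale jackknife SEs — the
50-replicate recovery studies (below) are the precision version.

The numbered drivers under `analysis/` run the same stages as a workflow
(`01_simulate.R` … `06_power_study.R`), writing tables under `results/`.

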