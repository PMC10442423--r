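#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs: a covariate cohort, an LD-blocked
# genotype panel, and the heritable mJSW trait with liability-threshold
# case status and an under-reporting EHR. Everything downstream (scripts
# 02-06) re-derives these deterministically from the same master seed, so
# the scripts can be run independently.

suppressPackageStartupMessages(library(oapower))

SEED <- 1
N <- 1500
M <- 1000
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(N, seed = 1)
panel <- simulate_genotypes(panel_config(N, M, block_size = 10, rho = c(0, 0.9)),
                            seed = 2)
arch <- trait_architecture() # h2 0.25, K = 3016/29257, EHR sens 1085/3016
traits <- simulate_traits(panel, arch, covariates = cohort, seed = 3)
cohort$true_mjsw <- traits$mjsw_mm

write_cohort_tsv(cohort, "results/cohort.tsv")
write_panel_tsv(panel, "results/genotype_dosages.tsv", "results/variant_map.tsv")
write_cohort_tsv(cbind(subject_id = cohort$subject_id, traits),
                 "results/traits.tsv")

# a few example phantoms across the resolution set, as PNG image + mask
res <- knee_resolutions()
dir.create("results/phantoms", showWarnings = FALSE)
for (k in seq_len(nrow(res))) {
  g <- cohort$true_mjsw[k]
  spec <- phantom_spec(
    image_width = res$width[k], image_height = res$height[k],
    pixel_spacing = res$pixel_spacing[k],
    gap_mm = c(lateral = g + 0.2, center = g, medial = max(g - 0.2, 0.5)),
    noise_sd = 6, seed = 100 + k, subject_id = cohort$subject_id[k]
  )
  scan <- validate_and_pad(generate_knee_phantom(spec))
  write_scan_png(scan,
                 sprintf("results/phantoms/%s_%s_image.png",
                         scan$subject_id, res$group[k]),
                 sprintf("results/phantoms/%s_%s_mask.png",
                         scan$subject_id, res$group[k]))
}

cat(sprintf("cohort: n = %d, male fraction %.3f, mean age %.1f\n",
            N, mean(cohort$sex == "M"), mean(cohort$age)))
cat(sprintf("panel: %d SNPs in %d blocks\n", M, max(panel$map$block)))
cat(sprintf("trait: prevalence %.3f (target %.3f), EHR case rate %.3f\n",
            mean(traits$true_case), arch$prevalence, mean(traits$ehr_case)))
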