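#!/usr/bin/env Rscript
# Stage 5 — genetic architecture: LD-score-regression heritability of the
# quantitative trait, its genetic correlation with the dichotomized
# phenotype, and clumping-and-thresholding polygenic scores from each scan
# evaluated against EHR diagnosis in an independent hold-out sample.

suppressPackageStartupMessages(library(oapower))

N <- 1500
N_HOLD <- 1000
dir.create("results/genarch", recursive = TRUE, showWarnings = FALSE)

cohort <- generate_cohort(N, seed = 1)
cfg <- panel_config(N, 1000, block_size = 10, rho = c(0, 0.9))
panel <- simulate_genotypes(cfg, seed = 2)
traits <- simulate_traits(panel, trait_architecture(), covariates = cohort,
                          seed = 3)
covars <- data.frame(sex = as.numeric(cohort$sex == "M"), age = cohort$age,
                     bmi = cohort$bmi, height = cohort$height)
model_case <- dichotomize(traits$y_quant, 3016 / 29257)$case

ss_q <- linear_assoc(panel, traits$y_quant, covars, phenotype = "mjsw")
ss_b <- logistic_assoc(panel, model_case, covars, phenotype = "model_binary")
ss_e <- logistic_assoc(panel, traits$ehr_case, covars, phenotype = "ehr_binary")

# hold-out sample doubles as LD reference panel
hold_panel <- simulate_genotypes(panel_config(N_HOLD, 1000, block_size = 10,
                                              rho = c(0, 0.9)),
                                 seed = 8, variant_map = panel$map)
l <- ld_scores(hold_panel, window_kb = 150)

lq <- l[match(ss_q$snp, panel$map$snp)]
h2_q <- ldsc_h2(ss_q$chi2, lq, N = N, M = nrow(ss_q))
print(h2_q)

common <- intersect(ss_q$snp, ss_b$snp)
iq <- match(common, ss_q$snp); ib <- match(common, ss_b$snp)
lc <- l[match(common, panel$map$snp)]
h2_b <- ldsc_h2(ss_b$chi2[ib], lc, N = N, M = length(common))
rg <- ldsc_rg(ss_q$beta[iq] / ss_q$se[iq], ss_b$beta[ib] / ss_b$se[ib], lc,
              N1 = N, N2 = N, h2_1 = max(h2_q$h2_hat, 1e-3),
              h2_2 = max(h2_b$h2_hat, 1e-3), M = length(common))
print(rg)

hold_cohort <- generate_cohort(N_HOLD, seed = 9)
hold_traits <- simulate_traits(hold_panel, trait_architecture(),
                               covariates = hold_cohort, seed = 10,
                               effects = attr(traits, "effects"))
hold_cov <- data.frame(sex = as.numeric(hold_cohort$sex == "M"),
                       age = hold_cohort$age, bmi = hold_cohort$bmi,
                       height = hold_cohort$height)
prs_tab <- do.call(rbind, lapply(
  list(mjsw = ss_q, model_binary = ss_b, ehr_binary = ss_e),
  function(ss) {
    prs <- build_prs(ss, panel)
    ev <- score_and_evaluate(prs, hold_panel, hold_traits$ehr_case,
                             covariates = hold_cov, n_tests = 21)
    cbind(phenotype = attr(ss, "phenotype"), ev)
  }
))
write_cohort_tsv(prs_tab, "results/genarch/prs_evaluation.tsv")
write_cohort_tsv(data.frame(trait = c("mjsw", "model_binary"),
                            h2_hat = c(h2_q$h2_hat, h2_b$h2_hat),
                            se = c(h2_q$se, h2_b$se)),
                 "results/genarch/h2.tsv")
write_cohort_tsv(data.frame(rg_hat = rg$rg_hat, se = rg$se),
                 "results/genarch/rg.tsv")
cat("\nBonferroni-significant PRS thresholds (of 7) per phenotype:\n")
print(aggregate(significant ~ phenotype, prs_tab, sum), row.names = FALSE)
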