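# Simulation studies: the package's experiments, each callable as one
# function so the analysis scripts, the test suite and the acceptance
# script all run the identical computation.

#' Geometry round-trip study
#'
#' Renders noiseless knee phantoms across the three resolution groups with
#' joint gaps tied exactly linearly to subject height, runs the full
#' measurement pipeline (gap profile, nine-point leg averages, per-subject
#' minimum, height-regression normalization), and compares the normalized
#' mJSW with the generator's ground truth (the same nine-point summary of
#' the true rendered gap profile).
#'
#' @param n_subjects Number of subjects (two legs each).
#' @param seed RNG seed.
#' @param reference_group Resolution group defining the output scale.
#' @return A data.frame with per-subject `truth_mm`, `mjsw_norm`, `err_mm`,
#'   and `tol_mm` (2 pixel spacings of the subject's group).
#' @export
geometry_suite <- function(n_subjects = 200, seed = 1L,
                           reference_group = "res025") {
  res <- knee_resolutions()
  with_seed(seed, {
    heights <- runif(n_subjects, 150, 192)
    grp <- rep_len(seq_len(nrow(res)), n_subjects)
    leg_seeds <- matrix(sample.int(1e6, 2 * n_subjects), ncol = 2)
    rows <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      r <- res[grp[i], ]
      base <- 2.0 + 0.012 * heights[i] # exact mm-per-cm relation
      truth_legs <- numeric(2)
      raw_legs <- numeric(2)
      for (leg in 1:2) {
        side <- c("left", "right")[leg]
        g <- base + c(-0.1, 0.1)[leg]
        spec <- phantom_spec(
          image_width = r$width, image_height = r$height,
          pixel_spacing = r$pixel_spacing, side = side,
          gap_mm = c(lateral = g + 0.2, center = g, medial = g - 0.2),
          noise_sd = 0, seed = leg_seeds[i, leg],
          subject_id = sprintf("G%04d", i)
        )
        scan <- generate_knee_phantom(spec)
        scan <- validate_and_pad(scan)
        raw_legs[leg] <- measure_leg(scan)
        ix <- nine_point_indices(nrow(scan$true_gap_profile))
        truth_legs[leg] <- mean(scan$true_gap_profile$gap_mm[ix])
      }
      rows[[i]] <- data.frame(
        subject_id = sprintf("G%04d", i), group = r$group,
        pixel_spacing = r$pixel_spacing, height = heights[i],
        raw_px = subject_mjsw(raw_legs[1], raw_legs[2]),
        truth_mm = min(truth_legs)
      )
    }
    d <- do.call(rbind, rows)
    model <- fit_normalization(
      data.frame(raw_px = d$raw_px, height = d$height, group = d$group,
                 pixel_spacing = d$pixel_spacing),
      reference_group = reference_group
    )
    d$mjsw_norm <- apply_normalization(model, d$raw_px, d$group)
    d$err_mm <- abs(d$mjsw_norm - d$truth_mm)
    d$tol_mm <- 2 * d$pixel_spacing
    attr(d, "model") <- model
    d
  })
}

#' Null calibration study
#'
#' Runs a quantitative GWAS of a zero-heritability trait on an independent
#' SNP panel and reports genomic inflation and per-SNP type-I error at 0.05.
#'
#' @param n_subjects,n_snps Panel size (defaults N = 2000, M = 5000).
#' @param seed RNG seed.
#' @return A list: `lambda`, `type1_rate`, `m`, `binomial_se`.
#' @export
calibration_suite <- function(n_subjects = 2000, n_snps = 5000, seed = 1L) {
  cfg <- panel_config(n_subjects, n_snps, block_size = 1, rho = 0)
  panel <- simulate_genotypes(cfg, seed = stage_seed(seed, 1))
  arch <- trait_architecture(m_causal = 1, h2 = 0)
  tr <- simulate_traits(panel, arch, seed = stage_seed(seed, 2))
  res <- linear_assoc(panel, tr$y_quant)
  list(
    lambda = lambda_gc(res),
    type1_rate = mean(res$p < 0.05),
    m = nrow(res),
    binomial_se = sqrt(0.05 * 0.95 / nrow(res))
  )
}

#' Heritability recovery study
#'
#' For each seed: simulate an LD-blocked panel and a quantitative trait of
#' known SNP heritability, run the GWAS, compute LD scores with a window
#' covering the LD blocks, and estimate h2 by LD score regression.
#'
#' @param n_seeds Number of replicates (default 50).
#' @param n_subjects,n_snps Panel size per replicate.
#' @param h2 Simulated SNP heritability (default 0.24).
#' @param m_causal Causal SNPs per replicate.
#' @param block_size,rho LD block structure; `rho` defaults to a range so
#'   that LD (and hence LD scores) vary across blocks, which is what makes
#'   the LD-score slope identifiable.
#' @param window_kb LD-score window (chosen to cover the simulated blocks).
#' @param n_reference Size of the independent reference sample the LD
#'   scores are computed on (in-sample LD scores share sampling noise with
#'   the test statistics and bias the slope upward at these panel sizes).
#' @param seed Master seed.
#' @return data.frame with one row per seed (`h2_hat`, `se`, `intercept`);
#'   summary attributes `mean_h2`, `mc_se`.
#' @export
h2_recovery_sim <- function(n_seeds = 50, n_subjects = 5000, n_snps = 5000,
                            h2 = 0.24, m_causal = 1500, block_size = 10,
                            rho = c(0, 0.9), window_kb = 150,
                            n_reference = 2000, seed = 1L) {
  cfg <- panel_config(n_subjects, n_snps, block_size = block_size, rho = rho)
  ref_cfg <- panel_config(n_reference, n_snps, block_size = block_size,
                          rho = rho)
  arch <- trait_architecture(m_causal = m_causal, h2 = h2)
  # One fixed genome (variant map and reference LD) across replicates;
  # each replicate draws a fresh cohort and trait from it.
  ref <- simulate_genotypes(ref_cfg, seed = stage_seed(seed, 0))
  l_ref <- ld_scores(ref, window_kb = window_kb)
  rows <- lapply(seq_len(n_seeds), function(s) {
    sd_i <- stage_seed(seed, s)
    panel <- simulate_genotypes(cfg, seed = sd_i, variant_map = ref$map)
    tr <- simulate_traits(panel, arch, seed = stage_seed(sd_i, 1))
    res <- linear_assoc(panel, tr$y_quant)
    l <- l_ref[match(res$snp, panel$map$snp)]
    est <- ldsc_h2(res$chi2, l, N = n_subjects, M = nrow(res))
    data.frame(seed = s, h2_hat = est$h2_hat, se = est$se,
               intercept = est$intercept)
  })
  d <- do.call(rbind, rows)
  attr(d, "mean_h2") <- mean(d$h2_hat)
  attr(d, "mc_se") <- stats::sd(d$h2_hat) / sqrt(n_seeds)
  attr(d, "h2_true") <- h2
  d
}

#' Genetic-correlation recovery study
#'
#' Simulates pairs of traits with causal effects correlated at `rg_true` on
#' a shared panel, estimates each trait's h2 and the cross-trait genetic
#' covariance by LD score regression, and reports the recovered rg per seed.
#'
#' @param n_seeds Replicates (default 25).
#' @param n_subjects,n_snps Panel size.
#' @param rg_true Simulated effect correlation (default -0.9).
#' @param h2 Heritability of both traits.
#' @param m_causal Causal SNPs.
#' @param block_size,rho LD block structure (per-block rho range).
#' @param window_kb LD-score window.
#' @param n_reference Independent reference-sample size for LD scores.
#' @param seed Master seed.
#' @return data.frame per seed (`rg_hat`, `se`); attributes `mean_rg`,
#'   `mc_se`, `mean_jk_se`.
#' @export
rg_recovery_sim <- function(n_seeds = 25, n_subjects = 5000, n_snps = 2000,
                            rg_true = -0.9, h2 = 0.5, m_causal = 500,
                            block_size = 10, rho = c(0, 0.9), window_kb = 150,
                            n_reference = 2000, seed = 1L) {
  cfg <- panel_config(n_subjects, n_snps, block_size = block_size, rho = rho)
  ref_cfg <- panel_config(n_reference, n_snps, block_size = block_size,
                          rho = rho)
  arch <- trait_architecture(m_causal = m_causal, h2 = h2, rg_shared = rg_true)
  ref <- simulate_genotypes(ref_cfg, seed = stage_seed(seed, 0))
  l_ref <- ld_scores(ref, window_kb = window_kb)
  rows <- lapply(seq_len(n_seeds), function(s) {
    sd_i <- stage_seed(seed, 1000 + s)
    panel <- simulate_genotypes(cfg, seed = sd_i, variant_map = ref$map)
    pair <- simulate_trait_pair(panel, arch, seed = sd_i)
    r1 <- linear_assoc(panel, pair$t1$y_quant)
    r2 <- linear_assoc(panel, pair$t2$y_quant)
    l <- l_ref[match(r1$snp, panel$map$snp)]
    M <- nrow(r1)
    h1 <- ldsc_h2(r1$chi2, l, N = n_subjects, M = M)
    h2e <- ldsc_h2(r2$chi2, l, N = n_subjects, M = M)
    z1 <- r1$beta / r1$se
    z2 <- r2$beta / r2$se
    est <- ldsc_rg(z1, z2, l, N1 = n_subjects, N2 = n_subjects,
                   h2_1 = max(h1$h2_hat, 1e-3), h2_2 = max(h2e$h2_hat, 1e-3),
                   M = M)
    data.frame(seed = s, rg_hat = est$rg_hat, se = est$se)
  })
  d <- do.call(rbind, rows)
  attr(d, "mean_rg") <- mean(d$rg_hat)
  attr(d, "mc_se") <- stats::sd(d$rg_hat) / sqrt(n_seeds)
  attr(d, "mean_jk_se") <- mean(d$se)
  attr(d, "rg_true") <- rg_true
  d
}

#' Clumping agreement study
#'
#' Generates random association instances (LD-blocked panels with p-values
#' spanning well past genome-wide significance) and checks that
#' [greedy_clump()] returns exactly the same indices and member assignments
#' as the plain [reference_clump()] transcription.
#'
#' @param n_instances Number of random instances (default 100).
#' @param n_snps SNPs per instance (default 200).
#' @param n_subjects Subjects per instance.
#' @param seed Master seed.
#' @return data.frame with per-instance locus counts and an `agree` flag.
#' @export
clump_agreement_sim <- function(n_instances = 100, n_snps = 200,
                                n_subjects = 400, seed = 1L) {
  rows <- lapply(seq_len(n_instances), function(i) {
    sd_i <- stage_seed(seed, 3000 + i)
    cfg <- panel_config(n_subjects, n_snps, block_size = 5, rho = 0.7)
    panel <- simulate_genotypes(cfg, seed = sd_i)
    res <- with_seed(stage_seed(sd_i, 1), {
      p <- 10^(-runif(n_snps, 0, 12))
      z <- qnorm(p / 2) # arbitrary consistent betas
      new_assoc_result(panel$map, beta = -z, se = rep(1, n_snps), p = p,
                       n_used = n_subjects, phenotype = "random",
                       excluded = character(0))
    })
    g <- greedy_clump(res, panel)
    r <- reference_clump(res, panel)
    agree <- identical(g$indices$snp, r$indices) &&
      length(g$members) == length(r$members) &&
      all(vapply(names(g$members), function(s) {
        setequal(g$members[[s]], r$members[[s]])
      }, logical(1)))
    data.frame(instance = i, count_greedy = g$count, count_reference = r$count,
               agree = agree)
  })
  do.call(rbind, rows)
}

#' Power-ordering study: quantitative vs dichotomized vs EHR-thinned GWAS
#'
#' The central power comparison in miniature. Per seed: one LD-blocked panel
#' and one heritable quantitative trait; three association scans of the same
#' data — the quantitative trait, its liability-threshold dichotomization at
#' prevalence K, and the dichotomization thinned by EHR sensitivity — each
#' followed by greedy clumping at genome-wide significance. A hold-out
#' sample from the same population is scored with clumping-and-thresholding
#' PRSs from each scan and evaluated against the hold-out EHR diagnosis by
#' Bonferroni-corrected logistic regression.
#'
#' @param n_seeds Replicates (default 25).
#' @param n_subjects GWAS sample size (default 4000).
#' @param n_snps SNPs (default 2000).
#' @param m_causal Causal SNPs (default 20).
#' @param h2 SNP heritability (default 0.25).
#' @param prevalence Disease prevalence K (default 0.10).
#' @param ehr_sensitivity EHR case sensitivity (default 0.36).
#' @param n_holdout Hold-out sample size for PRS evaluation (default 2000).
#' @param seed Master seed.
#' @return data.frame with one row per seed: loci counts and significant
#'   PRS threshold counts for the three phenotypes; column means as
#'   attribute `"summary"`.
#' @export
power_ordering_sim <- function(n_seeds = 25, n_subjects = 4000, n_snps = 2000,
                               m_causal = 20, h2 = 0.25, prevalence = 0.10,
                               ehr_sensitivity = 0.36, n_holdout = 2000,
                               seed = 1L) {
  cfg <- panel_config(n_subjects, n_snps, block_size = 10, rho = 0.8)
  arch <- trait_architecture(m_causal = m_causal, h2 = h2,
                             prevalence = prevalence,
                             ehr_sensitivity = ehr_sensitivity)
  cp <- clump_params()
  rows <- lapply(seq_len(n_seeds), function(s) {
    sd_i <- stage_seed(seed, 2000 + s)
    panel <- simulate_genotypes(cfg, seed = sd_i)
    tr <- simulate_traits(panel, arch, seed = stage_seed(sd_i, 1))
    y <- tr$y_quant
    model_case <- dichotomize(y, prevalence)$case
    ehr_case <- tr$ehr_case

    ss_q <- linear_assoc(panel, y, phenotype = "mjsw")
    ss_b <- logistic_assoc(panel, model_case, phenotype = "model_binary")
    ss_e <- logistic_assoc(panel, ehr_case, phenotype = "ehr_binary")

    loci <- vapply(list(ss_q, ss_b, ss_e), function(ss) {
      greedy_clump(ss, panel, cp)$count
    }, numeric(1))

    hold_cfg <- panel_config(n_holdout, n_snps, block_size = 10, rho = 0.8)
    hold_panel <- simulate_genotypes(hold_cfg, seed = stage_seed(sd_i, 2),
                                     variant_map = panel$map)
    hold_tr <- simulate_traits(hold_panel, arch,
                               seed = stage_seed(sd_i, 3),
                               effects = attr(tr, "effects"))
    nsig <- vapply(list(ss_q, ss_b, ss_e), function(ss) {
      prs <- build_prs(ss, panel, clump = cp)
      ev <- score_and_evaluate(prs, hold_panel, hold_tr$ehr_case, n_tests = 21)
      sum(ev$significant)
    }, numeric(1))

    data.frame(
      seed = s,
      loci_quant = loci[1], loci_binary = loci[2], loci_ehr = loci[3],
      prs_sig_quant = nsig[1], prs_sig_binary = nsig[2], prs_sig_ehr = nsig[3]
    )
  })
  d <- do.call(rbind, rows)
  attr(d, "summary") <- colMeans(d[, -1])
  d
}
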