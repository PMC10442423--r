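test_that("liability threshold is the upper-K normal quantile", {
  expect_identical(liability_threshold(0.5), 0)
  # numeric inverse-CDF oracle for K = 0.103
  oracle <- uniroot(function(x) pnorm(x) - (1 - 0.103), c(0, 5),
                    tol = 1e-10)$root
  expect_lt(abs(liability_threshold(0.103) - oracle), 1e-8)
  expect_lt(abs(oracle - 1.264), 1e-3)
})

test_that("trait variance decomposes into h2 and 1 - h2 across seeds", {
  cfg <- panel_config(5000, 400, block_size = 10, rho = 0.6)
  arch <- trait_architecture(m_causal = 50, h2 = 0.25)
  ratios <- vapply(1:50, function(s) {
    panel <- simulate_genotypes(cfg, seed = s)
    tr <- simulate_traits(panel, arch, seed = s + 1000)
    var(tr$genetic_value) / var(tr$y_quant)
  }, numeric(1))
  mc_se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.25), 2 * mc_se + 1e-3)
  expect_lt(abs(mean(ratios) - 0.25), 0.02)
})

test_that("case prevalence and EHR thinning converge to their targets", {
  cfg <- panel_config(20000, 200, block_size = 10, rho = 0.5)
  panel <- simulate_genotypes(cfg, seed = 3)
  K <- 3016 / 29257
  arch <- trait_architecture(m_causal = 20, h2 = 0.25)
  tr <- simulate_traits(panel, arch, seed = 4)
  N <- 20000
  expect_lt(abs(mean(tr$true_case) - K), 3 * sqrt(K * (1 - K) / N))
  sens <- 1085 / 3016
  pe <- K * sens
  expect_lt(abs(mean(tr$ehr_case) - pe), 4 * sqrt(pe * (1 - pe) / N))
  # EHR cases are a subset of true cases at specificity 1
  expect_true(all(tr$true_case[tr$ehr_case]))
  # y regressed on the genetic value has slope 1
  slope <- coef(lm(tr$y_quant ~ tr$genetic_value))[2]
  expect_lt(abs(slope - 1), 0.05)
})

test_that("covariate-linked fields and pain/fracture outcomes are generated", {
  cfg <- panel_config(8000, 100, block_size = 5, rho = 0.5)
  panel <- simulate_genotypes(cfg, seed = 5)
  co <- generate_cohort(8000, seed = 6)
  arch <- trait_architecture(m_causal = 10, h2 = 0.3)
  tr <- simulate_traits(panel, arch, covariates = co, seed = 7)
  expect_true(all(tr$pain_rating >= 0 & tr$pain_rating <= 10))
  # configured case/control pain rates
  expect_lt(abs(mean(tr$pain_month_flag[tr$true_case]) - 0.494), 0.04)
  expect_lt(abs(mean(tr$pain_month_flag[!tr$true_case]) - 0.272), 0.02)
  expect_lt(abs(mean(tr$pain_3mo_flag[tr$true_case]) - 0.804), 0.04)
  r_mean_case <- mean(tr$pain_rating[tr$true_case])
  r_mean_ctrl <- mean(tr$pain_rating[!tr$true_case])
  expect_gt(r_mean_case, r_mean_ctrl)
  # mm mJSW composition: cases sit lower
  expect_lt(mean(tr$mjsw_mm[tr$true_case]), mean(tr$mjsw_mm[!tr$true_case]))
  expect_true(mean(tr$fracture_5yr_flag) > 0.01 && mean(tr$fracture_5yr_flag) < 0.2)
})

test_that("trait generation is deterministic and validates its inputs", {
  cfg <- panel_config(200, 50)
  panel <- simulate_genotypes(cfg, seed = 8)
  arch <- trait_architecture(m_causal = 5, h2 = 0.5)
  a <- simulate_traits(panel, arch, seed = 9)
  b <- simulate_traits(panel, arch, seed = 9)
  expect_identical(a, b)
  expect_error(trait_architecture(h2 = 1.2), "h2")
  expect_error(trait_architecture(prevalence = 0), "prevalence")
  expect_error(trait_architecture(ehr_sensitivity = 0), "sensitivity")
  expect_error(simulate_traits(panel, trait_architecture(m_causal = 51), seed = 1),
               "m_causal")
})

test_that("paired traits carry the configured effect correlation", {
  cfg <- panel_config(3000, 500, block_size = 1, rho = 0)
  panel <- simulate_genotypes(cfg, seed = 10)
  arch <- trait_architecture(m_causal = 400, h2 = 0.8, rg_shared = -0.9)
  pair <- simulate_trait_pair(panel, arch, seed = 11)
  g_cor <- cor(pair$t1$genetic_value, pair$t2$genetic_value)
  expect_lt(abs(g_cor - (-0.9)), 0.07)
})
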