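test_that("LD scores equal the exhaustive pairwise oracle", {
  p <- simulate_genotypes(panel_config(600, 200, block_size = 10,
                                       rho = c(0.2, 0.9), n_chrom = 2),
                          seed = 111)
  # all-pairs window: row sums of the full r2 matrix, per chromosome
  l <- ld_scores(p, window_kb = 1e9)
  want <- numeric(200)
  for (ch in unique(p$map$chrom)) {
    ix <- which(p$map$chrom == ch)
    want[ix] <- rowSums(stats::cor(p$dosages[, ix])^2)
  }
  expect_equal(l, want, tolerance = 1e-12)
  # finite window: explicit double loop over in-window pairs
  win <- 35000
  l2 <- ld_scores(p, window_kb = win / 1000)
  want2 <- vapply(seq_len(200), function(j) {
    ix <- which(p$map$chrom == p$map$chrom[j] &
                  abs(p$map$pos - p$map$pos[j]) <= win)
    sum(stats::cor(p$dosages[, j], p$dosages[, ix])^2)
  }, numeric(1))
  expect_equal(l2, want2, tolerance = 1e-12)
  # degenerate window: self term only
  expect_true(all(ld_scores(p, 0) == 1))
  # independent SNPs at large N: scores near 1
  q <- simulate_genotypes(panel_config(4000, 100, block_size = 1, rho = 0),
                          seed = 112)
  expect_lt(max(abs(ld_scores(q, 50) - 1)), 0.05)
})

test_that("LDSC inverts its noiseless forward model exactly", {
  p <- simulate_genotypes(panel_config(500, 300, block_size = 10,
                                       rho = c(0.1, 0.9)), seed = 113)
  l <- ld_scores(p, 150)
  N <- 5000
  M <- 300
  chi2 <- 1 + N * 0.24 * l / M
  est <- ldsc_h2(chi2, l, N, M)
  expect_equal(est$h2_hat, 0.24, tolerance = 1e-10)
  expect_equal(est$intercept, 1, tolerance = 1e-10)
  # flat chi-square: zero heritability, intercept one
  null <- ldsc_h2(rep(1, M), l, N, M)
  expect_equal(null$h2_hat, 0, tolerance = 1e-12)
  expect_equal(null$intercept, 1, tolerance = 1e-12)
  expect_error(ldsc_h2(chi2, rep(2, M), N, M), "constant")
})

test_that("genetic correlation is 1 against itself and symmetric", {
  p <- simulate_genotypes(panel_config(500, 300, block_size = 10,
                                       rho = c(0.1, 0.9)), seed = 114)
  l <- ld_scores(p, 150)
  set.seed(115)
  z <- rnorm(300, sd = sqrt(1 + 3 * l))
  h <- ldsc_h2(z^2, l, N = 2000, M = 300)
  self <- ldsc_rg(z, z, l, 2000, 2000, h$h2_hat, h$h2_hat, M = 300)
  expect_equal(self$rg_hat, 1, tolerance = 1e-10)
  set.seed(116)
  z2 <- rnorm(300, sd = sqrt(1 + 1.5 * l))
  h2e <- ldsc_h2(z2^2, l, N = 2000, M = 300)
  ab <- ldsc_rg(z, z2, l, 2000, 2000, h$h2_hat, h2e$h2_hat, M = 300)
  ba <- ldsc_rg(z2, z, l, 2000, 2000, h2e$h2_hat, h$h2_hat, M = 300)
  expect_equal(ab$rg_hat, ba$rg_hat, tolerance = 1e-12)
  expect_error(ldsc_rg(z, z2, l, 2000, 2000, -0.1, 0.2), "positive")
})

test_that("genetically independent traits show no spurious correlation", {
  d <- rg_recovery_sim(n_seeds = 3, n_subjects = 1500, n_snps = 500,
                       rg_true = 0, h2 = 0.4, m_causal = 100, seed = 117)
  expect_lt(abs(mean(d$rg_hat)), 2 * max(mean(d$se), sd(d$rg_hat)))
})

test_that("PRS threshold selections are nested and degenerate weights flagged", {
  cfg <- panel_config(500, 200, block_size = 5, rho = 0.7)
  panel <- simulate_genotypes(cfg, seed = 118)
  set.seed(119)
  res <- make_assoc(panel, p = 10^(-runif(200, 0, 8)),
                    beta = rnorm(200, sd = 0.1))
  prs <- build_prs(res, panel)
  sets <- lapply(prs$selections, `[[`, "snps")
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
  expect_identical(length(sets[[1]]), nrow(prs$indices))
  # all-zero weights give a zero score, which evaluation flags and skips
  res0 <- make_assoc(panel, p = rep(1e-9, 200), beta = rep(0, 200))
  prs0 <- build_prs(res0, panel)
  ev0 <- score_and_evaluate(prs0, panel, rep(c(TRUE, FALSE), 250))
  expect_true(all(ev0$skipped))
})

test_that("PRS evaluation z-scores the hold-out and applies Bonferroni exactly", {
  cfg <- panel_config(800, 300, block_size = 5, rho = 0.6)
  panel <- simulate_genotypes(cfg, seed = 120)
  arch <- trait_architecture(m_causal = 30, h2 = 0.6, prevalence = 0.2)
  tr <- simulate_traits(panel, arch, seed = 121)
  ss <- linear_assoc(panel, tr$y_quant)
  prs <- build_prs(ss, panel)
  hold <- simulate_genotypes(panel_config(700, 300, block_size = 5, rho = 0.6),
                             seed = 122, variant_map = panel$map)
  htr <- simulate_traits(hold, arch, seed = 123,
                         effects = attr(tr, "effects"))
  ev <- score_and_evaluate(prs, hold, htr$true_case, n_tests = 21)
  sc <- attr(ev, "scores")
  for (z in sc) {
    expect_lt(abs(mean(z)), 1e-10)
    expect_equal(sd(z), 1, tolerance = 1e-10)
  }
  ok <- !ev$skipped
  expect_identical(ev$significant[ok], ev$p[ok] < 0.05 / 21)
})

test_that("a genotype-independent outcome rarely earns a significant PRS", {
  cfg <- panel_config(400, 150, block_size = 5, rho = 0.6)
  panel <- simulate_genotypes(cfg, seed = 124)
  flags <- 0
  tests <- 0
  for (s in 1:20) {
    tr <- simulate_traits(panel, trait_architecture(m_causal = 10, h2 = 0.4),
                          seed = 200 + s)
    ss <- linear_assoc(panel, tr$y_quant)
    prs <- build_prs(ss, panel)
    hold <- simulate_genotypes(cfg, seed = 300 + s, variant_map = panel$map)
    out <- with(list(), {set.seed(400 + s); runif(400) < 0.2})
    ev <- score_and_evaluate(prs, hold, out, n_tests = 21)
    flags <- flags + sum(ev$significant, na.rm = TRUE)
    tests <- tests + sum(!ev$skipped)
  }
  # family-wise alpha 0.05 over 21 tests: expect ~ 0.0024 per test
  expect_lte(flags, max(3, qbinom(0.999, tests, 0.05 / 21) + 1))
})
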