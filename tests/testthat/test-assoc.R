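test_that("linear association equals the normal-equations oracle", {
  p <- simulate_genotypes(panel_config(400, 30), seed = 71)
  set.seed(72)
  y <- rnorm(400)
  cov <- data.frame(a = rnorm(400), b = rnorm(400))
  res <- linear_assoc(p, y, cov)
  for (j in c(3, 17, 30)) {
    X <- cbind(1, p$dosages[, j], cov$a, cov$b)
    bh <- solve(crossprod(X), crossprod(X, y))
    r <- y - X %*% bh
    s2 <- sum(r^2) / (400 - 4)
    se <- sqrt(s2 * solve(crossprod(X))[2, 2])
    i <- match(p$map$snp[j], res$snp)
    expect_lt(abs(res$beta[i] - bh[2]), 1e-8)
    expect_lt(abs(res$se[i] - se), 1e-8)
    expect_lt(abs(res$chi2[i] - (res$beta[i] / res$se[i])^2), 1e-6)
  }
})

test_that("a self-regression gives beta one and a floored p-value", {
  p <- simulate_genotypes(panel_config(300, 10), seed = 73)
  y <- p$dosages[, 4] - mean(p$dosages[, 4])
  res <- linear_assoc(p, y)
  i <- match(p$map$snp[4], res$snp)
  expect_equal(res$beta[i], 1, tolerance = 1e-10)
  expect_identical(res$p[i], .Machine$double.xmin)
  expect_error(linear_assoc(p, y, covariates = data.frame(c1 = rep(1, 300))),
               "rank deficient")
})

test_that("linear type-I error is nominal under the null", {
  p <- simulate_genotypes(panel_config(500, 1000, block_size = 1, rho = 0),
                          seed = 74)
  tr <- simulate_traits(p, trait_architecture(m_causal = 1, h2 = 0), seed = 75)
  res <- linear_assoc(p, tr$y_quant)
  rate <- mean(res$p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(res)))
})

test_that("logistic association matches glm and flags degenerate SNPs", {
  p <- simulate_genotypes(panel_config(600, 20), seed = 76)
  set.seed(77)
  cov <- data.frame(a = rnorm(600))
  case <- runif(600) < plogis(-1 + 0.4 * scale(p$dosages[, 9])[, 1] + 0.3 * cov$a)
  res <- logistic_assoc(p, case, cov)
  for (j in c(2, 9, 20)) {
    fit <- glm(case ~ p$dosages[, j] + cov$a, family = binomial())
    i <- match(p$map$snp[j], res$snp)
    expect_lt(abs(res$beta[i] - coef(fit)[2]), 1e-6)
    expect_lt(abs(res$se[i] - summary(fit)$coefficients[2, 2]), 1e-5)
  }
  # monomorphic SNP is excluded with a reason
  p$dosages[, 5] <- 2
  res2 <- logistic_assoc(p, case)
  expect_false(p$map$snp[5] %in% res2$snp)
  exc <- attr(res2, "excluded")
  expect_identical(exc$reason[exc$snp == p$map$snp[5]], "maf")
  expect_error(logistic_assoc(p, rep(TRUE, 600)), "both classes")
})

test_that("genomic inflation follows its definition and is calibrated", {
  expect_equal(lambda_gc(rep(qchisq(0.5, 1), 10)), 1)
  expect_equal(round(lambda_gc(c(1, 2, 3)), 3),
               round(2 / qchisq(0.5, 1), 3))
  expect_identical(round(lambda_gc(c(1, 2, 3)), 3), 4.396)
  expect_error(lambda_gc(numeric(0)), "no test statistics")
  # balanced null binary GWAS: lambda within 0.05 of 1 at M = 5000
  p <- simulate_genotypes(panel_config(800, 5000, block_size = 1, rho = 0),
                          seed = 78)
  case <- rep(c(TRUE, FALSE), 400)
  res <- logistic_assoc(p, case)
  expect_lt(abs(lambda_gc(res) - 1), 0.05)
})

test_that("greedy clumping reproduces a hand-executed example", {
  set.seed(81)
  n <- 500
  gA <- rbinom(n, 2, 0.3)
  gB <- gA
  swap <- sample(n, n * 0.45)
  gB[swap] <- rbinom(length(swap), 2, 0.3)
  gC <- rbinom(n, 2, 0.3)
  D <- cbind(gA, gB, gC)
  panel <- make_panel(D, pos = c(100000, 200000, 600000))
  stopifnot(cor(gA, gB)^2 > 0.2, cor(gA, gC)^2 < 0.05)
  res <- make_assoc(panel, p = c(1e-10, 1e-9, 4e-8))
  ls <- greedy_clump(res, panel, clump_params())
  expect_identical(ls$count, 2L)
  expect_identical(ls$indices$snp, c("s001", "s003"))
  expect_identical(ls$members[["s001"]], "s002")
  expect_length(ls$members[["s003"]], 0)
  # no SNP past the index threshold: zero loci
  none <- make_assoc(panel, p = rep(1e-4, 3))
  expect_identical(greedy_clump(none, panel)$count, 0L)
  # one significant SNP: one locus
  one <- make_assoc(panel, p = c(1e-10, 0.5, 0.5))
  expect_identical(greedy_clump(one, panel)$count, 1L)
})

test_that("greedy clumping agrees with the literal oracle on random instances", {
  for (i in 1:10) {
    cfg <- panel_config(300, 120, block_size = 6, rho = c(0.2, 0.9))
    panel <- simulate_genotypes(cfg, seed = 90 + i)
    set.seed(190 + i)
    pv <- 10^(-runif(120, 0, 12))
    res <- make_assoc(panel, p = pv)
    got <- greedy_clump(res, panel)
    want <- oracle_clump(as.data.frame(res), panel$dosages, panel$map$snp,
                         p1 = 5e-8, p2 = 1e-4, r2_min = 0.1,
                         window_bp = 250000)
    expect_identical(got$indices$snp, names(want))
    for (s in names(want)) expect_setequal(got$members[[s]], want[[s]])
  }
})

test_that("locus counts move monotonically with the clumping thresholds", {
  cfg <- panel_config(400, 150, block_size = 5, rho = 0.7)
  panel <- simulate_genotypes(cfg, seed = 101)
  set.seed(102)
  res <- make_assoc(panel, p = 10^(-runif(150, 0, 12)))
  count <- function(p1, r2) {
    greedy_clump(res, panel, clump_params(p1 = p1, r2_max = r2))$count
  }
  # non-decreasing in p1
  expect_true(count(1e-10, 0.1) <= count(5e-8, 0.1))
  expect_true(count(5e-8, 0.1) <= count(1e-5, 0.1))
  # non-increasing as r2_max loosens (more absorption with smaller r2_max)
  expect_true(count(5e-8, 0.05) <= count(5e-8, 0.3))
})
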