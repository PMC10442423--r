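test_that("dichotomization takes the lower quantile, reports ties, and is rank-invariant", {
  d <- dichotomize(1:10, 0.2)
  expect_identical(which(d$case), 1:2)
  expect_equal(d$realized_fraction, 0.2)
  # degenerate ties: everyone at the cutoff is included
  tied <- dichotomize(rep(5, 8), 0.2)
  expect_true(all(tied$case))
  expect_equal(tied$realized_fraction, 1)
  # invariance under a strictly monotone transform
  set.seed(31)
  x <- rnorm(500)
  a <- dichotomize(x, 3016 / 29257)
  b <- dichotomize(exp(2 * x) - 5, 3016 / 29257)
  expect_identical(a$case, b$case)
  expect_lt(abs(a$realized_fraction - 3016 / 29257), 1 / 500)
  expect_error(dichotomize(x, 0), "prevalence_target")
})

test_that("pairwise confusion tables are proportions of 100 and average elementwise", {
  perfect <- pairwise_confusion(rep(c(0, 1), c(60, 40)), rep(c(0, 1), c(60, 40)))
  expect_equal(unname(perfect), matrix(c(60, 0, 0, 40), 2, 2))
  mixed <- pairwise_confusion(c(0, 0, 1, 1), c(0, 1, 1, 0))
  expect_equal(unname(mixed), matrix(25, 2, 2))
  expect_equal(sum(mixed), 100)
  avg <- average_confusion(list(mixed, mixed, mixed))
  expect_equal(avg, mixed)
  expect_equal(sum(average_confusion(list(perfect, mixed))), 100,
               tolerance = 1e-9)
  expect_error(pairwise_confusion(c(0, 1), c(0, 1, 1)), "length")
})

test_that("sensitivity and specificity count the confusion cells", {
  tr <- rep(c(TRUE, FALSE), each = 10)
  expect_equal(sens_spec(tr, tr), c(sensitivity = 1, specificity = 1))
  pred <- c(rep(TRUE, 8), rep(FALSE, 2), rep(FALSE, 9), TRUE)
  expect_equal(sens_spec(tr, pred), c(sensitivity = 0.8, specificity = 0.9))
  expect_equal(sens_spec(tr, !tr), c(sensitivity = 0, specificity = 0))
  expect_error(sens_spec(rep(TRUE, 5), rep(TRUE, 5)), "controls")
  expect_error(sens_spec(rep(FALSE, 5), rep(TRUE, 5)), "cases")
})

test_that("case comparison reproduces the published count arithmetic", {
  n <- 29257
  ehr <- rep(c(TRUE, FALSE), c(1085, n - 1085))
  model <- rep(c(TRUE, FALSE), c(3016, n - 3016))
  cmp <- compare_cases(ehr, model)
  expect_identical(cmp$n_new_cases, 1931L)
  expect_identical(cmp$pct_increase, 178)
  expect_identical(cmp$n_ehr_cases + (n - 1085), n)
  # identical ascertainment: nothing new
  same <- compare_cases(model, model)
  expect_identical(same$n_new_cases, 0L)
  expect_identical(same$pct_increase, 0)
  # EHR not nested in model: counts still conserve (set-count oracle)
  set.seed(41)
  e <- runif(1000) < 0.1
  m <- runif(1000) < 0.15
  cmp2 <- compare_cases(e, m)
  expect_identical(cmp2$n_new_cases, sum(m & !e))
  expect_identical(cmp2$overlap, sum(m & e))
  expect_identical(cmp2$n_new_cases + cmp2$overlap, cmp2$n_model_cases)
  expect_true(compare_cases(rep(FALSE, 5), rep(TRUE, 5))$pct_undefined)
})

test_that("pain associations match hand-expanded chi-square and Welch t", {
  # 2x2 table [[10,90],[30,70]]: hand expansion of sum (O-E)^2/E gives 12.5
  case <- rep(c(TRUE, FALSE), each = 100)
  pain <- c(rep(c(TRUE, FALSE), c(10, 90)), rep(c(TRUE, FALSE), c(30, 70)))
  pa <- pain_association(case, pain, pain, c(rep(1:3, length.out = 100),
                                             rep(2:4, length.out = 100)))
  expect_equal(pa$statistic[pa$item == "pain_month"], 12.5, tolerance = 1e-9)
  # identical proportions: statistic 0
  eq <- pain_association(case, rep(c(TRUE, FALSE), 100),
                         rep(c(TRUE, FALSE), 100), rnorm(200))
  expect_equal(eq$statistic[eq$item == "pain_month"], 0, tolerance = 1e-9)
  # Welch t for {1,2,3} vs {2,3,4}
  tt <- pain_association(rep(c(TRUE, FALSE), each = 3), rep(c(TRUE, FALSE), 3),
                         rep(c(TRUE, FALSE), 3), c(1, 2, 3, 2, 3, 4))
  expect_equal(round(tt$statistic[tt$item == "pain_rating"], 4), -1.2247)
  # chi-square equals the textbook oracle on arbitrary 2x2 tables
  set.seed(51)
  for (i in 1:5) {
    cs <- runif(400) < 0.4
    fl <- runif(400) < plogis(-0.5 + cs)
    got <- pain_association(cs, fl, fl, rnorm(400))
    tab <- table(cs, fl)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(got$statistic[got$item == "pain_month"],
                 sum((tab - E)^2 / E), tolerance = 1e-9)
  }
})

test_that("the fracture model recovers a known mJSW log-odds slope", {
  set.seed(61)
  n <- 20000
  co <- generate_cohort(n, seed = 62)
  mjsw <- co$true_mjsw
  lin <- -0.5 * mjsw + 0.01 * co$height - 0.3 * (co$sex == "M") +
    0.04 * co$age + 0.01 * co$body_fat
  b0 <- qlogis(0.06) - mean(lin)
  frac <- runif(n) < plogis(b0 + lin)
  fit <- fracture_model(frac, mjsw, co)
  expect_false(fit$separation)
  expect_lt(abs(fit$estimate - (-0.5)), 2 * fit$se)
})

test_that("the fracture model is calibrated under a null mJSW effect", {
  co <- generate_cohort(1500, seed = 63)
  hits <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    frac <- runif(1500) < 0.08
    fit <- fracture_model(frac, co$true_mjsw, co)
    abs(fit$estimate) < 2 * fit$se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
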