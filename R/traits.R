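# Quantitative trait, liability-threshold disease status and EHR
# misclassification.
#
# The quantitative endophenotype is its own disease liability: a standardized
# genetic value (variance h2) plus standardized environmental noise
# (variance 1 - h2). LOW liability (narrow joint space) is disease, so a
# subject is a true case when -y exceeds the upper-K standard-normal
# quantile, i.e. y falls in the lower-K tail. The health record then records
# a true case with probability `ehr_sensitivity` and a control as a false
# case with probability `1 - ehr_specificity`.

#' Specify a genetic trait architecture
#'
#' @param m_causal Number of causal SNPs.
#' @param h2 SNP heritability of the quantitative trait, in `[0, 1]`.
#' @param prevalence Population prevalence K of the binary disease, in
#'   (0, 1). Default 3016/29257, the image-model case fraction of the
#'   motivating cohort.
#' @param ehr_sensitivity Probability a true case carries the diagnosis code;
#'   default 1085/3016, the ratio of coded to image-ascertained cases.
#' @param ehr_specificity Probability a control is free of the code
#'   (default 1: under-diagnosis only).
#' @param rg_shared Correlation of causal effect sizes for paired traits
#'   (used by [simulate_trait_pair()]).
#' @param pain_month,pain_3mo Named `c(case=, control=)` rates for knee pain
#'   in the past month and pain lasting 3+ months.
#' @param pain_rating_mean Named `c(case=, control=)` means of the 0-10 pain
#'   rating; `pain_rating_sd` its common sd before rounding/truncation.
#' @param fracture_coef Log-odds coefficients of the fracture-generating
#'   model: `mjsw` (per mm), `height` (per cm), `sexM`, `age` (per year),
#'   `body_fat` (per %).
#' @param fracture_rate Marginal 5-year fracture rate used to anchor the
#'   model intercept at the covariate means.
#' @return A list of class `trait_architecture`.
#' @export
trait_architecture <- function(m_causal = 20,
                               h2 = 0.25,
                               prevalence = 3016 / 29257,
                               ehr_sensitivity = 1085 / 3016,
                               ehr_specificity = 1,
                               rg_shared = NULL,
                               pain_month = c(case = 0.494, control = 0.272),
                               pain_3mo = c(case = 0.804, control = 0.706),
                               pain_rating_mean = c(case = 3.33, control = 2.58),
                               pain_rating_sd = 2.2,
                               fracture_coef = c(mjsw = -0.5, height = 0.01,
                                                 sexM = -0.3, age = 0.04,
                                                 body_fat = 0.01),
                               fracture_rate = 0.06) {
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  if (ehr_sensitivity <= 0 || ehr_sensitivity > 1) {
    stop("ehr_sensitivity must be in (0, 1]")
  }
  if (ehr_specificity <= 0 || ehr_specificity > 1) {
    stop("ehr_specificity must be in (0, 1]")
  }
  stopifnot(m_causal >= 1)
  structure(as.list(environment()), class = "trait_architecture")
}

#' Liability threshold for a given prevalence
#'
#' Upper-K quantile of the standard normal: cases are the K-tail of the
#' liability distribution.
#' @param K Prevalence in (0, 1).
#' @export
liability_threshold <- function(K) {
  stopifnot(K > 0, K < 1)
  qnorm(1 - K)
}

# Scale a vector to exact sample mean 0 and variance v (n > 1).
scale_to_var <- function(x, v) {
  s <- stats::sd(x)
  if (s == 0 || v == 0) return(rep(0, length(x)))
  (x - mean(x)) / s * sqrt(v)
}

#' Simulate phenotypes on a genotype panel
#'
#' Draws causal effects, composes the standardized quantitative trait,
#' applies the liability threshold and EHR thinning, and (when covariates
#' are supplied) generates pain items, the mm-scale mJSW and 5-year fracture
#' outcomes.
#'
#' @param panel A `genotype_panel`.
#' @param arch A [trait_architecture()].
#' @param covariates Optional data.frame with `height`, `age`, `sex`,
#'   `body_fat` (e.g. from [generate_cohort()]); enables `mjsw_mm`, pain and
#'   fracture fields.
#' @param seed RNG seed.
#' @param effects Optional effects list (`idx`, `beta`) from a previous call
#'   (its attribute `"effects"`), to replay the same genetic architecture on
#'   a new sample.
#' @return A data.frame with columns `y_quant`, `genetic_value`, `liability`,
#'   `true_case`, `ehr_case` and, with covariates, `mjsw_mm`,
#'   `pain_month_flag`, `pain_3mo_flag`, `pain_rating`, `fracture_5yr_flag`.
#'   The causal architecture is attached as attribute `"effects"`.
#' @export
simulate_traits <- function(panel, arch, covariates = NULL, seed = 1L,
                            effects = NULL) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(arch, "trait_architecture"))
  if (arch$m_causal > panel$n_snps) stop("m_causal exceeds n_snps")
  n <- panel$n_subjects
  with_seed(seed, {
    if (is.null(effects)) {
      idx <- sort(sample.int(panel$n_snps, arch$m_causal))
      beta <- rnorm(arch$m_causal)
      effects <- list(idx = idx, beta = beta)
    }
    Gs <- standardize_dosages(panel$dosages[, effects$idx, drop = FALSE])
    g_raw <- as.vector(Gs %*% effects$beta)
    g <- scale_to_var(g_raw, arch$h2)
    e <- scale_to_var(rnorm(n), 1 - arch$h2)
    y <- g + e

    thr <- liability_threshold(arch$prevalence)
    true_case <- (-y) > thr # low joint space = disease
    ehr_case <- (true_case & runif(n) < arch$ehr_sensitivity) |
      (!true_case & runif(n) < 1 - arch$ehr_specificity)

    out <- data.frame(
      y_quant = y,
      genetic_value = g,
      liability = -y,
      true_case = true_case,
      ehr_case = ehr_case
    )

    if (!is.null(covariates)) {
      stopifnot(all(c("height", "age", "sex", "body_fat") %in% names(covariates)),
                nrow(covariates) == n)
      out$mjsw_mm <- compose_mjsw(covariates$height, covariates$age, y)
      rate <- function(p) ifelse(true_case, p[["case"]], p[["control"]])
      out$pain_month_flag <- runif(n) < rate(arch$pain_month)
      out$pain_3mo_flag <- runif(n) < rate(arch$pain_3mo)
      out$pain_rating <- as.integer(clamp(
        round(rnorm(n, rate(arch$pain_rating_mean), arch$pain_rating_sd)), 0, 10
      ))
      b <- arch$fracture_coef
      sexM <- as.numeric(covariates$sex == "M")
      lin <- b[["mjsw"]] * out$mjsw_mm + b[["height"]] * covariates$height +
        b[["sexM"]] * sexM + b[["age"]] * covariates$age +
        b[["body_fat"]] * covariates$body_fat
      # anchor intercept so the fracture rate at covariate means is as set
      b0 <- qlogis(arch$fracture_rate) -
        (b[["mjsw"]] * 4.0 + b[["height"]] * 169.5 + b[["sexM"]] * 0.502 +
           b[["age"]] * 64 + b[["body_fat"]] * 30.5)
      out$fracture_5yr_flag <- runif(n) < plogis(b0 + lin)
    }
    attr(out, "effects") <- effects
    out
  })
}

#' Simulate a pair of traits with correlated causal effects
#'
#' Both traits share the same causal SNPs; their effect-size vectors are
#' bivariate normal with correlation `arch$rg_shared`, so the pair's true
#' genetic correlation equals `rg_shared`.
#'
#' @inheritParams simulate_traits
#' @return A list with data.frames `t1`, `t2` (as [simulate_traits()],
#'   without covariate-derived fields).
#' @export
simulate_trait_pair <- function(panel, arch, seed = 1L) {
  stopifnot(inherits(arch, "trait_architecture"))
  rg <- arch$rg_shared
  if (is.null(rg) || abs(rg) > 1) stop("arch$rg_shared must be set in [-1, 1]")
  eff <- with_seed(seed, {
    idx <- sort(sample.int(panel$n_snps, arch$m_causal))
    b1 <- rnorm(arch$m_causal)
    b2 <- rg * b1 + sqrt(1 - rg^2) * rnorm(arch$m_causal)
    list(idx = idx, b1 = b1, b2 = b2)
  })
  t1 <- simulate_traits(panel, arch, seed = stage_seed(seed, 1),
                        effects = list(idx = eff$idx, beta = eff$b1))
  t2 <- simulate_traits(panel, arch, seed = stage_seed(seed, 2),
                        effects = list(idx = eff$idx, beta = eff$b2))
  list(t1 = t1, t2 = t2)
}
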