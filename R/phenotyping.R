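# Binary case ascertainment and its downstream analytics: a quantile
# dichotomizer standing in for an image classifier, inter-rater agreement
# tables, EHR-vs-model case comparison, and pain/fracture associations.

#' Dichotomize a quantitative phenotype at a target prevalence
#'
#' Cases are subjects whose value is at or below the empirical
#' lower-`prevalence_target` quantile. All values tied with the cutoff are
#' included, and the realized case fraction is reported. The dichotomizer
#' depends only on ranks, so it is invariant under strictly monotone
#' transforms of the phenotype. It stands in for an image-based classifier:
#' it thresholds the same latent severity quantity that the classifier
#' would, which is exactly the construct whose power is compared against
#' the quantitative analysis.
#'
#' @param values Numeric phenotype (lower = more severe).
#' @param prevalence_target Target case fraction in (0, 1).
#' @return A list with `case` (logical), `cutoff`, `realized_fraction`.
#' @export
dichotomize <- function(values, prevalence_target) {
  if (length(values) == 0) stop("values must be nonempty")
  if (prevalence_target <= 0 || prevalence_target >= 1) {
    stop("prevalence_target must be in (0, 1)")
  }
  n <- length(values)
  k <- max(1L, ceiling(prevalence_target * n))
  cutoff <- sort(values)[k]
  case <- values <= cutoff
  list(case = case, cutoff = cutoff, realized_fraction = mean(case))
}

#' Pairwise confusion table as proportions of 100
#'
#' Cross-tabulates two binary label vectors (control = 0/FALSE first) and
#' scales the 2x2 counts to sum to 100, the convention used for reporting
#' inter-rater agreement.
#'
#' @param rater_a,rater_b Equal-length binary label vectors.
#' @return A 2x2 matrix (rows = rater_a, cols = rater_b) summing to 100.
#' @export
pairwise_confusion <- function(rater_a, rater_b) {
  if (length(rater_a) != length(rater_b)) stop("label vectors differ in length")
  a <- factor(as.integer(as.logical(rater_a)), levels = 0:1)
  b <- factor(as.integer(as.logical(rater_b)), levels = 0:1)
  tab <- table(a, b)
  m <- matrix(as.numeric(tab), 2, 2,
              dimnames = list(c("control", "case"), c("control", "case")))
  m / sum(m) * 100
}

#' Average several confusion tables elementwise
#'
#' @param tables A list of 2x2 matrices (proportions of 100).
#' @export
average_confusion <- function(tables) {
  stopifnot(length(tables) >= 1)
  Reduce(`+`, tables) / length(tables)
}

#' Sensitivity and specificity of binary predictions
#'
#' @param truth,pred Equal-length binary vectors; both classes must be
#'   present in `truth`.
#' @return Named vector `c(sensitivity=, specificity=)`.
#' @export
sens_spec <- function(truth, pred) {
  truth <- as.logical(truth)
  pred <- as.logical(pred)
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  if (!any(truth)) stop("no cases present in truth")
  if (all(truth)) stop("no controls present in truth")
  c(
    sensitivity = sum(pred & truth) / sum(truth),
    specificity = sum(!pred & !truth) / sum(!truth)
  )
}

#' Compare EHR-coded cases with model-ascertained cases
#'
#' Counts cases found by each ascertainment, the overlap, the newly found
#' cases (model but not EHR), and the percentage increase over the EHR count
#' (rounded to the nearest integer for reporting).
#'
#' @param ehr_flags,model_flags Equal-length logical case vectors.
#' @return A list of class `case_comparison`.
#' @export
compare_cases <- function(ehr_flags, model_flags) {
  ehr_flags <- as.logical(ehr_flags)
  model_flags <- as.logical(model_flags)
  if (length(ehr_flags) != length(model_flags)) stop("flag vectors differ in length")
  n_ehr <- sum(ehr_flags)
  n_model <- sum(model_flags)
  overlap <- sum(ehr_flags & model_flags)
  n_new <- sum(model_flags & !ehr_flags)
  pct <- if (n_ehr == 0) NA_real_ else round(100 * n_new / n_ehr)
  structure(
    list(
      n_total = length(ehr_flags),
      n_ehr_cases = n_ehr,
      n_model_cases = n_model,
      overlap = overlap,
      n_new_cases = n_new,
      pct_increase = pct,
      pct_undefined = n_ehr == 0
    ),
    class = "case_comparison"
  )
}

#' @export
print.case_comparison <- function(x, ...) {
  cat(sprintf(
    "cases: EHR %d, model %d (overlap %d); %d new cases (%s%% increase) of %d subjects\n",
    x$n_ehr_cases, x$n_model_cases, x$overlap, x$n_new_cases,
    ifelse(x$pct_undefined, "NA", format(x$pct_increase)), x$n_total
  ))
  invisible(x)
}

#' Pain associations between cases and controls
#'
#' Pearson chi-square tests (no continuity correction) for the two binary
#' pain items and a two-sided Welch t-test for the 0-10 rating.
#'
#' @param case Logical case indicator.
#' @param pain_month,pain_3mo Logical pain flags.
#' @param pain_rating Integer 0-10 ratings.
#' @return A data.frame with one row per item: statistic, df (NA for t with
#'   fractional df reported separately), p-value, case/control summaries.
#' @export
pain_association <- function(case, pain_month, pain_3mo, pain_rating) {
  case <- as.logical(case)
  if (!any(case) || all(case)) stop("both cases and controls are required")
  chi_row <- function(flag, name) {
    tab <- table(factor(case, c(FALSE, TRUE)), factor(as.logical(flag), c(FALSE, TRUE)))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(
      item = name, statistic = unname(ct$statistic), df = unname(ct$parameter),
      p = unname(ct$p.value),
      case_value = mean(flag[case]), control_value = mean(flag[!case]),
      stringsAsFactors = FALSE
    )
  }
  tt <- stats::t.test(pain_rating[case], pain_rating[!case], var.equal = FALSE)
  rbind(
    chi_row(pain_month, "pain_month"),
    chi_row(pain_3mo, "pain_3mo"),
    data.frame(
      item = "pain_rating", statistic = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value,
      case_value = mean(pain_rating[case]),
      control_value = mean(pain_rating[!case]),
      stringsAsFactors = FALSE
    )
  )
}

#' Covariate-adjusted logistic model of 5-year fracture on mJSW
#'
#' Maximum-likelihood logistic regression (IRLS via `stats::glm`) of the
#' fracture flag on normalized mJSW, controlling for height, sex, age and
#' body-fat percentage; reports the Wald estimate, SE and p for the mJSW
#' coefficient. Perfect separation is flagged instead of estimated.
#'
#' @param fracture Logical outcome.
#' @param mjsw Normalized mJSW (mm).
#' @param covariates data.frame with `height`, `sex`, `age`, `body_fat`.
#' @return A list with `estimate`, `se`, `p`, `separation`, `fit`.
#' @export
fracture_model <- function(fracture, mjsw, covariates) {
  stopifnot(all(c("height", "sex", "age", "body_fat") %in% names(covariates)))
  d <- data.frame(
    fracture = as.logical(fracture), mjsw = mjsw,
    height = covariates$height, sex = factor(covariates$sex),
    age = covariates$age, body_fat = covariates$body_fat
  )
  fit <- suppressWarnings(
    stats::glm(fracture ~ mjsw + height + sex + age + body_fat,
               family = stats::binomial(), data = d)
  )
  mu <- fit$fitted.values
  sep <- !fit$converged || any(mu < 1e-10) || any(mu > 1 - 1e-10)
  if (sep) {
    return(list(estimate = NA_real_, se = NA_real_, p = NA_real_,
                separation = TRUE, fit = fit))
  }
  sm <- summary(fit)$coefficients["mjsw", ]
  list(estimate = unname(sm["Estimate"]), se = unname(sm["Std. Error"]),
       p = max(unname(sm["Pr(>|z|)"]), P_FLOOR), separation = FALSE, fit = fit)
}
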