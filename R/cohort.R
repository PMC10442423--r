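# Synthetic cohort covariates, mirroring the population characteristics of a
# biobank DXA-imaged subsample (sex-stratified age/height/BMI moments, low
# steroid-use and knee-trauma rates, self-reported pain items).

#' Default cohort configuration
#'
#' Sex-stratified moments for age at imaging (years), standing height (cm)
#' and BMI (kg/m^2), plus rates for steroid medication use and past knee
#' trauma. Defaults reproduce the marginal distributions of a 29,257-person
#' imaged biobank subsample: overall age 64 (7.5), height 169.5 (9.2),
#' 50.2% male. Body-fat percentage has no published moment in that table and
#' uses DXA-realistic sex-specific values.
#'
#' @param male_frac Probability a subject is male.
#' @param age_mean,age_sd,height_mean,height_sd,bmi_mean,bmi_sd Named
#'   two-element vectors (`M`, `F`).
#' @param body_fat_mean,body_fat_sd Named two-element vectors (`M`, `F`), %.
#' @param steroid_rate,trauma_rate Bernoulli rates.
#' @param age_range Truncation range for age (years).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(male_frac = 0.502,
                          age_mean = c(M = 64.6, F = 63.0),
                          age_sd = c(M = 7.6, F = 7.3),
                          height_mean = c(M = 176.2, F = 162.8),
                          height_sd = c(M = 6.6, F = 6.2),
                          bmi_mean = c(M = 27.0, F = 26.0),
                          bmi_sd = c(M = 3.9, F = 4.6),
                          body_fat_mean = c(M = 25, F = 36),
                          body_fat_sd = c(M = 6, F = 7),
                          steroid_rate = 424 / 29257,
                          trauma_rate = 351 / 29257,
                          age_range = c(46, 81)) {
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws `n` subjects with sex, age, height, BMI, body fat, steroid and
#' trauma flags, and a non-genetic baseline mJSW (mm). The baseline mJSW
#' declines with age (-0.028 mm/year) and scales with height; when traits
#' are simulated genetically (see [simulate_traits()]) the mJSW column is
#' recomposed there from the same covariate effects plus the genetic trait.
#'
#' @param n Number of subjects (>= 1).
#' @param config A [cohort_config()].
#' @param seed RNG seed.
#' @return A data.frame with one row per subject.
#' @export
generate_cohort <- function(n, config = cohort_config(), seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  cfg <- config
  with_seed(seed, {
    sex <- ifelse(runif(n) < cfg$male_frac, "M", "F")
    draw <- function(mean, sd) rnorm(n, mean[sex], sd[sex])
    age <- clamp(draw(cfg$age_mean, cfg$age_sd), cfg$age_range[1], cfg$age_range[2])
    height <- draw(cfg$height_mean, cfg$height_sd)
    bmi <- pmax(draw(cfg$bmi_mean, cfg$bmi_sd), 15)
    body_fat <- clamp(draw(cfg$body_fat_mean, cfg$body_fat_sd), 5, 60)
    data.frame(
      subject_id = sprintf("S%06d", seq_len(n)),
      sex = sex,
      age = age,
      height = height,
      bmi = bmi,
      body_fat = body_fat,
      steroid_flag = runif(n) < cfg$steroid_rate,
      trauma_flag = runif(n) < cfg$trauma_rate,
      true_mjsw = compose_mjsw(height, age, rnorm(n)),
      stringsAsFactors = FALSE
    )
  })
}

# mJSW in mm as a function of height (cm), age (years) and a standardized
# residual z (genetic + environmental when traits are simulated). Centered
# to 4.0 mm at the cohort's mean height (169.5 cm) and age (64 y).
compose_mjsw <- function(height, age, z,
                         mean_mm = 4.0, sd_mm = 0.45,
                         height_beta = 0.0165, age_beta = -0.028) {
  mean_mm + height_beta * (height - 169.5) + age_beta * (age - 64) + sd_mm * z
}
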