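#' Coefficient presets for the placental outcome model
#'
#' Returns the generative regression coefficients for one placental
#' outcome, taken from the fitted adjusted models reported for the cohort
#' the package emulates (MVPA and % ST jointly, adjusted for maternal
#' age, pre-pregnancy BMI, GDM and fetal sex). The outcome SD implied by
#' the reported standardized betas (sd_y = beta * sd_x / SB, consistent
#' between the MVPA and ST columns) fixes the residual SD, so simulated
#' cohorts reproduce both the effect sizes and their reported precision.
#' Covariate coefficients other than the exposures are not reported for
#' that cohort; small non-zero defaults are used so the adjustment set is
#' exercised without materially shifting the outcome variance.
#'
#' @param outcome one of `"density_whole"`, `"density_regions"`,
#'   `"vessel_area_whole"`, `"vessel_area_regions"`,
#'   `"vessel_count_whole"`, `"vessel_count_regions"`.
#' @return list with `beta` (named vector: intercept, mvpa, st_pct, age,
#'   bmi, gdm, fetal_sex), `residual_sd`, `mean_outcome`, `sd_outcome`.
#' @export
outcome_model_coefficients <- function(outcome = c("density_whole",
                                                   "density_regions",
                                                   "vessel_area_whole",
                                                   "vessel_area_regions",
                                                   "vessel_count_whole",
                                                   "vessel_count_regions")) {
  outcome <- match.arg(outcome)
  # beta_mvpa, beta_st, implied sd(y), cohort mean of the outcome
  tab <- list(
    density_whole        = c(0.12,  0.23,   6.6,   49.7),
    density_regions      = c(0.17,  0.35,   9.3,   56.6),
    vessel_area_whole    = c(-0.03, 0.03,   3.8,   15.6),
    vessel_area_regions  = c(-0.05, -0.03,  4.8,   17.9),
    vessel_count_whole   = c(0.10,  4.50,  215,  1324),
    vessel_count_regions = c(-1.52, 2.47,  286,  1735)
  )[[outcome]]
  cov <- default_covariate_distributions()
  beta <- c(intercept = NA_real_, mvpa = tab[1], st_pct = tab[2],
            age = 0.05, bmi = -0.10, gdm = -1.0, fetal_sex = 0.5)
  means <- c(1, cov$mvpa_mean, cov$st_mean, cov$age_mean,
             exp(cov$bmi_meanlog + cov$bmi_sdlog^2 / 2),
             cov$gdm_prev, 0.5)
  vars <- c(0, cov$mvpa_mean^2 / cov$mvpa_gamma_shape, cov$st_sd^2,
            cov$age_sd^2,
            (exp(cov$bmi_sdlog^2) - 1) * exp(2 * cov$bmi_meanlog + cov$bmi_sdlog^2),
            cov$gdm_prev * (1 - cov$gdm_prev), 0.25)
  beta["intercept"] <- 0
  beta["intercept"] <- tab[4] - sum(beta * means)
  explained <- sum(beta[-1]^2 * vars[-1])
  residual_sd <- sqrt(max(tab[3]^2 - explained, (0.3 * tab[3])^2))
  list(beta = beta, residual_sd = residual_sd,
       mean_outcome = tab[4], sd_outcome = tab[3])
}

#' Default covariate distributions of the simulated cohort
#'
#' Cohort summaries of the obese pregnant cohort being emulated: age
#' 33.3 +/- 5.4 years; pre-pregnancy BMI median 32.9 (IQR 4.2) kg/m^2 via
#' a log-normal truncated at the BMI >= 29 inclusion threshold; GDM
#' prevalence 34.8%; smoking 10.9%; PE/PIH 9.0%; nine recruiting
#' countries; exposures matching the activity calibration (MVPA mean
#' 39.5 min/day, gamma shape 4; % ST 72.3 +/- 7.6).
#'
#' @return named list of distribution parameters.
#' @export
default_covariate_distributions <- function() {
  iqr_ratio <- 4.2 / 32.9
  sdlog <- asinh(iqr_ratio / 2) / stats::qnorm(0.75)
  list(age_mean = 33.3, age_sd = 5.4,
       bmi_meanlog = log(32.9), bmi_sdlog = sdlog, bmi_min = 29,
       gdm_prev = 0.348, smoking_prev = 0.109, pe_pih_prev = 0.090,
       female_prev = 0.5,
       mvpa_mean = 39.5, mvpa_gamma_shape = 4,
       st_mean = 72.3, st_sd = 7.6,
       countries = c("AT", "BE", "DK", "IE", "IT", "NL", "PL", "ES", "UK"))
}

#' Specification of a simulated cohort
#'
#' @param n cohort size (default 92).
#' @param coefficients generative model from
#'   [outcome_model_coefficients()] or a compatible list.
#' @param outcome_name column name for the simulated outcome.
#' @param residual_sd override of the preset residual SD.
#' @param covariates covariate distributions
#'   ([default_covariate_distributions()]).
#' @param country_random_intercept_sd SD of the country-level random
#'   intercept added to the outcome (default 1.8, i.e. a country variance
#'   near the reported 3.23).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 92L,
                        coefficients = outcome_model_coefficients("density_whole"),
                        outcome_name = "density_whole",
                        residual_sd = NULL,
                        covariates = default_covariate_distributions(),
                        country_random_intercept_sd = 1.8,
                        seed = 1L) {
  check_scalar_number(n, "n", min = 2)
  residual_sd <- residual_sd %||% coefficients$residual_sd
  check_scalar_number(residual_sd, "residual_sd", min = 1e-9)
  check_scalar_number(country_random_intercept_sd,
                      "country_random_intercept_sd", min = 0)
  for (p in c("gdm_prev", "smoking_prev", "pe_pih_prev", "female_prev")) {
    check_scalar_number(covariates[[p]], p, 0, 1)
  }
  abort_if(!all(c("intercept", "mvpa", "st_pct") %in% names(coefficients$beta)),
           "coefficient vector must name intercept, mvpa and st_pct")
  structure(list(n = as.integer(n), coefficients = coefficients,
                 outcome_name = outcome_name, residual_sd = residual_sd,
                 covariates = covariates,
                 country_random_intercept_sd = country_random_intercept_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort table with known effect sizes
#'
#' Draws covariates and exposures from the configured distributions,
#' assigns women round-robin to countries, and generates the outcome as
#' `y = X beta + country intercept + eps`, `eps ~ N(0, residual_sd)`.
#'
#' @param spec a [cohort_spec()].
#' @param exposures optional data.frame with columns `mvpa` and `st_pct`
#'   (one row per woman) to use instead of freshly drawn exposures, e.g.
#'   measurements produced by the accelerometry stage.
#' @return data.frame with columns subject_id, country, age, bmi, gdm,
#'   fetal_sex, smoking, pe_pih, mvpa, st_pct and the outcome column.
#' @export
generate_cohort <- function(spec, exposures = NULL) {
  abort_if(!inherits(spec, "cohort_spec"), "`spec` must come from cohort_spec()")
  cov <- spec$covariates
  with_seed(spec$seed, {
    n <- spec$n
    age <- stats::rnorm(n, cov$age_mean, cov$age_sd)
    bmi <- stats::qlnorm(stats::runif(n, stats::plnorm(cov$bmi_min, cov$bmi_meanlog,
                                                       cov$bmi_sdlog), 1),
                         cov$bmi_meanlog, cov$bmi_sdlog)
    gdm <- stats::rbinom(n, 1, cov$gdm_prev)
    smoking <- stats::rbinom(n, 1, cov$smoking_prev)
    pe_pih <- stats::rbinom(n, 1, cov$pe_pih_prev)
    fetal_sex <- stats::rbinom(n, 1, cov$female_prev)  # 1 = female
    if (is.null(exposures)) {
      mvpa <- stats::rgamma(n, shape = cov$mvpa_gamma_shape,
                            scale = cov$mvpa_mean / cov$mvpa_gamma_shape)
      st_pct <- pmin(pmax(stats::rnorm(n, cov$st_mean, cov$st_sd), 30), 98)
    } else {
      abort_if(nrow(exposures) != n,
               "`exposures` must have one row per woman")
      mvpa <- exposures$mvpa
      st_pct <- exposures$st_pct
    }
    abort_if(stats::sd(mvpa) == 0 && stats::sd(st_pct) == 0,
             "singular exposure specification: MVPA and % ST both constant")
    country <- rep_len(cov$countries, n)
    u <- stats::rnorm(length(cov$countries), 0, spec$country_random_intercept_sd)
    names(u) <- cov$countries
    b <- spec$coefficients$beta
    y <- b[["intercept"]] + b[["mvpa"]] * mvpa + b[["st_pct"]] * st_pct +
      b[["age"]] * age + b[["bmi"]] * bmi + b[["gdm"]] * gdm +
      b[["fetal_sex"]] * fetal_sex + u[country] +
      stats::rnorm(n, 0, spec$residual_sd)
    out <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                      country = country, age = age, bmi = bmi, gdm = gdm,
                      fetal_sex = fetal_sex, smoking = smoking,
                      pe_pih = pe_pih, mvpa = mvpa, st_pct = st_pct,
                      stringsAsFactors = FALSE)
    out[[spec$outcome_name]] <- as.numeric(y)
    out
  })
}
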