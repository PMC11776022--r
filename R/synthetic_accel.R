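#' Cohort activity profile for the accelerometer simulator
#'
#' Describes the wear-time composition of a pregnant cohort's days. The
#' defaults are calibrated to the study conditions the package models:
#' cohort mean MVPA of 39.5 min/day and mean percent sedentary time of
#' 72.3% over a 14-h (840 min) wear day, with between-woman spread set by
#' `mvpa_gamma_shape` (gamma-distributed daily MVPA minutes; shape 4 gives
#' an interquartile range close to the reported 24.8 min) and
#' `sed_fraction_sd` (normal, 0.076 matching the reported SD of 7.6
#' percentage points).
#'
#' @param mean_mvpa_fraction,mean_sed_fraction,mean_light_fraction mean
#'   fractions of wear time per intensity; must sum to 1.
#' @param wear_minutes_per_day wear time per day (<= 1440).
#' @param n_days monitored days per time period.
#' @param swim_minutes_per_day diary-reported swimming minutes per day
#'   (added to MVPA downstream, not to wear time).
#' @param mvpa_gamma_shape shape of the gamma distribution of per-woman
#'   MVPA minutes per day.
#' @param sed_fraction_sd between-woman SD of the sedentary fraction.
#' @return object of class `activity_profile`.
#' @export
activity_profile <- function(mean_mvpa_fraction = 39.5 / 840,
                             mean_sed_fraction = 0.723,
                             mean_light_fraction =
                               1 - 0.723 - 39.5 / 840,
                             wear_minutes_per_day = 840,
                             n_days = 4L,
                             swim_minutes_per_day = 0,
                             mvpa_gamma_shape = 4,
                             sed_fraction_sd = 0.076) {
  check_scalar_number(mean_mvpa_fraction, "mean_mvpa_fraction", 0, 1)
  check_scalar_number(mean_sed_fraction, "mean_sed_fraction", 0, 1)
  check_scalar_number(mean_light_fraction, "mean_light_fraction", 0, 1)
  abort_if(abs(mean_mvpa_fraction + mean_sed_fraction + mean_light_fraction - 1) > 1e-8,
           "intensity fractions must sum to 1 over wear time")
  check_scalar_number(wear_minutes_per_day, "wear_minutes_per_day", 1, 1440)
  check_scalar_number(n_days, "n_days", min = 1)
  check_scalar_number(swim_minutes_per_day, "swim_minutes_per_day", 0, 1440)
  structure(list(mean_mvpa_fraction = mean_mvpa_fraction,
                 mean_sed_fraction = mean_sed_fraction,
                 mean_light_fraction = mean_light_fraction,
                 wear_minutes_per_day = wear_minutes_per_day,
                 n_days = as.integer(n_days),
                 swim_minutes_per_day = swim_minutes_per_day,
                 mvpa_gamma_shape = mvpa_gamma_shape,
                 sed_fraction_sd = sed_fraction_sd),
            class = "activity_profile")
}

accel_periods <- function() c("<20w", "24-28w", "35-37w")

#' Simulate minute-epoch accelerometer counts for a cohort
#'
#' Each woman gets a persistent activity level (gamma-distributed MVPA
#' minutes, normally distributed sedentary fraction, truncated to
#' physical ranges); each monitored day places `wear_minutes_per_day` of
#' wear in a continuous daytime block, draws a per-minute intensity
#' category from her composition, and draws counts uniformly within the
#' Freedson band of that category (sedentary 0-99, light 100-1951, MVPA
#' 1952-6000 counts/min). Non-wear minutes are zeros, forming >= 60-min
#' runs on both sides of the wear block.
#'
#' @param profile an [activity_profile()].
#' @param n_subjects number of women.
#' @param seed integer seed.
#' @param periods periods to simulate (default all three).
#' @return list with `counts` (data.frame: subject_id, period, day,
#'   minute_of_day, counts) and `swim_diary` (subject_id, period, day,
#'   swim_minutes).
#' @export
generate_accel_series <- function(profile, n_subjects = 92L, seed = 1L,
                                  periods = accel_periods()) {
  abort_if(!inherits(profile, "activity_profile"),
           "`profile` must come from activity_profile()")
  abort_if(profile$wear_minutes_per_day > 1440,
           "wear_minutes_per_day exceeds the length of a day")
  with_seed(seed, {
    wear <- as.integer(profile$wear_minutes_per_day)
    wear_start <- 420L                       # 07:00; leaves >= 60-min zero runs
    if (wear_start + wear > 1440L) wear_start <- 1440L - wear
    mean_mvpa_min <- profile$mean_mvpa_fraction * wear

    subj <- sprintf("S%03d", seq_len(n_subjects))
    # Persistent per-woman composition, drawn by stratified inverse-CDF
    # sampling: one uniform per stratum of 1/n, shuffled across women, so
    # the realized cohort distribution (mean, IQR) matches the calibrated
    # one without n = 92 sampling drift, while each woman's level remains
    # a random draw from the same marginal.
    strat_u <- function() {
      (seq_len(n_subjects) - stats::runif(n_subjects))[sample.int(n_subjects)] /
        n_subjects
    }
    mvpa_min_i <- if (mean_mvpa_min > 0) {
      stats::qgamma(strat_u(), shape = profile$mvpa_gamma_shape,
                    scale = mean_mvpa_min / profile$mvpa_gamma_shape)
    } else rep(0, n_subjects)
    mvpa_frac_i <- pmin(mvpa_min_i / wear, 0.30)
    sed_frac_i <- pmin(pmax(stats::qnorm(strat_u(), profile$mean_sed_fraction,
                                         profile$sed_fraction_sd), 0.40), 0.95)
    sed_frac_i <- pmin(sed_frac_i, 0.98 - mvpa_frac_i)
    light_frac_i <- 1 - sed_frac_i - mvpa_frac_i

    rows <- vector("list", n_subjects * length(periods))
    k <- 0L
    for (i in seq_len(n_subjects)) {
      p_cat <- c(sed_frac_i[i], light_frac_i[i], mvpa_frac_i[i])
      for (per in periods) {
        n_min <- profile$n_days * 1440L
        counts <- integer(n_min)
        for (d in seq_len(profile$n_days)) {
          cat_draw <- sample.int(3L, wear, replace = TRUE, prob = p_cat)
          cmin <- c(0L, 100L, 1952L)[cat_draw]
          cmax <- c(99L, 1951L, 6000L)[cat_draw]
          day_counts <- cmin + floor(stats::runif(wear) * (cmax - cmin + 1L))
          off <- (d - 1L) * 1440L
          counts[off + wear_start + seq_len(wear)] <- as.integer(day_counts)
        }
        k <- k + 1L
        rows[[k]] <- data.frame(subject_id = subj[i], period = per,
                                day = rep(seq_len(profile$n_days), each = 1440L),
                                minute_of_day = rep(0:1439, profile$n_days),
                                counts = counts,
                                stringsAsFactors = FALSE)
      }
    }
    counts_df <- do.call(rbind, rows)
    diary <- expand.grid(subject_id = subj, period = periods,
                         day = seq_len(profile$n_days),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    diary$swim_minutes <- profile$swim_minutes_per_day
    diary <- diary[order(diary$subject_id, diary$period, diary$day), ,
                   drop = FALSE]
    rownames(diary) <- NULL
    list(counts = counts_df, swim_diary = diary)
  })
}
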