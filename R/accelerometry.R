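#' Freedson cut-point classification of minute epochs
#'
#' Sedentary < 100 counts/min; light 100-1951; MVPA > 1951.
#'
#' @param counts nonnegative integer vector of counts per minute.
#' @return factor with levels sedentary, light, mvpa.
#' @export
classify_epoch <- function(counts) {
  abort_if(any(!is.finite(counts)) || any(counts < 0),
           "counts must be nonnegative")
  factor(ifelse(counts < 100, "sedentary",
                ifelse(counts <= 1951, "light", "mvpa")),
         levels = c("sedentary", "light", "mvpa"))
}

#' Wear-time detection for one subject-day
#'
#' Non-wear is any run of >= 60 consecutive zero-count minutes; the
#' remaining minutes are wear. A day is valid iff wear >= `min_wear`
#' minutes (default 600). Minutes absent from the record are treated as
#' zero counts.
#'
#' @param day data.frame with columns `minute_of_day` (0-1439) and
#'   `counts` for a single subject-day.
#' @param nonwear_run minimum zero-run length counting as non-wear.
#' @param min_wear minimum wear minutes for a valid day.
#' @return list: `wear` (logical length 1440), `wear_minutes`, `valid`.
#' @export
detect_wear <- function(day, nonwear_run = 60L, min_wear = 600L) {
  abort_if(anyDuplicated(day$minute_of_day) > 0,
           "duplicate minute_of_day within a day")
  abort_if(any(day$minute_of_day < 0 | day$minute_of_day > 1439),
           "minute_of_day must lie in [0, 1439]")
  counts <- integer(1440L)
  counts[day$minute_of_day + 1L] <- day$counts
  r <- rle(counts == 0L)
  nonwear <- rep(r$values & r$lengths >= nonwear_run, r$lengths)
  wear <- !nonwear
  list(wear = wear, wear_minutes = sum(wear), valid = sum(wear) >= min_wear)
}

#' Summarize one subject's accelerometry for one time period
#'
#' Per valid day, classifies wear minutes with the Freedson cut-points,
#' adds diary swimming minutes to that day's MVPA (swimming is not added
#' to wear time, so % ST keeps its wear-time denominator), computes the
#' daily % ST as 100 x sedentary / wear, and averages the daily values
#' over valid days. The summary is flagged invalid when fewer than
#' `min_days` valid days are available.
#'
#' @param records data.frame with columns subject_id, period, day,
#'   minute_of_day, counts for one subject-period.
#' @param swim_diary optional data.frame with subject_id, period, day,
#'   swim_minutes.
#' @param min_days minimum valid days for a valid period (default 3).
#' @param nonwear_run,min_wear forwarded to [detect_wear()].
#' @return one-row data.frame of class `period_summary`: subject_id,
#'   period, n_valid_days, mvpa_min_per_day, st_pct, light_min_per_day,
#'   sed_min_per_day, wear_min_per_day, valid.
#' @export
summarize_period <- function(records, swim_diary = NULL, min_days = 3L,
                             nonwear_run = 60L, min_wear = 600L) {
  abort_if(nrow(records) == 0, "no records supplied")
  sid <- unique(records$subject_id); per <- unique(records$period)
  abort_if(length(sid) != 1 || length(per) != 1,
           "records must cover exactly one subject and period")
  days <- split(records, records$day)
  daily <- lapply(names(days), function(d) {
    day <- days[[d]]
    w <- detect_wear(day, nonwear_run = nonwear_run, min_wear = min_wear)
    if (!w$valid) return(NULL)
    counts <- integer(1440L)
    counts[day$minute_of_day + 1L] <- day$counts
    cls <- classify_epoch(counts[w$wear])
    mins <- table(cls)
    swim <- 0
    if (!is.null(swim_diary)) {
      m <- swim_diary$subject_id == sid & swim_diary$period == per &
        swim_diary$day == as.integer(d)
      if (any(m)) swim <- sum(swim_diary$swim_minutes[m])
    }
    data.frame(sed = as.numeric(mins[["sedentary"]]),
               light = as.numeric(mins[["light"]]),
               mvpa = as.numeric(mins[["mvpa"]]) + swim,
               wear = w$wear_minutes,
               st_pct = 100 * as.numeric(mins[["sedentary"]]) / w$wear_minutes)
  })
  daily <- do.call(rbind, daily[!vapply(daily, is.null, logical(1))])
  n_valid <- if (is.null(daily)) 0L else nrow(daily)
  out <- data.frame(subject_id = sid, period = per, n_valid_days = n_valid,
                    mvpa_min_per_day = if (n_valid) mean(daily$mvpa) else NA_real_,
                    st_pct = if (n_valid) mean(daily$st_pct) else NA_real_,
                    light_min_per_day = if (n_valid) mean(daily$light) else NA_real_,
                    sed_min_per_day = if (n_valid) mean(daily$sed) else NA_real_,
                    wear_min_per_day = if (n_valid) mean(daily$wear) else NA_real_,
                    valid = n_valid >= min_days,
                    stringsAsFactors = FALSE)
  class(out) <- c("period_summary", class(out))
  out
}

#' Average period summaries into one pregnancy exposure
#'
#' Unweighted mean of MVPA and % ST over a subject's valid periods. A
#' subject with fewer than two valid periods is excluded (error).
#'
#' @param summaries data.frame of period summaries for one subject.
#' @return one-row data.frame: subject_id, mean_mvpa_min_per_day,
#'   mean_st_pct, n_periods_used.
#' @export
average_pregnancy <- function(summaries) {
  sid <- unique(summaries$subject_id)
  abort_if(length(sid) != 1, "summaries must belong to one subject")
  ok <- summaries[summaries$valid, , drop = FALSE]
  abort_if(nrow(ok) < 2,
           sprintf("subject %s excluded: fewer than two valid periods", sid))
  data.frame(subject_id = sid,
             mean_mvpa_min_per_day = mean(ok$mvpa_min_per_day),
             mean_st_pct = mean(ok$st_pct),
             n_periods_used = nrow(ok),
             stringsAsFactors = FALSE)
}

#' Full accelerometry stage for a cohort
#'
#' Runs [summarize_period()] per subject-period and [average_pregnancy()]
#' per subject, collecting exclusions instead of failing.
#'
#' @param counts minute-epoch table (subject_id, period, day,
#'   minute_of_day, counts).
#' @param swim_diary optional swim diary table.
#' @param min_days,nonwear_run,min_wear forwarded validity settings.
#' @return list: `exposures` data.frame (subject_id,
#'   mean_mvpa_min_per_day, mean_st_pct, n_periods_used), `summaries`
#'   (all period summaries), `excluded` data.frame (subject_id, reason).
#' @export
compute_exposures <- function(counts, swim_diary = NULL, min_days = 3L,
                              nonwear_run = 60L, min_wear = 600L) {
  dt <- data.table::as.data.table(counts)
  groups <- split(dt, by = c("subject_id", "period"), drop = TRUE)
  summaries <- lapply(groups, function(sub) {
    summarize_period(as.data.frame(sub), swim_diary, min_days = min_days,
                     nonwear_run = nonwear_run, min_wear = min_wear)
  })
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  exposures <- list(); excluded <- list()
  for (sid in unique(summaries$subject_id)) {
    s <- summaries[summaries$subject_id == sid, , drop = FALSE]
    res <- tryCatch(average_pregnancy(s), error = function(e) conditionMessage(e))
    if (is.character(res)) {
      excluded[[length(excluded) + 1L]] <- data.frame(subject_id = sid,
                                                      reason = res,
                                                      stringsAsFactors = FALSE)
    } else {
      exposures[[length(exposures) + 1L]] <- res
    }
  }
  list(exposures = if (length(exposures)) do.call(rbind, exposures) else NULL,
       summaries = summaries,
       excluded = if (length(excluded)) do.call(rbind, excluded) else
         data.frame(subject_id = character(0), reason = character(0)))
}
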