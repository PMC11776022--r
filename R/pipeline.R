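#' Default pipeline configuration
#'
#' A file-first configuration (round-trips losslessly through YAML) for
#' the end-to-end simulate -> segment -> quantify -> accel -> stats run.
#' The demonstration defaults use a reduced cohort and slide size so a
#' full run completes on a desktop; every block is overridable.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param n_subjects number of women simulated.
#' @return nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L, n_subjects = 16L) {
  structure(list(
    seed = as.integer(seed),
    n_subjects = as.integer(n_subjects),
    slides_per_subject = 2L,
    countries = c("AT", "DK", "NL"),
    slide = list(width_px = 256L, height_px = 256L, pixel_size_um = 4,
                 fibrin_fraction = 0.03, artifact_fraction = 0.01,
                 vessel_density_per_mm2 = 1324,
                 vessel_radius_um_range = c(4, 8)),
    regions = list(k = 2L, diameter_um = 500, floor = 0.30),
    accel = list(wear_minutes_per_day = 840, n_days = 4L,
                 min_days = 3L, min_wear = 600L, nonwear_run = 60L),
    cohort = list(outcome = "density_whole",
                  country_random_intercept_sd = 1.8,
                  zero_effects = FALSE),
    qc = list(artifact_threshold = 0.15, stain_floor = 0.2,
              weak_stain_subjects = character(0)),
    vessels = list(min_area_um2 = 20)
  ), class = "run_config")
}

#' Read/write a run configuration as YAML
#' @param config a `run_config` list.
#' @param path YAML file path.
#' @return `write_config` the path; `read_config` a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  merge_rec <- function(base, new) {
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(new[[nm]])) {
        merge_rec(base[[nm]], new[[nm]])
      } else new[[nm]]
    }
    base
  }
  structure(merge_rec(unclass(default_config()), cfg), class = "run_config")
}

stage_seed <- function(seed, k) (as.integer(seed) * 101L + k * 7919L) %% 2147483562L

#' Run the full simulation-and-analysis pipeline
#'
#' Stages: (1) simulate minute-epoch accelerometry for the cohort and
#' derive MVPA / % ST exposures; (2) simulate the cohort table with
#' outcomes generated from the measured exposures under the configured
#' coefficient preset; (3) render two slides per woman whose villous
#' fraction encodes her whole-section outcome, segment them, apply QC,
#' and compute whole-section and region stereology metrics (two-slide
#' means per woman); (4) fit the tertile contrasts, adjusted models,
#' country-clustered mixed model and sensitivity analyses on the measured
#' metrics; (5) write all tables plus a run report with content hashes
#' and the exclusion log.
#'
#' @param config a [default_config()]-style `run_config`.
#' @param out_dir output directory (created).
#' @return list of class `run_report` (also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  ## Stage 1: accelerometry ------------------------------------------------
  profile <- activity_profile(wear_minutes_per_day = config$accel$wear_minutes_per_day,
                              n_days = config$accel$n_days)
  accel <- generate_accel_series(profile, n_subjects = config$n_subjects,
                                 seed = stage_seed(seed, 1L))
  exp_res <- compute_exposures(accel$counts, accel$swim_diary,
                               min_days = config$accel$min_days,
                               nonwear_run = config$accel$nonwear_run,
                               min_wear = config$accel$min_wear)
  exclusions <- if (nrow(exp_res$excluded)) {
    cbind(stage = "accelerometry", exp_res$excluded)
  } else NULL
  exposures <- exp_res$exposures
  abort_if(is.null(exposures), "accelerometry: no subject had two valid periods")

  ## Stage 2: cohort with outcomes from measured exposures ------------------
  cov <- default_covariate_distributions()
  cov$countries <- config$countries
  coeffs <- outcome_model_coefficients(config$cohort$outcome)
  if (isTRUE(config$cohort$zero_effects)) {
    coeffs$beta[c("mvpa", "st_pct")] <- 0
  }
  spec <- cohort_spec(n = nrow(exposures),
                      coefficients = coeffs,
                      outcome_name = config$cohort$outcome,
                      covariates = cov,
                      country_random_intercept_sd = config$cohort$country_random_intercept_sd,
                      seed = stage_seed(seed, 2L))
  cohort <- generate_cohort(spec, exposures = data.frame(
    mvpa = exposures$mean_mvpa_min_per_day, st_pct = exposures$mean_st_pct))
  cohort$subject_id <- exposures$subject_id

  ## Stage 3: slides, segmentation, stereology ------------------------------
  slide_rows <- list(); qc_rows <- list()
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject_id[i]
    vf <- min(max(cohort[[config$cohort$outcome]][i] / 100, 0.15), 0.85)
    stain_scale <- if (sid %in% config$qc$weak_stain_subjects) 0.1 else 1
    per_slide <- list()
    for (s in seq_len(config$slides_per_subject)) {
      sp <- slide_params(width_px = config$slide$width_px,
                         height_px = config$slide$height_px,
                         pixel_size_um = config$slide$pixel_size_um,
                         villous_fraction = vf,
                         fibrin_fraction = config$slide$fibrin_fraction,
                         artifact_fraction = config$slide$artifact_fraction,
                         vessel_density_per_mm2 = config$slide$vessel_density_per_mm2,
                         vessel_radius_um_range = config$slide$vessel_radius_um_range,
                         stain_intensity_scale = stain_scale,
                         seed = stage_seed(seed, 100L + 10L * i + s))
      sl <- generate_slide(sp, id = sprintf("%s_s%d", sid, s))
      seg <- segment_slide(sl$image,
                           vessel_opts = vessel_params(min_area_um2 = config$vessels$min_area_um2))
      qc <- qc_slide(seg$labels, seg$stain_field,
                     artifact_threshold = config$qc$artifact_threshold,
                     stain_floor = config$qc$stain_floor)
      qc_rows[[length(qc_rows) + 1L]] <- data.frame(
        subject_id = sid, slide_id = sl$image$id, pass = qc$pass,
        reason = qc$reason, stringsAsFactors = FALSE)
      if (!qc$pass) {
        exclusions <- rbind(exclusions, data.frame(
          stage = "slide_qc", subject_id = sid,
          reason = sprintf("slide %s failed QC: %s", sl$image$id, qc$reason),
          stringsAsFactors = FALSE))
        next
      }
      whole <- compute_metrics(seg$labels, seg$vessels)
      regs <- tryCatch(place_regions(seg$labels, k = config$regions$k,
                                     diameter_um = config$regions$diameter_um,
                                     seed = stage_seed(seed, 200L + i),
                                     floor = config$regions$floor),
                       error = function(e) list())
      reg_metrics <- lapply(regs, function(r) compute_metrics(seg$labels, seg$vessels,
                                                              region = r))
      per_slide[[s]] <- data.frame(
        subject_id = sid, slide_id = sl$image$id,
        density_whole = whole$density_villi_pct,
        vessel_area_whole = whole$vessel_area_pct,
        vessel_count_whole = whole$vessel_count_per_mm2,
        density_regions = if (length(reg_metrics)) {
          mean(vapply(reg_metrics, function(m) m$density_villi_pct, numeric(1)))
        } else NA_real_,
        vessel_area_regions = if (length(reg_metrics)) {
          mean(vapply(reg_metrics, function(m) m$vessel_area_pct, numeric(1)))
        } else NA_real_,
        vessel_count_regions = if (length(reg_metrics)) {
          mean(vapply(reg_metrics, function(m) m$vessel_count_per_mm2, numeric(1)))
        } else NA_real_,
        stringsAsFactors = FALSE)
    }
    per_slide <- do.call(rbind, per_slide)
    if (!is.null(per_slide) && nrow(per_slide) > 0) {
      slide_rows[[length(slide_rows) + 1L]] <- per_slide
    }
  }
  slide_metrics <- do.call(rbind, slide_rows)
  abort_if(is.null(slide_metrics), "imaging: every slide failed QC")
  # Two sections per woman are averaged before analysis.
  metric_cols <- setdiff(names(slide_metrics), c("subject_id", "slide_id"))
  agg <- stats::aggregate(slide_metrics[metric_cols],
                          by = list(subject_id = slide_metrics$subject_id),
                          FUN = mean)
  analysis <- merge(cohort[setdiff(names(cohort), config$cohort$outcome)],
                    agg, by = "subject_id")
  measured_outcome <- "density_whole"

  ## Stage 4: statistics ----------------------------------------------------
  tert <- assign_tertiles(analysis$mvpa)
  tertile_res <- compare_tertiles(analysis[[measured_outcome]], tert$group)
  fits <- lapply(intersect(c("density_whole", "density_regions",
                             "vessel_area_whole", "vessel_count_whole"),
                           names(analysis)),
                 function(oc) {
                   ft <- tryCatch(fit_adjusted_model(analysis, oc),
                                  error = function(e) NULL)
                   if (is.null(ft)) NULL else cbind(outcome = oc, ft$table)
                 })
  table2 <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
  mixed <- tryCatch(fit_mixed_model(analysis, measured_outcome),
                    error = function(e) NULL)
  sens <- sensitivity_analysis(analysis, measured_outcome)

  ## Stage 5: outputs and report --------------------------------------------
  paths <- list(cohort = "cohort.csv", exposures = "exposures.csv",
                slide_metrics = "slide_metrics.csv",
                analysis = "analysis_table.csv",
                table2 = "adjusted_models.csv",
                sensitivity = "sensitivity.csv", qc = "qc.csv")
  paths <- lapply(paths, function(p) file.path(out_dir, p))
  utils::write.csv(cohort, paths$cohort, row.names = FALSE)
  utils::write.csv(exposures, paths$exposures, row.names = FALSE)
  utils::write.csv(slide_metrics, paths$slide_metrics, row.names = FALSE)
  utils::write.csv(analysis, paths$analysis, row.names = FALSE)
  utils::write.csv(table2, paths$table2, row.names = FALSE)
  utils::write.csv(sens, paths$sensitivity, row.names = FALSE)
  utils::write.csv(do.call(rbind, qc_rows), paths$qc, row.names = FALSE)

  manifest <- data.frame(file = basename(unlist(paths)),
                         md5 = unname(tools::md5sum(unlist(paths))),
                         stringsAsFactors = FALSE)
  report <- list(
    config = unclass(config),
    n_subjects_analysed = nrow(analysis),
    exclusions = if (is.null(exclusions)) list() else exclusions,
    tertiles = list(cuts = tert$cuts, test = tertile_res$test,
                    p_value = tertile_res$p_value),
    mixed = if (is.null(mixed)) NULL else list(
      cluster_variance = mixed$cluster_variance,
      cluster_variance_se = mixed$cluster_variance_se,
      lrt_p = mixed$lrt$p_value),
    manifest = manifest)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  structure(c(report, list(out_dir = out_dir, table2 = table2,
                           analysis = analysis)),
            class = "run_report")
}

#' Segment a slide end to end
#'
#' Convenience wrapper chaining [detect_tissue()],
#' [classify_villous_tissue()], [extract_stain_channel()] and
#' [segment_vessels()].
#'
#' @param image a [slide_image()].
#' @param exclusion_polygons optional polygons for [apply_exclusions()].
#' @param classifier_opts from [classifier_params()].
#' @param vessel_opts from [vessel_params()].
#' @return list: `labels` ([label_mask()]), `stain_field`, `vessels`
#'   ([vessel_instances()]).
#' @export
segment_slide <- function(image, exclusion_polygons = list(),
                          classifier_opts = classifier_params(),
                          vessel_opts = vessel_params()) {
  tissue <- detect_tissue(image, classifier_opts$tissue_threshold)
  labels <- classify_villous_tissue(image, tissue, classifier_opts)
  labels <- apply_exclusions(labels, exclusion_polygons)
  stain <- extract_stain_channel(image)
  vessels <- segment_vessels(stain, labels, vessel_opts)
  list(labels = labels, stain_field = stain, vessels = vessels)
}

#' Rebuild the run report from an existing output directory
#'
#' Recomputes the manifest hashes from the files on disk; running it on
#' an untouched output directory reproduces `report.json` exactly.
#'
#' @param out_dir a [run_pipeline()] output directory.
#' @return the report list, invisibly; rewrites `report.json`.
#' @export
rebuild_report <- function(out_dir) {
  path <- file.path(out_dir, "report.json")
  abort_if(!file.exists(path), "no report.json in out_dir")
  report <- jsonlite::read_json(path, simplifyVector = TRUE)
  files <- report$manifest$file
  report$manifest <- data.frame(file = files,
                                md5 = unname(tools::md5sum(file.path(out_dir, files))),
                                stringsAsFactors = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(report)
}
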