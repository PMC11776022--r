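#' Detect tissue by the 8-bit intensity threshold
#'
#' A pixel is tissue iff its luminance (arithmetic mean of R, G, B,
#' rounded half-up) is strictly below 210 on the 8-bit scale; the
#' near-white intervillous background and slide glass fall above it.
#'
#' @param image a [slide_image()] with integer 8-bit channel values.
#' @param threshold intensity threshold (default 210).
#' @return logical matrix, `TRUE` = tissue.
#' @export
detect_tissue <- function(image, threshold = 210) {
  abort_if(!inherits(image, "slide_image"), "`image` must be a slide_image")
  rgb <- image$rgb
  abort_if(any(rgb != round(rgb)) || min(rgb) < 0 || max(rgb) > 255,
           "image is not 8-bit: channel values must be integers in [0, 255]")
  luminance(rgb) < threshold
}

#' Apply manual exclusion polygons to a class mask
#'
#' Marks pixels inside the given polygons as `excluded`; every downstream
#' denominator ignores them. Polygons reaching outside the image are
#' clipped with a warning. Point-in-polygon uses the even-odd rule on
#' pixel centres.
#'
#' @param mask a [label_mask()].
#' @param polygons list of n x 2 matrices of (row, col) pixel coordinates
#'   (closed implicitly).
#' @return updated [label_mask()].
#' @export
apply_exclusions <- function(mask, polygons) {
  abort_if(!inherits(mask, "label_mask"), "`mask` must be a label_mask")
  if (length(polygons) == 0) return(mask)
  labels <- mask$labels
  nr <- nrow(labels); nc <- ncol(labels)
  for (poly in polygons) {
    poly <- as.matrix(poly)
    abort_if(ncol(poly) != 2 || nrow(poly) < 3,
             "each polygon needs >= 3 (row, col) vertices")
    if (any(poly[, 1] < 1 | poly[, 1] > nr | poly[, 2] < 1 | poly[, 2] > nc)) {
      warning("exclusion polygon extends outside image bounds; clipping")
    }
    rlo <- max(1L, floor(min(poly[, 1]))); rhi <- min(nr, ceiling(max(poly[, 1])))
    clo <- max(1L, floor(min(poly[, 2]))); chi <- min(nc, ceiling(max(poly[, 2])))
    if (rlo > rhi || clo > chi) next
    rr <- rep(rlo:rhi, times = chi - clo + 1L)
    cc <- rep(clo:chi, each = rhi - rlo + 1L)
    inside <- point_in_polygon(rr, cc, poly)
    labels[cbind(rr[inside], cc[inside])] <- label_codes()[["excluded"]]
  }
  label_mask(labels, mask$pixel_size_um)
}

# Even-odd rule, vectorized over query points.
point_in_polygon <- function(py, px, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(py))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Parameters of the rule-based tissue classifier
#'
#' Decision thresholds of the deterministic pixel classifier, fitted once
#' on generated labelled tiles and frozen: staining artifacts are dark
#' achromatic speckles (low channel spread, luminance < `artifact_lum`),
#' fibrin is pale tissue (luminance >= `fibrin_lum`), and everything else
#' below the tissue threshold is villous tissue (vessel pixels, which sit
#' on villi, stay in the villi class).
#'
#' @param tissue_threshold 8-bit luminance threshold for tissue.
#' @param artifact_lum luminance ceiling of artifact pixels.
#' @param artifact_sat channel max-min ceiling of (achromatic) artifacts.
#' @param fibrin_lum luminance floor of fibrin pixels.
#' @return named list.
#' @export
classifier_params <- function(tissue_threshold = 210, artifact_lum = 120,
                              artifact_sat = 25, fibrin_lum = 170) {
  list(tissue_threshold = tissue_threshold, artifact_lum = artifact_lum,
       artifact_sat = artifact_sat, fibrin_lum = fibrin_lum)
}

#' Classify tissue pixels into villi, fibrin, artifact and background
#'
#' Deterministic rule-based pixel classification of the tissue mask, then
#' artifact components lying in the intervillous space (their border is
#' predominantly background) are reassigned to background.
#'
#' The returned mask carries the attribute `artifact_fraction_raw`: the
#' artifact share of tissue pixels *before* reassignment, used by
#' [qc_slide()] to judge staining quality.
#'
#' @param image a [slide_image()].
#' @param tissue_mask logical matrix from [detect_tissue()]; computed if
#'   `NULL`.
#' @param params thresholds from [classifier_params()].
#' @return a [label_mask()].
#' @export
classify_villous_tissue <- function(image, tissue_mask = NULL,
                                    params = classifier_params()) {
  abort_if(!inherits(image, "slide_image"), "`image` must be a slide_image")
  if (is.null(tissue_mask)) tissue_mask <- detect_tissue(image, params$tissue_threshold)
  codes <- label_codes()
  lum <- luminance(image$rgb)
  sat <- pmax(image$rgb[, , 1], image$rgb[, , 2], image$rgb[, , 3]) -
    pmin(image$rgb[, , 1], image$rgb[, , 2], image$rgb[, , 3])
  labels <- matrix(codes[["background"]], nrow(lum), ncol(lum))
  is_artifact <- tissue_mask & lum < params$artifact_lum & sat < params$artifact_sat
  is_fibrin <- tissue_mask & !is_artifact & lum >= params$fibrin_lum
  is_villi <- tissue_mask & !is_artifact & !is_fibrin
  labels[is_villi] <- codes[["villi"]]
  labels[is_fibrin] <- codes[["fibrin"]]
  labels[is_artifact] <- codes[["artifact"]]
  n_tissue <- sum(tissue_mask)
  raw_frac <- if (n_tissue > 0) sum(is_artifact) / n_tissue else 0

  # Reassign artifact components surrounded by intervillous space.
  if (any(is_artifact)) {
    comp <- as_matrix_img(EBImage::bwlabel(is_artifact * 1))
    nr <- nrow(labels); nc <- ncol(labels)
    for (k in seq_len(max(comp))) {
      idx <- which(comp == k)
      rr <- (idx - 1L) %% nr + 1L; cc <- (idx - 1L) %/% nr + 1L
      ring <- unique(rbind(cbind(pmax(rr - 1L, 1L), cc),
                           cbind(pmin(rr + 1L, nr), cc),
                           cbind(rr, pmax(cc - 1L, 1L)),
                           cbind(rr, pmin(cc + 1L, nc))))
      ring_lab <- labels[ring]
      border <- ring_lab[!(ring_lab == codes[["artifact"]])]
      if (length(border) == 0 ||
          mean(border == codes[["background"]]) >= 0.5) {
        labels[idx] <- codes[["background"]]
      }
    }
  }
  out <- label_mask(labels, image$pixel_size_um)
  attr(out, "artifact_fraction_raw") <- raw_frac
  out
}

#' Extract the AEC (CD34) stain channel
#'
#' Per-pixel AEC optical density by colour deconvolution with the
#' configured stain vectors; white pixels map to ~0 and negative
#' deconvolution residues are clipped at 0.
#'
#' @param image a [slide_image()] or a (rows, cols, 3) array (continuous
#'   values accepted).
#' @param stains stain basis from [stain_vectors()].
#' @return nonnegative numeric matrix of AEC optical densities.
#' @export
extract_stain_channel <- function(image, stains = stain_vectors()) {
  rgb <- if (inherits(image, "slide_image")) image$rgb else image
  pmax(deconvolve_stains(rgb, stains)$aec, 0)
}

# Otsu threshold on a numeric vector (256-bin histogram, maximizing
# between-class variance). Used within villous pixels only, so EBImage's
# whole-image otsu does not apply.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) < 1e-12) return(rng[1])
  h <- tabulate(pmin(pmax(floor((x - rng[1]) / diff(rng) * n_bins) + 1L, 1L),
                     n_bins), nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  rng[1] + k / n_bins * diff(rng)
}

#' Parameters of the vessel segmentation step
#'
#' @param min_area_um2 minimum instance area kept (default 20 um^2, a
#'   lower bound for capillary cross-sections).
#' @param threshold fixed AEC-OD threshold; `NULL` (default) uses a
#'   per-slide Otsu threshold within villous pixels.
#' @param watershed_tolerance,watershed_ext arguments of the
#'   distance-transform watershed that splits touching vessels.
#' @return named list.
#' @export
vessel_params <- function(min_area_um2 = 20, threshold = NULL,
                          watershed_tolerance = 1, watershed_ext = 1) {
  list(min_area_um2 = min_area_um2, threshold = threshold,
       watershed_tolerance = watershed_tolerance,
       watershed_ext = watershed_ext)
}

#' Segment vessel cross-sections from the AEC stain field
#'
#' Thresholds the stain field (per-slide Otsu within villous pixels by
#' default), fills internal holes so vessel lumina count toward the
#' cross-section area, separates touching vessels by distance-transform
#' watershed, drops instances below the minimum area, and flags each
#' instance as inside the villous area iff its centroid lies on a
#' villi-class pixel.
#'
#' @param stain_field AEC OD matrix from [extract_stain_channel()].
#' @param labels a [label_mask()] of the same shape.
#' @param params from [vessel_params()].
#' @return a [vessel_instances()] object.
#' @export
segment_vessels <- function(stain_field, labels, params = vessel_params()) {
  abort_if(!inherits(labels, "label_mask"), "`labels` must be a label_mask")
  abort_if(!identical(dim(stain_field), dim(labels$labels)),
           "stain field and labels must share shape")
  codes <- label_codes()
  villi <- labels$labels == codes[["villi"]]
  abort_if(!any(villi), "no villous tissue")
  thr <- params$threshold %||% otsu_threshold(stain_field[villi])
  bw <- stain_field > thr & labels$labels != codes[["excluded"]]
  if (!any(bw)) {
    return(vessel_instances(matrix(0L, nrow(bw), ncol(bw)),
                            empty_vessel_records(), labels$pixel_size_um))
  }
  bw <- as_matrix_img(EBImage::fillHull(bw * 1)) > 0
  dm <- EBImage::distmap(bw * 1)
  ws <- as_matrix_img(EBImage::watershed(dm,
                                         tolerance = params$watershed_tolerance,
                                         ext = params$watershed_ext))
  ws <- matrix(as.integer(ws), nrow(bw), ncol(bw))
  px_area <- labels$pixel_size_um^2
  n0 <- max(ws)
  if (n0 == 0) {
    return(vessel_instances(ws, empty_vessel_records(), labels$pixel_size_um))
  }
  areas <- tabulate(ws[ws > 0], nbins = n0)
  keep <- which(areas * px_area >= params$min_area_um2)
  remap <- integer(n0)
  remap[keep] <- seq_along(keep)
  ws[ws > 0] <- remap[ws[ws > 0]]
  if (length(keep) == 0) {
    return(vessel_instances(ws, empty_vessel_records(), labels$pixel_size_um))
  }
  idx <- which(ws > 0)
  ids <- ws[idx]
  nr <- nrow(ws)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  cy <- rowsum(as.numeric(rows), ids)[, 1] / tabulate(ids)
  cx <- rowsum(as.numeric(cols), ids)[, 1] / tabulate(ids)
  ci <- cbind(pmin(pmax(round(cy), 1), nr), pmin(pmax(round(cx), 1), ncol(ws)))
  records <- data.frame(id = seq_along(keep),
                        area_um2 = areas[keep] * px_area,
                        centroid_row = cy, centroid_col = cx,
                        inside_villi = labels$labels[ci] == codes[["villi"]])
  vessel_instances(ws, records, labels$pixel_size_um)
}

empty_vessel_records <- function() {
  data.frame(id = integer(0), area_um2 = numeric(0),
             centroid_row = numeric(0), centroid_col = numeric(0),
             inside_villi = logical(0))
}

#' Slide-level staining quality control
#'
#' Fails a slide when the (pre-reassignment) artifact share of tissue
#' exceeds `artifact_threshold`, or when the 90th percentile of villous
#' AEC optical density falls below `stain_floor` (weak CD34 staining).
#'
#' @param labels classified [label_mask()] from
#'   [classify_villous_tissue()].
#' @param stain_field AEC OD matrix.
#' @param artifact_threshold maximum tolerated artifact fraction of
#'   tissue (default 0.15).
#' @param stain_floor minimum 90th-percentile villous AEC OD (default
#'   0.2).
#' @return list of class `qc_report`: `artifact_fraction`,
#'   `stain_p90_od`, `pass`, `reason`.
#' @export
qc_slide <- function(labels, stain_field, artifact_threshold = 0.15,
                     stain_floor = 0.2) {
  abort_if(!inherits(labels, "label_mask"), "`labels` must be a label_mask")
  codes <- label_codes()
  art <- attr(labels, "artifact_fraction_raw")
  if (is.null(art)) {
    tissue <- labels$labels != codes[["background"]] &
      labels$labels != codes[["excluded"]]
    art <- if (any(tissue)) {
      sum(labels$labels == codes[["artifact"]]) / sum(tissue)
    } else 0
  }
  villi <- labels$labels == codes[["villi"]]
  p90 <- if (any(villi)) {
    as.numeric(stats::quantile(stain_field[villi], 0.9, names = FALSE))
  } else 0
  reason <- character(0)
  if (art > artifact_threshold) reason <- c(reason, "artifact fraction above threshold")
  if (p90 < stain_floor) reason <- c(reason, "weak staining")
  structure(list(artifact_fraction = art, stain_p90_od = p90,
                 pass = length(reason) == 0,
                 reason = if (length(reason)) paste(reason, collapse = "; ") else "ok"),
            class = "qc_report")
}
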