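#' Slide image container
#'
#' An 8-bit RGB section image with its physical pixel size. The raster is
#' stored as a (rows, cols, 3) array with values in \[0, 255\].
#'
#' @param rgb numeric array of dim (rows, cols, 3).
#' @param pixel_size_um physical edge length of one pixel in micrometres.
#' @param id slide identifier string.
#' @return object of class `slide_image`.
#' @export
slide_image <- function(rgb, pixel_size_um, id = "slide") {
  abort_if(length(dim(rgb)) != 3L || dim(rgb)[3] != 3L,
           "`rgb` must be a (rows, cols, 3) array")
  abort_if(min(rgb) < 0 || max(rgb) > 255, "channel values must lie in [0, 255]")
  check_scalar_number(pixel_size_um, "pixel_size_um", min = 1e-6)
  structure(list(rgb = rgb, pixel_size_um = pixel_size_um, id = as.character(id)),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<slide_image '%s'> %d x %d px @ %.3g um/px (%.2f x %.2f mm)\n",
              x$id, d[1], d[2], x$pixel_size_um,
              d[1] * x$pixel_size_um / 1000, d[2] * x$pixel_size_um / 1000))
  invisible(x)
}

# Integer label codes shared by the generator, the classifier and all IO.
#' Label codes of the tissue class mask
#'
#' Integer per-pixel codes: 0 background/intervillous space, 1 villi,
#' 2 fibrin, 3 staining artifact, 4 manually excluded.
#' @return named integer vector.
#' @export
label_codes <- function() {
  c(background = 0L, villi = 1L, fibrin = 2L, artifact = 3L, excluded = 4L)
}

#' Tissue class mask container
#'
#' @param labels integer matrix using [label_codes()].
#' @param pixel_size_um pixel edge in micrometres (inherited from the image).
#' @return object of class `label_mask`.
#' @export
label_mask <- function(labels, pixel_size_um) {
  abort_if(!is.matrix(labels), "`labels` must be a matrix")
  abort_if(!all(labels %in% label_codes()), "unknown label code in mask")
  check_scalar_number(pixel_size_um, "pixel_size_um", min = 1e-6)
  structure(list(labels = labels, pixel_size_um = pixel_size_um),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = label_codes(),
                      labels = names(label_codes())))
  cat(sprintf("<label_mask> %d x %d px @ %.3g um/px\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_um))
  print(round(100 * tab / length(x$labels), 2))
  invisible(x)
}

#' Vessel instance container
#'
#' @param instance_labels integer matrix; 0 = no vessel, k = vessel k with
#'   ids contiguous from 1.
#' @param records data.frame with one row per instance: `id`, `area_um2`,
#'   `centroid_row`, `centroid_col`, `inside_villi`.
#' @param pixel_size_um pixel edge in micrometres.
#' @return object of class `vessel_instances`.
#' @export
vessel_instances <- function(instance_labels, records, pixel_size_um) {
  abort_if(!is.matrix(instance_labels), "`instance_labels` must be a matrix")
  n <- nrow(records)
  abort_if(n > 0 && !identical(sort(unique(records$id)), seq_len(n)),
           "instance ids must be contiguous from 1")
  abort_if(n > 0 && any(records$area_um2 <= 0), "instance areas must be positive")
  structure(list(instance_labels = instance_labels, records = records,
                 pixel_size_um = pixel_size_um),
            class = "vessel_instances")
}

#' @export
print.vessel_instances <- function(x, ...) {
  cat(sprintf("<vessel_instances> %d instances (%d inside villi)\n",
              nrow(x$records), sum(x$records$inside_villi)))
  invisible(x)
}
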