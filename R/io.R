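#' Write and read slide images
#'
#' Slides are stored as 8-bit RGB TIFF or PNG (by file extension) with a
#' sidecar JSON (`<path>.json`) carrying the pixel size and id.
#'
#' @param image a [slide_image()].
#' @param path output path ending in .tif/.tiff or .png.
#' @return the path, invisibly.
#' @export
write_slide <- function(image, path) {
  abort_if(!inherits(image, "slide_image"), "`image` must be a slide_image")
  arr <- image$rgb / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(arr, path)
  } else stop("unsupported image extension: ", ext, call. = FALSE)
  jsonlite::write_json(list(pixel_size_um = image$pixel_size_um, id = image$id),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_slide
#' @param pixel_size_um pixel size override; taken from the sidecar JSON
#'   when `NULL`.
#' @export
read_slide <- function(path, pixel_size_um = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else stop("unsupported image extension: ", ext, call. = FALSE)
  id <- tools::file_path_sans_ext(basename(path))
  if (is.null(pixel_size_um)) {
    sidecar <- paste0(path, ".json")
    abort_if(!file.exists(sidecar),
             "no pixel size given and no sidecar JSON found")
    meta <- jsonlite::read_json(sidecar)
    pixel_size_um <- as.numeric(meta$pixel_size_um)
    id <- meta$id %||% id
  }
  slide_image(round(arr * 255), as.numeric(pixel_size_um), id = id)
}

#' Write and read label masks as single-channel PNG
#'
#' Label codes (see [label_codes()]) are stored directly as 8-bit gray
#' levels with a sidecar JSON recording the pixel size and code table.
#'
#' @param mask a [label_mask()].
#' @param path output .png path.
#' @return the path, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  abort_if(!inherits(mask, "label_mask"), "`mask` must be a label_mask")
  png::writePNG(mask$labels / 255, path)
  jsonlite::write_json(list(pixel_size_um = mask$pixel_size_um,
                            codes = as.list(label_codes())),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  sidecar <- paste0(path, ".json")
  abort_if(!file.exists(sidecar), "label mask sidecar JSON not found")
  meta <- jsonlite::read_json(sidecar)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  label_mask(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)),
             as.numeric(meta$pixel_size_um))
}

#' Write vessel instances as a 16-bit label TIFF plus a CSV of records
#'
#' @param vessels a [vessel_instances()].
#' @param tiff_path output label TIFF (instance ids as 16-bit gray).
#' @param csv_path output CSV of per-instance records.
#' @return invisibly, the two paths.
#' @export
write_vessel_instances <- function(vessels, tiff_path, csv_path) {
  abort_if(!inherits(vessels, "vessel_instances"),
           "`vessels` must be a vessel_instances")
  abort_if(max(vessels$instance_labels) > 65535, "more than 65535 instances")
  tiff::writeTIFF(vessels$instance_labels / 65535, tiff_path,
                  bits.per.sample = 16L)
  utils::write.csv(vessels$records, csv_path, row.names = FALSE)
  invisible(c(tiff_path, csv_path))
}

#' Read exclusion polygons from GeoJSON
#'
#' Accepts a GeoJSON FeatureCollection (or single Polygon geometry) in
#' pixel coordinates; GeoJSON (x, y) positions are mapped to (row = y,
#' col = x).
#'
#' @param path GeoJSON file path.
#' @return list of n x 2 (row, col) matrices.
#' @export
read_exclusion_polygons <- function(path) {
  g <- jsonlite::read_json(path)
  geoms <- if (identical(g$type, "FeatureCollection")) {
    lapply(g$features, `[[`, "geometry")
  } else list(g)
  lapply(geoms, function(geom) {
    abort_if(!identical(geom$type, "Polygon"), "only Polygon geometries supported")
    ring <- geom$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(p) {
      c(as.numeric(p[[2]]), as.numeric(p[[1]]))
    }))
    colnames(xy) <- c("row", "col")
    xy
  })
}
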