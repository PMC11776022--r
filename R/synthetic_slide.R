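#' Parameters of the synthetic CD34 slide generator
#'
#' Defaults reproduce the cohort-mean conditions of the study the package
#' models: villous tissue occupying 49.7% of the section, ~1324 vessel
#' cross-sections per mm^2 of villous area, and vessel radii of 4-8 um
#' (uniform), which together imply a vessel area fraction near 15.5% of
#' the villous area. Pixel size defaults to 2 um/px, a desk-scale stand-in
#' for ~0.5 um/px 20x scans.
#'
#' @param width_px,height_px canvas size in pixels.
#' @param pixel_size_um physical pixel edge (um).
#' @param villous_fraction target fraction of the canvas occupied by villi.
#' @param fibrin_fraction target fraction occupied by fibrin deposits.
#' @param artifact_fraction target fraction occupied by staining artifacts
#'   (dark speckles placed in the intervillous space).
#' @param vessel_density_per_mm2 ground-truth vessel cross-sections per
#'   mm^2 villous area (Poisson mean).
#' @param vessel_radius_um_range min/max vessel radius in um (uniform draw).
#' @param vessel_touch_fraction fraction of vessels allowed to touch or
#'   slightly overlap an earlier vessel (exercises watershed separation).
#' @param stain_intensity_scale multiplier on the AEC (CD34) chromogen
#'   concentration; values well below 1 emulate weak staining.
#' @param villous_scale_um,fibrin_scale_um Gaussian correlation length of
#'   the random fields that shape villous and fibrin blobs.
#' @param seed integer seed; rendering is a pure function of
#'   (params, seed).
#' @return validated object of class `slide_params`.
#' @export
slide_params <- function(width_px = 1024L, height_px = 1024L,
                         pixel_size_um = 2,
                         villous_fraction = 0.497,
                         fibrin_fraction = 0.03,
                         artifact_fraction = 0.01,
                         vessel_density_per_mm2 = 1324,
                         vessel_radius_um_range = c(4, 8),
                         vessel_touch_fraction = 0.10,
                         stain_intensity_scale = 1,
                         villous_scale_um = 50,
                         fibrin_scale_um = 25,
                         seed = 1L) {
  check_scalar_number(width_px, "width_px", min = 8)
  check_scalar_number(height_px, "height_px", min = 8)
  check_scalar_number(pixel_size_um, "pixel_size_um", min = 1e-3)
  check_scalar_number(villous_fraction, "villous_fraction", 0, 1)
  check_scalar_number(fibrin_fraction, "fibrin_fraction", 0, 1)
  check_scalar_number(artifact_fraction, "artifact_fraction", 0, 1)
  check_scalar_number(vessel_density_per_mm2, "vessel_density_per_mm2", min = 0)
  check_scalar_number(vessel_touch_fraction, "vessel_touch_fraction", 0, 1)
  check_scalar_number(stain_intensity_scale, "stain_intensity_scale", min = 0)
  abort_if(villous_fraction + fibrin_fraction > 1,
           "villous_fraction + fibrin_fraction must not exceed 1")
  abort_if(length(vessel_radius_um_range) != 2L ||
             any(vessel_radius_um_range <= 0) ||
             vessel_radius_um_range[1] > vessel_radius_um_range[2],
           "`vessel_radius_um_range` must be an increasing pair of positive reals")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um,
                 villous_fraction = villous_fraction,
                 fibrin_fraction = fibrin_fraction,
                 artifact_fraction = artifact_fraction,
                 vessel_density_per_mm2 = vessel_density_per_mm2,
                 vessel_radius_um_range = vessel_radius_um_range,
                 vessel_touch_fraction = vessel_touch_fraction,
                 stain_intensity_scale = stain_intensity_scale,
                 villous_scale_um = villous_scale_um,
                 fibrin_scale_um = fibrin_scale_um,
                 seed = as.integer(seed)),
            class = "slide_params")
}

# Smooth Gaussian random field: iid normals blurred to correlation
# length `scale_um`; thresholding its upper quantile yields irregular
# blob-shaped regions with an exactly controlled pixel fraction.
smooth_field <- function(nr, nc, sigma_px) {
  f <- matrix(stats::rnorm(nr * nc), nr, nc)
  # the Gaussian brush must fit inside the canvas; cap the correlation
  # length on very small canvases
  sigma_px <- min(max(sigma_px, 1), (min(nr, nc) - 3) / 7)
  as_matrix_img(EBImage::gblur(f, sigma = sigma_px))
}

# Reference stain concentrations used for rendering each class.
# Villi: hematoxylin-dominated blue-purple; vessels: strong AEC red on a
# nuclear background; fibrin: faint pink (weak AEC + trace hematoxylin).
render_concentrations <- function() {
  list(villi  = c(h = 0.60, a = 0.00),
       vessel = c(h = 0.20, a = 0.90),
       fibrin = c(h = 0.05, a = 0.15))
}

#' Generate a synthetic CD34-stained placental section with ground truth
#'
#' Villous and fibrin regions are carved from thresholded smooth random
#' fields (exact pixel-fraction control), vessels are placed as discs
#' strictly inside villi with a Poisson count proportional to villous
#' area, artifacts as dark speckles in the intervillous space, and the
#' image is rendered through the Beer-Lambert model with the configured
#' hematoxylin/AEC stain vectors plus mild sensor noise.
#'
#' @param params a [slide_params()] object.
#' @param id slide identifier.
#' @return list with `image` (a [slide_image()]) and `truth`: a list of
#'   `label_mask` ([label_mask()]), `vessel_mask` (logical matrix, subset
#'   of villi), `vessel_count`, `vessel_centers` (px), and `class_counts`
#'   (named integer vector summing to the canvas size).
#' @export
generate_slide <- function(params, id = "synthetic") {
  abort_if(!inherits(params, "slide_params"), "`params` must come from slide_params()")
  with_seed(params$seed, {
    nr <- params$height_px; nc <- params$width_px
    px_um <- params$pixel_size_um
    codes <- label_codes()

    villi <- top_fraction_mask(smooth_field(nr, nc, params$villous_scale_um / px_um),
                               params$villous_fraction)
    fibrin <- top_fraction_mask(smooth_field(nr, nc, params$fibrin_scale_um / px_um),
                                params$fibrin_fraction, eligible = !villi)

    labels <- matrix(codes[["background"]], nr, nc)
    labels[villi] <- codes[["villi"]]
    labels[fibrin] <- codes[["fibrin"]]

    # Artifact speckles: small discs restricted to intervillous pixels.
    n_art_target <- round(params$artifact_fraction * nr * nc)
    if (n_art_target > 0) {
      bg_idx <- which(labels == codes[["background"]])
      n_art <- 0L; guard <- 0L
      while (n_art < n_art_target && guard < 20000L && length(bg_idx) > 0) {
        guard <- guard + 1L
        ctr <- sample(bg_idx, 1L)
        cy <- (ctr - 1L) %% nr + 1L; cx <- (ctr - 1L) %/% nr + 1L
        ii <- disc_indices(nr, nc, cy, cx, stats::runif(1, 2, 6))
        ii <- ii[labels[ii] == codes[["background"]]]
        labels[ii] <- codes[["artifact"]]
        n_art <- n_art + length(ii)
      }
    }

    # Vessel placement: Poisson count over villous area; discs fit fully
    # inside villi (distance transform check); a configurable fraction may
    # touch a neighbour to exercise the downstream watershed split.
    villous_mm2 <- sum(villi) * px_um^2 / 1e6
    n_vessels <- if (params$vessel_density_per_mm2 > 0 && villous_mm2 > 0) {
      stats::rpois(1L, params$vessel_density_per_mm2 * villous_mm2)
    } else 0L
    vessel_mask <- matrix(FALSE, nr, nc)
    vy <- numeric(0); vx <- numeric(0); vr <- numeric(0)
    if (n_vessels > 0) {
      dmap <- as_matrix_img(EBImage::distmap(villi * 1))
      vidx <- which(villi)
      dv <- dmap[vidx]
      ord <- order(dv)                      # ascending distance to border
      vidx <- vidx[ord]; dv <- dv[ord]
      r_rng <- params$vessel_radius_um_range / px_um
      placed <- 0L
      for (i in seq_len(n_vessels)) {
        r <- stats::runif(1, r_rng[1], r_rng[2])
        lo <- findInterval(r + 0.5, dv) + 1L   # first index with clearance
        if (lo > length(vidx)) next
        allow_touch <- stats::runif(1) < params$vessel_touch_fraction
        ok <- FALSE
        for (try in 1:25) {
          ctr <- vidx[sample.int(length(vidx) - lo + 1L, 1L) + lo - 1L]
          cy <- (ctr - 1L) %% nr + 1L; cx <- (ctr - 1L) %/% nr + 1L
          if (placed == 0L) { ok <- TRUE; break }
          d <- sqrt((cy - vy[seq_len(placed)])^2 + (cx - vx[seq_len(placed)])^2)
          sep <- r + vr[seq_len(placed)]
          if (allow_touch) {
            if (all(d >= 0.85 * sep)) { ok <- TRUE; break }
          } else if (all(d >= sep + 1)) { ok <- TRUE; break }
        }
        if (!ok) next
        placed <- placed + 1L
        vy[placed] <- cy; vx[placed] <- cx; vr[placed] <- r
        vessel_mask[disc_indices(nr, nc, cy, cx, r)] <- TRUE
      }
      length(vy) <- placed; length(vx) <- placed; length(vr) <- placed
      n_vessels <- placed
    }

    # Render through the stain model; vessels sit on villous tissue.
    conc <- render_concentrations()
    sv <- stain_vectors()
    rgb <- array(250, dim = c(nr, nc, 3L))  # near-white intervillous space
    paint <- function(sel, h, a) {
      if (!any(sel)) return()
      cols <- render_stain_rgb(h, a * params$stain_intensity_scale, stains = sv)
      for (ch in 1:3) {
        plane <- rgb[, , ch]; plane[sel] <- cols[1, ch]; rgb[, , ch] <<- plane
      }
    }
    paint(labels == codes[["villi"]] & !vessel_mask,
          conc$villi["h"], conc$villi["a"])
    paint(vessel_mask, conc$vessel["h"], conc$vessel["a"])
    paint(labels == codes[["fibrin"]], conc$fibrin["h"], conc$fibrin["a"])
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[labels == codes[["artifact"]]] <- 60
      rgb[, , ch] <- plane
    }
    noise <- array(stats::rnorm(nr * nc * 3, sd = 2), dim = dim(rgb))
    rgb <- round(pmin(pmax(rgb + noise, 0), 255))

    class_counts <- vapply(names(codes), function(nm) sum(labels == codes[[nm]]),
                           integer(1))
    list(image = slide_image(rgb, px_um, id = id),
         truth = list(label_mask = label_mask(labels, px_um),
                      vessel_mask = vessel_mask,
                      vessel_count = n_vessels,
                      vessel_centers = cbind(row = vy, col = vx, radius_px = vr),
                      class_counts = class_counts))
  })
}
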