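#' Circular measurement region
#'
#' @param center numeric pair (row, col) in pixel coordinates.
#' @param diameter_um circle diameter in micrometres (default 1000, i.e.
#'   the 1-mm regions placed on villous structures).
#' @return object of class `region_spec`.
#' @export
region_spec <- function(center, diameter_um = 1000) {
  abort_if(length(center) != 2 || !is.numeric(center),
           "`center` must be a numeric (row, col) pair")
  check_scalar_number(diameter_um, "diameter_um", min = 1e-6)
  structure(list(center = as.numeric(center), diameter_um = diameter_um),
            class = "region_spec")
}

region_mask <- function(labels_dim, region, pixel_size_um) {
  r_px <- region$diameter_um / 2 / pixel_size_um
  m <- matrix(FALSE, labels_dim[1], labels_dim[2])
  m[disc_indices(labels_dim[1], labels_dim[2],
                 region$center[1], region$center[2], r_px)] <- TRUE
  m
}

#' Normalized stereology metrics of a section or region
#'
#' Computes the three normalized structural outcomes: density of villi
#' (%) = 100 x villi / (villi + fibrin + intervillous) pixels; vessel
#' area (%) = 100 x vessel pixels within villi / villi pixels; vessel
#' count per mm^2 = number of instances whose centroid lies on a
#' villi-class pixel (and inside the region, if one is given), divided by
#' the villous area in mm^2. Excluded pixels are removed from every term.
#' With `legend_denominator = TRUE` the density denominator omits fibrin
#' (villi / (villi + intervillous)).
#'
#' @param labels a [label_mask()].
#' @param vessels a [vessel_instances()] or `NULL` (vessel metrics 0).
#' @param region a [region_spec()] restricting every term to the circle,
#'   or `NULL` for the whole section.
#' @param legend_denominator drop fibrin from the density denominator.
#' @return data.frame of class `stereology_metrics` with columns `scope`,
#'   `density_villi_pct`, `vessel_area_pct`, `vessel_count_per_mm2`,
#'   `villous_area_mm2`.
#' @export
compute_metrics <- function(labels, vessels = NULL, region = NULL,
                            legend_denominator = FALSE) {
  abort_if(!inherits(labels, "label_mask"), "`labels` must be a label_mask")
  codes <- label_codes()
  lab <- labels$labels
  in_scope <- if (is.null(region)) {
    matrix(TRUE, nrow(lab), ncol(lab))
  } else {
    region_mask(dim(lab), region, labels$pixel_size_um)
  }
  in_scope <- in_scope & lab != codes[["excluded"]]
  n_villi <- sum(lab == codes[["villi"]] & in_scope)
  abort_if(n_villi == 0, "no villous tissue")
  n_fibrin <- sum(lab == codes[["fibrin"]] & in_scope)
  n_inter <- sum(lab == codes[["background"]] & in_scope)
  denom <- n_villi + n_inter + if (legend_denominator) 0 else n_fibrin
  px_area_mm2 <- labels$pixel_size_um^2 / 1e6
  villous_mm2 <- n_villi * px_area_mm2

  if (is.null(vessels) || nrow(vessels$records) == 0) {
    n_vessel_px <- 0; n_count <- 0
  } else {
    vmask <- vessels$instance_labels > 0
    n_vessel_px <- sum(vmask & lab == codes[["villi"]] & in_scope)
    rec <- vessels$records
    ci <- cbind(pmin(pmax(round(rec$centroid_row), 1), nrow(lab)),
                pmin(pmax(round(rec$centroid_col), 1), ncol(lab)))
    counted <- rec$inside_villi & in_scope[ci]
    n_count <- sum(counted)
  }
  out <- data.frame(scope = if (is.null(region)) "whole_section" else "region",
                    density_villi_pct = 100 * n_villi / denom,
                    vessel_area_pct = 100 * n_vessel_px / n_villi,
                    vessel_count_per_mm2 = n_count / villous_mm2,
                    villous_area_mm2 = villous_mm2,
                    stringsAsFactors = FALSE)
  class(out) <- c("stereology_metrics", class(out))
  out
}

#' Place circular regions on villous structures
#'
#' Greedy placement over a seeded candidate grid: candidate centres are a
#' regular grid (randomly offset by the seed) of points whose circle fits
#' inside the image; the villous pixel fraction of every candidate circle
#' is computed by convolution, and circles are picked greedily by
#' descending villous fraction subject to not overlapping an already
#' picked circle. Only candidates with villous fraction >= `floor` are
#' eligible.
#'
#' @param labels a [label_mask()].
#' @param k number of circles wanted (returns `min(k, feasible)`).
#' @param diameter_um circle diameter (default 1000 um).
#' @param seed integer seed for the grid offset.
#' @param floor minimum villous fraction of a returned circle
#'   (default 0.30).
#' @param stride_px candidate grid stride; 1 evaluates every valid
#'   centre.
#' @return list of [region_spec()] objects.
#' @export
place_regions <- function(labels, k = 3L, diameter_um = 1000, seed = 1L,
                          floor = 0.30, stride_px = NULL) {
  abort_if(!inherits(labels, "label_mask"), "`labels` must be a label_mask")
  abort_if(k < 1, "`k` must be >= 1")
  codes <- label_codes()
  lab <- labels$labels
  r_px <- diameter_um / 2 / labels$pixel_size_um
  nr <- nrow(lab); nc <- ncol(lab)
  abort_if(2 * r_px + 1 > min(nr, nc), "image smaller than the circle diameter")
  stride_px <- stride_px %||% max(1L, round(r_px / 8))

  villi <- (lab == codes[["villi"]]) * 1
  kern_r <- ceiling(r_px)
  kidx <- outer((-kern_r:kern_r)^2, (-kern_r:kern_r)^2, "+") <= r_px^2
  kern <- kidx / sum(kidx)
  frac <- as_matrix_img(EBImage::filter2(villi, kern))

  off <- with_seed(seed, sample.int(stride_px, 2, replace = TRUE))
  lo_r <- ceiling(r_px) + 1L; hi_r <- nr - ceiling(r_px)
  lo_c <- ceiling(r_px) + 1L; hi_c <- nc - ceiling(r_px)
  cand_r <- seq(lo_r + (off[1] %% stride_px), hi_r, by = stride_px)
  cand_c <- seq(lo_c + (off[2] %% stride_px), hi_c, by = stride_px)
  cand <- expand.grid(row = cand_r, col = cand_c)
  cand$frac <- frac[cbind(cand$row, cand$col)]
  cand <- cand[cand$frac >= floor, , drop = FALSE]
  abort_if(nrow(cand) == 0, "insufficient villous tissue")
  cand <- cand[order(-cand$frac, cand$row, cand$col), , drop = FALSE]

  picked <- list()
  for (i in seq_len(nrow(cand))) {
    if (length(picked) >= k) break
    p <- cand[i, ]
    ok <- all(vapply(picked, function(q) {
      sqrt((p$row - q$center[1])^2 + (p$col - q$center[2])^2) >= 2 * r_px
    }, logical(1)))
    if (ok) picked[[length(picked) + 1L]] <- region_spec(c(p$row, p$col), diameter_um)
  }
  picked
}
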