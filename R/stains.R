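#' Stain absorbance vectors for colour deconvolution
#'
#' Unit RGB optical-density vectors for hematoxylin (nuclear counterstain)
#' and the AEC chromogen (red peroxidase product marking CD34-positive
#' endothelium), after Ruifrok & Johnston's published stain calibrations.
#' A third, residual vector (normalized cross product) completes the basis
#' so the 3x3 deconvolution matrix is invertible.
#'
#' The same vectors drive the synthetic slide renderer and the
#' deconvolution in [extract_stain_channel()], so the forward render is
#' analytically invertible.
#'
#' @return list with unit vectors `hematoxylin`, `aec`, `residual` and the
#'   3x3 matrix `M` whose columns are those vectors.
#' @export
stain_vectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  a <- c(0.2743, 0.6796, 0.6803)
  h <- h / sqrt(sum(h^2))
  a <- a / sqrt(sum(a^2))
  r <- c(h[2] * a[3] - h[3] * a[2],
         h[3] * a[1] - h[1] * a[3],
         h[1] * a[2] - h[2] * a[1])
  r <- r / sqrt(sum(r^2))
  M <- cbind(hematoxylin = h, aec = a, residual = r)
  list(hematoxylin = h, aec = a, residual = r, M = M)
}

#' Forward Beer-Lambert render of stain concentrations to RGB
#'
#' Transmitted intensity per channel is `255 * 10^(-M %*% c)` for
#' concentration vector `c` in the stain basis. Used by the synthetic
#' slide generator; the continuous (unquantized) values it returns are
#' rounded to 8-bit only at the final rendering step.
#'
#' @param hematoxylin,aec,residual concentration (absorbance) per stain;
#'   vectors are recycled to a common length.
#' @param stains stain basis from [stain_vectors()].
#' @return numeric matrix with one row per pixel and columns R, G, B on
#'   the continuous \[0, 255\] scale.
#' @export
render_stain_rgb <- function(hematoxylin, aec = 0, residual = 0,
                             stains = stain_vectors()) {
  n <- max(length(hematoxylin), length(aec), length(residual))
  conc <- rbind(rep_len(hematoxylin, n), rep_len(aec, n), rep_len(residual, n))
  od <- stains$M %*% conc                  # 3 x n channel optical densities
  t(255 * 10^(-od))
}

#' Colour deconvolution into stain concentration fields
#'
#' Converts RGB to per-channel optical density `-log10(I/255)` and solves
#' the stain mixing model for per-pixel concentrations in the configured
#' basis. White pixels map to zero absorbance.
#'
#' @param rgb array (rows, cols, 3), values in \[0, 255\] (continuous
#'   values accepted).
#' @param stains stain basis from [stain_vectors()].
#' @return list of matrices `hematoxylin`, `aec`, `residual` (same shape
#'   as the image plane); values can be slightly negative from noise and
#'   are not clipped here.
#' @export
deconvolve_stains <- function(rgb, stains = stain_vectors()) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  M <- stains$M
  abort_if(abs(det(M)) < 1e-6, "degenerate stain matrix: vectors are collinear")
  d <- dim(rgb)[1:2]
  I <- pmax(matrix(rgb, ncol = 3L), 1e-4)
  od <- -log10(I / 255)                     # n x 3
  conc <- od %*% t(solve(M))                # n x 3 in stain basis
  list(hematoxylin = matrix(conc[, 1], d[1], d[2]),
       aec         = matrix(conc[, 2], d[1], d[2]),
       residual    = matrix(conc[, 3], d[1], d[2]))
}
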