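# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG state
#'
#' Evaluates `code` with the global RNG seeded to `seed`, restoring the
#' previous `.Random.seed` afterwards so callers never leak RNG state.
#' All stochastic operations in the package flow through an explicit seed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  abort_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
           sprintf("`%s` must be a single finite number", name))
  abort_if(x < min || x > max,
           sprintf("`%s` must be in [%s, %s]", name, min, max))
  invisible(x)
}

#' Pixel luminance on the 8-bit scale
#'
#' Arithmetic mean of the R, G, B channels, rounded half-up to an integer.
#' This is the luminance convention used by the 210 tissue threshold.
#'
#' @param rgb array of dim (rows, cols, 3) with values in \[0, 255\].
#' @return integer matrix of dim (rows, cols).
#' @export
luminance <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  floor((rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3 + 0.5)
}

# Paint a filled disc into a logical/integer matrix, clipped to bounds.
# Returns the linear indices of the disc pixels.
disc_indices <- function(nrow_m, ncol_m, cy, cx, r) {
  ylo <- max(1L, floor(cy - r)); yhi <- min(nrow_m, ceiling(cy + r))
  xlo <- max(1L, floor(cx - r)); xhi <- min(ncol_m, ceiling(cx + r))
  if (ylo > yhi || xlo > xhi) return(integer(0))
  ys <- ylo:yhi; xs <- xlo:xhi
  dy2 <- (ys - cy)^2
  dx2 <- (xs - cx)^2
  inside <- outer(dy2, dx2, "+") <= r^2
  yy <- rep(ys, times = length(xs))[inside]
  xx <- rep(xs, each = length(ys))[inside]
  (xx - 1L) * nrow_m + yy
}

# Exact-fraction threshold of a continuous field: returns a logical matrix
# marking the `fraction` largest values among `eligible` (all if NULL).
top_fraction_mask <- function(field, fraction, eligible = NULL) {
  out <- matrix(FALSE, nrow(field), ncol(field))
  if (fraction <= 0) return(out)
  if (is.null(eligible)) {
    n_take <- round(fraction * length(field))
    if (n_take <= 0) return(out)
    cut <- -sort(-as.vector(field), partial = n_take)[n_take]
    sel <- which(field >= cut)
    out[sel[seq_len(min(n_take, length(sel)))]] <- TRUE
  } else {
    idx <- which(eligible)
    n_take <- round(fraction * length(field))
    n_take <- min(n_take, length(idx))
    if (n_take <= 0) return(out)
    ord <- idx[order(field[idx], decreasing = TRUE)]
    out[ord[seq_len(n_take)]] <- TRUE
  }
  out
}

as_matrix_img <- function(x) {
  if (inherits(x, "Image")) EBImage::imageData(x) else x
}
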