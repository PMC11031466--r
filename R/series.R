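#' Dynamic CT-perfusion series
#'
#' Container for a 4D dynamic contrast CT acquisition: a `(t, z, y, x)` array
#' of Hounsfield units on a uniform time grid, together with the sampling
#' interval and voxel geometry. The hemisphere convention is a midline split
#' along the x axis (last array dimension).
#'
#' @param data 4D numeric array with dimensions `(t, z, y, x)`; all finite.
#' @param dt Sampling interval between frames (s, > 0).
#' @param voxel_mm Numeric length-3 vector of voxel edge lengths (mm) in
#'   `(z, y, x)` order.
#' @param baseline_subtracted Logical; whether `data` already holds
#'   baseline-subtracted contrast enhancement rather than raw HU.
#'
#' @return An object of class `ctp_series` with elements `data`, `dt`,
#'   `time` (s, starting at 0), `voxel_mm` and `baseline_subtracted`.
#' @export
#' @examples
#' s <- ctp_series(array(0, c(5, 2, 4, 4)), dt = 1.5, voxel_mm = c(10, 4, 4))
#' n_frames(s)
ctp_series <- function(data, dt, voxel_mm, baseline_subtracted = FALSE) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    abort("`data` must be a 4D (t, z, y, x) array")
  }
  if (!all(is.finite(data))) abort("`data` must be finite everywhere")
  assert_scalar_number(dt, "dt", lower = 0, strict = TRUE)
  if (length(voxel_mm) != 3L || any(!is.finite(voxel_mm)) || any(voxel_mm <= 0)) {
    abort("`voxel_mm` must be three positive edge lengths (z, y, x)")
  }
  nt <- dim(data)[1L]
  structure(
    list(
      data = data,
      dt = dt,
      time = (seq_len(nt) - 1) * dt,
      voxel_mm = as.numeric(voxel_mm),
      baseline_subtracted = isTRUE(baseline_subtracted)
    ),
    class = "ctp_series"
  )
}

#' @export
print.ctp_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ctp_series> %d frames @ dt = %g s (window %g s), grid %d x %d x %d (z,y,x), voxel %g x %g x %g mm%s\n",
    d[1L], x$dt, (d[1L] - 1) * x$dt, d[2L], d[3L], d[4L],
    x$voxel_mm[1L], x$voxel_mm[2L], x$voxel_mm[3L],
    if (x$baseline_subtracted) ", baseline-subtracted" else ""
  ))
  invisible(x)
}

#' @export
dim.ctp_series <- function(x) dim(x$data)

#' Number of frames in a series
#' @param series A [ctp_series()].
#' @return Integer frame count.
#' @export
n_frames <- function(series) dim(series$data)[1L]

#' Voxel volume in millilitres
#' @param x A [ctp_series()], a voxel-size vector (mm), or a `ctp_maps` object.
#' @return Voxel volume in mL.
#' @export
voxel_volume_ml <- function(x) {
  v <- if (is.numeric(x)) x else x$voxel_mm
  prod(v) / 1000
}

#' Hemisphere masks for a series grid
#'
#' Splits the grid at the x midline (last dimension). With an even number of
#' columns the two hemispheres are equal; with an odd number the midline
#' column is assigned to neither.
#'
#' @param series A [ctp_series()] or a length-3 `(z, y, x)` dimension vector.
#' @return A list of two logical `(z, y, x)` arrays, `left` and `right`.
#' @export
hemisphere_masks <- function(series) {
  d <- if (is.numeric(series)) series else dim(series$data)[2:4]
  xi <- array(rep(seq_len(d[3L]), each = d[1L] * d[2L]), dim = d)
  half <- d[3L] / 2
  list(left = xi <= floor(half), right = xi > ceiling(half))
}

## Series data as an (n_frames x n_voxel) matrix, optionally masked.
series_matrix <- function(series, mask = NULL) {
  d <- dim(series$data)
  m <- matrix(series$data, nrow = d[1L])
  if (!is.null(mask)) m <- m[, as.logical(mask), drop = FALSE]
  m
}
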