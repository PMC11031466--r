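#' Simulate reduced temporal resolution by frame decimation
#'
#' Retains frames at indices 0, `factor`, `2 * factor`, ... (0-based), i.e.
#' the series always starts at its first datapoint and the effective sampling
#' interval becomes `factor * dt`. The retained frame count is
#' `ceiling(n / factor)`; the last available frame is not necessarily kept.
#'
#' @param series A [ctp_series()].
#' @param factor Integer subsampling factor (>= 1); 1 returns the series
#'   unchanged.
#' @return A [ctp_series()] on the coarser grid.
#' @export
#' @examples
#' s <- ctp_series(array(rnorm(27 * 8), c(27, 2, 2, 2)), 1.5, c(10, 4, 4))
#' n_frames(decimate(s, 2))  # 14
decimate <- function(series, factor) {
  stopifnot(inherits(series, "ctp_series"))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor < 1 || factor != round(factor)) {
    abort("`factor` must be a single integer >= 1")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(series)
  idx <- seq(1L, n_frames(series), by = factor)
  out <- ctp_series(series$data[idx, , , , drop = FALSE],
                    dt = series$dt * factor,
                    voxel_mm = series$voxel_mm,
                    baseline_subtracted = series$baseline_subtracted)
  out
}

#' Sampling scheme descriptor
#'
#' @param n_frames Number of frames in the reference series.
#' @param factor Integer subsampling factor.
#' @param dt Reference sampling interval (s).
#' @return A tibble row with the factor, effective interval, retained frame
#'   count and retained (1-based) indices as a list-column.
#' @export
sampling_scheme <- function(n_frames, factor, dt = 1.5) {
  idx <- seq(1L, n_frames, by = as.integer(factor))
  tibble::tibble(
    factor = as.integer(factor),
    effective_dt = dt * factor,
    n_retained = length(idx),
    retained_indices = list(idx)
  )
}
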