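#' Quality-control thresholds
#'
#' The three automated rules applied to every acquisition, plus a stricter
#' "uninterpretable" rule standing in for visual exclusion of fatally flawed
#' scans (which cannot be automated faithfully).
#'
#' @param peak_fraction Flag a truncated bolus when the mean-brain bolus
#'   peak occurs later than this fraction of the acquisition window.
#' @param peak_height_hu Flag low contrast-to-noise when the mean-brain
#'   bolus peak is smaller than this height (HU).
#' @param motion_min Flag motion when the minimum frame-to-first-frame
#'   correlation falls below this value.
#' @param uninterpretable_motion Minimum motion index below which the case
#'   is uninterpretable (fatal motion); a zero-variance bolus is likewise
#'   uninterpretable.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(peak_fraction = 0.9, peak_height_hu = 8,
                          motion_min = 0.7, uninterpretable_motion = 0.3) {
  structure(list(peak_fraction = peak_fraction, peak_height_hu = peak_height_hu,
                 motion_min = motion_min,
                 uninterpretable_motion = uninterpretable_motion),
            class = "qc_thresholds")
}

#' Mean contrast bolus curve over a mask
#'
#' @param series A [ctp_series()] (typically baseline-subtracted).
#' @param mask Logical `(z, y, x)` array; must be non-empty.
#' @return Frame-wise mean curve.
#' @export
mean_bolus_curve <- function(series, mask) {
  stopifnot(inherits(series, "ctp_series"))
  if (is.null(mask) || !any(mask)) abort("`mask` is empty")
  rowMeans(series_matrix(series, mask))
}

#' Per-frame motion index
#'
#' Pearson correlation of each frame's voxel vector (within the mask)
#' against the first frame; the first frame's value is 1 by definition.
#' Correlation is invariant to global HU offsets. A zero-variance frame
#' yields `NA` (and triggers the motion flag in [evaluate_qc()]).
#'
#' @param series A [ctp_series()] with at least 2 frames.
#' @param mask Optional logical `(z, y, x)` array; default uses all voxels.
#' @return Numeric vector of correlations, one per frame.
#' @export
motion_index <- function(series, mask = NULL) {
  stopifnot(inherits(series, "ctp_series"))
  if (n_frames(series) < 2L) abort("motion index needs >= 2 frames")
  m <- series_matrix(series, mask)
  ref <- m[1L, ]
  v0 <- stats::sd(ref)
  vapply(seq_len(nrow(m)), function(f) {
    if (f == 1L) return(1)
    vf <- stats::sd(m[f, ])
    if (!is.finite(v0) || !is.finite(vf) || v0 == 0 || vf == 0) return(NA_real_)
    stats::cor(ref, m[f, ])
  }, numeric(1))
}

#' Automated quality control of a dynamic series
#'
#' Evaluates the mean contrast bolus curve and the motion index against the
#' thresholds of [qc_thresholds()]: a bolus peaking later than 90% of the
#' acquisition window flags truncation, a peak below 8 HU flags low
#' contrast-to-noise, and a minimum motion index below 0.7 flags motion.
#' Scan quality is `"high"` iff no flag is set. The acquisition window is
#' `(n_frames - 1) * dt` of the series being evaluated, so decimated series
#' are judged on their own grid.
#'
#' @param series A [ctp_series()] (raw HU or baseline-subtracted).
#' @param brain_mask Logical `(z, y, x)` parenchyma mask.
#' @param thresholds A [qc_thresholds()].
#' @param n_baseline Passed to [baseline_subtract()] when needed.
#' @return A list of class `ctp_qc`: `peak_position_fraction`, `peak_height`,
#'   `motion_index` (vector) and `motion_index_min`, `flags` (logical
#'   `truncated_bolus`, `low_cnr`, `motion`), `quality_class`
#'   (`"high"`/`"impaired"`) and `uninterpretable`.
#' @export
evaluate_qc <- function(series, brain_mask, thresholds = qc_thresholds(),
                        n_baseline = NULL) {
  stopifnot(inherits(series, "ctp_series"))
  raw <- series
  if (!series$baseline_subtracted) {
    series <- baseline_subtract(series, n_baseline)
  }
  nt <- n_frames(series)
  window <- (nt - 1) * series$dt
  curve <- mean_bolus_curve(series, brain_mask)
  peak_idx <- which.max(curve)
  peak_height <- curve[peak_idx]
  peak_fraction <- (peak_idx - 1) * series$dt / window
  mi <- motion_index(raw, brain_mask)
  mi_min <- suppressWarnings(min(mi, na.rm = TRUE))
  zero_var <- any(is.na(mi)) || !is.finite(mi_min)

  flags <- list(
    truncated_bolus = peak_fraction > thresholds$peak_fraction,
    low_cnr = peak_height < thresholds$peak_height_hu,
    motion = zero_var || mi_min < thresholds$motion_min
  )
  uninterpretable <- (stats::sd(curve) == 0) ||
    zero_var || mi_min < thresholds$uninterpretable_motion
  structure(
    list(peak_position_fraction = peak_fraction,
         peak_height = peak_height,
         motion_index = mi,
         motion_index_min = if (zero_var) NA_real_ else mi_min,
         flags = flags,
         quality_class = if (any(unlist(flags))) "impaired" else "high",
         uninterpretable = uninterpretable,
         thresholds = thresholds),
    class = "ctp_qc"
  )
}

#' @export
print.ctp_qc <- function(x, ...) {
  fl <- names(x$flags)[unlist(x$flags)]
  cat(sprintf(
    "<ctp_qc> quality %s%s | peak %.1f HU at %.0f%% of window, min motion index %.2f\n",
    x$quality_class,
    if (length(fl)) paste0(" [", paste(fl, collapse = ", "), "]") else "",
    x$peak_height, 100 * x$peak_position_fraction,
    x$motion_index_min %||% NA_real_
  ))
  invisible(x)
}

#' @export
tidy.ctp_qc <- function(x, ...) {
  tibble::tibble(
    peak_position_fraction = x$peak_position_fraction,
    peak_height_hu = x$peak_height,
    motion_index_min = x$motion_index_min,
    flag_truncated_bolus = x$flags$truncated_bolus,
    flag_low_cnr = x$flags$low_cnr,
    flag_motion = x$flags$motion,
    quality_class = x$quality_class,
    uninterpretable = x$uninterpretable
  )
}
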