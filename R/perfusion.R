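#' Deconvolution configuration
#'
#' @param lambda_rel Tikhonov regularization strength as a fraction of the
#'   largest singular value of the convolution operator (0 <= lambda_rel < 1).
#'   The default 0.10 is the strongest regularization that still recovers
#'   noiseless CBF ratios within 5% and Tmax within one sample interval.
#' @param padding Zero-padding factor (>= 2) for the circulant embedding of
#'   the AIF; delay-preserving, so Tmax measures arrival delay.
#' @param n_baseline Number of pre-contrast frames for baseline subtraction;
#'   `NULL` estimates it from the mean bolus curve (minimum 2).
#' @param smooth_fwhm_vox FWHM (voxels) of the optional 3D Gaussian
#'   pre-smoothing applied to each frame; 0 disables.
#' @param penalty Tikhonov penalty: `"identity"` (default) or
#'   `"first_derivative"`.
#' @return A list of class `deconv_config`.
#' @export
deconv_config <- function(lambda_rel = 0.10, padding = 2, n_baseline = NULL,
                          smooth_fwhm_vox = 1,
                          penalty = c("identity", "first_derivative")) {
  penalty <- match.arg(penalty)
  assert_scalar_number(lambda_rel, "lambda_rel", lower = 0)
  if (lambda_rel >= 1) abort("`lambda_rel` must be < 1")
  assert_scalar_number(padding, "padding", lower = 2)
  structure(list(lambda_rel = lambda_rel, padding = padding,
                 n_baseline = n_baseline, smooth_fwhm_vox = smooth_fwhm_vox,
                 penalty = penalty),
            class = "deconv_config")
}

## Estimate the number of pre-contrast frames from the mean curve:
## frames strictly before the first 10%-of-peak enhancement, minimum 2.
estimate_n_baseline <- function(series) {
  d <- dim(series$data)
  m <- matrix(series$data, nrow = d[1L])
  keep <- m[1L, ] > 10  # tissue, not air
  if (!any(keep)) keep <- rep(TRUE, ncol(m))
  mc <- rowMeans(m[, keep, drop = FALSE])
  thr <- min(mc) + 0.1 * (max(mc) - min(mc))
  first <- which(mc >= thr)[1L]
  max(2L, min(first - 1L, d[1L] - 1L))
}

#' Convert a dynamic series to contrast enhancement
#'
#' Subtracts, per voxel, the mean of the first `n_baseline` (pre-contrast)
#' frames. Negative values are retained for tissue curves; set
#' `clip_negative = TRUE` for arterial-input use.
#'
#' @param series A [ctp_series()].
#' @param n_baseline Number of leading frames to average (1 <= n < frames);
#'   `NULL` estimates it from the mean bolus curve.
#' @param clip_negative Clip negative enhancements to zero.
#' @return A baseline-subtracted [ctp_series()].
#' @export
baseline_subtract <- function(series, n_baseline = NULL, clip_negative = FALSE) {
  stopifnot(inherits(series, "ctp_series"))
  nt <- n_frames(series)
  if (is.null(n_baseline)) n_baseline <- estimate_n_baseline(series)
  if (!is.numeric(n_baseline) || n_baseline < 1L || n_baseline >= nt) {
    abort("`n_baseline` must satisfy 1 <= n_baseline < n_frames")
  }
  n_baseline <- as.integer(n_baseline)
  d <- dim(series$data)
  m <- matrix(series$data, nrow = d[1L])
  b <- colMeans(m[seq_len(n_baseline), , drop = FALSE])
  m <- sweep(m, 2L, b)
  if (clip_negative) m[m < 0] <- 0
  out <- ctp_series(array(m, d), series$dt, series$voxel_mm,
                    baseline_subtracted = TRUE)
  out$n_baseline <- n_baseline
  out
}

#' Arterial input function selection
#'
#' Automatic mode scores every candidate voxel by early arrival, high peak
#' and narrow width -- `score = peak / (first_moment * width)` with the width
#' taken as the time the curve spends at or above half its peak -- and
#' averages the `top_k` highest-scoring curves. Manual mode averages the
#' curves of a user-supplied voxel mask. The returned curve is clipped to be
#' non-negative.
#'
#' @param series A baseline-subtracted [ctp_series()] (subtraction with
#'   clipping is applied if needed).
#' @param mask Logical `(z, y, x)` array of candidate voxels (automatic mode).
#' @param manual_mask Optional logical array; when given, its voxels are
#'   averaged directly and scoring is skipped.
#' @param top_k Number of top-scoring candidates averaged in automatic mode.
#' @return A list of class `ctp_aif`: `curve`, `dt`, `voxels` (linear
#'   indices) and `source` (`"automatic"` or `"manual"`).
#' @export
select_aif <- function(series, mask, manual_mask = NULL, top_k = 9L) {
  stopifnot(inherits(series, "ctp_series"))
  if (!series$baseline_subtracted) {
    series <- baseline_subtract(series, clip_negative = TRUE)
  }
  pick <- manual_mask %||% mask
  if (is.null(pick) || !any(pick)) abort("AIF mask is empty")
  if (!is.null(manual_mask)) {
    m <- series_matrix(series, manual_mask)
    curve <- rowMeans(m)
    curve[curve < 0] <- 0
    return(structure(list(curve = curve, dt = series$dt,
                          voxels = which(as.logical(manual_mask)),
                          source = "manual"),
                     class = "ctp_aif"))
  }
  m <- series_matrix(series, mask)
  m[m < 0] <- 0
  t <- series$time
  peak <- apply(m, 2L, max)
  total <- colSums(m)
  ok <- peak > 0 & total > 0
  moment <- colSums(m * t) / pmax(total, .Machine$double.eps)
  width <- colSums(sweep(m, 2L, peak / 2, ">=")) * series$dt
  score <- ifelse(ok, peak / pmax(moment * width, .Machine$double.eps), -Inf)
  k <- min(top_k, sum(ok))
  if (k < 1L) abort("no usable AIF candidate voxels in mask")
  top <- order(score, decreasing = TRUE)[seq_len(k)]
  curve <- rowMeans(m[, top, drop = FALSE])
  curve[curve < 0] <- 0
  structure(list(curve = curve, dt = series$dt,
                 voxels = which(as.logical(mask))[top],
                 source = "automatic"),
            class = "ctp_aif")
}

#' Tikhonov-regularized deconvolution
#'
#' Recovers the residue-flow function `k(t) = CBF * R(t - delay)` from tissue
#' and arterial curves. The discrete convolution operator is the circulant
#' embedding of the AIF, zero-padded to `padding * n` samples so delayed
#' residue peaks stay inside the solution window (Tmax measures delay). The
#' Tikhonov solution `argmin ||A k - c||^2 + lambda^2 ||L k||^2` with
#' `lambda = lambda_rel * sigma_max` is computed spectrally: for a circulant
#' operator the SVD filter factors `sigma_i^2 / (sigma_i^2 + lambda^2)`
#' reduce to Fourier-domain filtering, which is applied to all voxels at
#' once.
#'
#' @param tissue Tissue concentration curve(s): a length-n vector or an
#'   `n x n_voxel` matrix.
#' @param aif A [select_aif()] result or a numeric curve on the same grid.
#' @param dt Sampling interval (s).
#' @param config A [deconv_config()].
#' @return The residue-flow function `k` (units 1/s), truncated to the
#'   acquisition window: a vector or matrix matching `tissue`, with the
#'   regularization parameter in attribute `"lambda"`.
#' @export
deconvolve_tikhonov <- function(tissue, aif, dt, config = deconv_config()) {
  a <- if (inherits(aif, "ctp_aif")) aif$curve else aif
  vec_in <- is.null(dim(tissue))
  tm <- if (vec_in) matrix(tissue, ncol = 1L) else tissue
  n <- nrow(tm)
  if (length(a) != n) abort("`tissue` and `aif` must share the time grid")
  if (all(a == 0)) abort("all-zero AIF: degenerate convolution operator")
  L <- as.integer(ceiling(config$padding * n))
  psi <- stats::fft(c(a, rep(0, L - n))) * dt
  sig <- Mod(psi)
  smax <- max(sig)
  lambda <- config$lambda_rel * smax
  pen <- switch(config$penalty,
    identity = rep(1, L),
    first_derivative = Mod(stats::fft(c(1, -1, rep(0, L - 2L))))^2
  )
  if (lambda == 0 && any(sig < smax * 1e-12)) {
    abort("unregularized deconvolution with a numerically singular operator")
  }
  filt <- Conj(psi) / (sig^2 + lambda^2 * pen)
  tpad <- rbind(tm, matrix(0, L - n, ncol(tm)))
  khat <- stats::mvfft(tpad) * filt
  k <- Re(stats::mvfft(khat, inverse = TRUE)) / L
  k <- k[seq_len(n), , drop = FALSE]
  if (vec_in) k <- drop(k)
  attr(k, "lambda") <- lambda
  k
}

#' Compute relative perfusion maps
#'
#' Runs the full per-voxel pipeline: baseline subtraction, optional 3D
#' Gaussian pre-smoothing, automatic (or supplied) AIF, Tikhonov
#' deconvolution, and map formation. Per voxel: `CBF_raw = max_t k(t)`,
#' `Tmax = dt * argmax_t k(t)` (reported on the acquisition grid, no
#' sub-grid interpolation), `CBV_raw` is the trapezoid area ratio
#' tissue/AIF, and `MTT = CBV_raw / CBF_raw`. CBF and CBV are then expressed
#' as percent of their mean over the full contralateral hemisphere, taken as
#' the hemisphere with the lower mean Tmax.
#'
#' @param series A [ctp_series()] (raw HU or baseline-subtracted).
#' @param brain_mask Logical `(z, y, x)` parenchyma mask used for map
#'   formation and normalization.
#' @param aif Optional [select_aif()] result, numeric curve, or logical
#'   voxel mask (treated as a manual AIF mask). `NULL` selects automatically.
#' @param config A [deconv_config()].
#' @param aif_search_mask Optional mask for automatic AIF search (e.g.
#'   including vessels excluded from `brain_mask`); defaults to `brain_mask`.
#' @return A list of class `ctp_maps` with 3D arrays `cbf_rel`, `cbv_rel`
#'   (percent of contralateral mean), `tmax`, `mtt` (s; NA outside the mask
#'   or where CBF is zero), plus `brain_mask`, `contralateral`
#'   (`"left"`/`"right"`), `dt`, `voxel_mm`, `aif` and `config`.
#' @export
compute_maps <- function(series, brain_mask, aif = NULL,
                         config = deconv_config(), aif_search_mask = NULL) {
  stopifnot(inherits(series, "ctp_series"))
  if (is.null(brain_mask) || !any(brain_mask)) abort("`brain_mask` is empty")
  if (!series$baseline_subtracted) {
    series <- baseline_subtract(series, config$n_baseline)
  }
  if (config$smooth_fwhm_vox > 0) {
    d <- dim(series$data)
    sm <- series$data
    for (f in seq_len(d[1L])) {
      sm[f, , , ] <- smooth_3d(array(sm[f, , , ], d[2:4]), config$smooth_fwhm_vox)
    }
    series <- ctp_series(sm, series$dt, series$voxel_mm, baseline_subtracted = TRUE)
  }
  if (is.null(aif)) {
    aif <- select_aif(series, aif_search_mask %||% brain_mask)
  } else if (is.logical(aif) || (is.array(aif) && length(dim(aif)) == 3L)) {
    aif <- select_aif(series, brain_mask, manual_mask = aif)
  } else if (is.numeric(aif)) {
    aif <- structure(list(curve = pmax(aif, 0), dt = series$dt, voxels = integer(),
                          source = "supplied"), class = "ctp_aif")
  }
  dt <- series$dt
  nt <- n_frames(series)
  cm <- series_matrix(series, brain_mask)
  k <- deconvolve_tikhonov(cm, aif, dt, config)
  if (is.null(dim(k))) k <- matrix(k, ncol = 1L)
  imax <- max.col(t(k), ties.method = "first")
  cbf_raw <- pmax(k[cbind(imax, seq_len(ncol(k)))], 0)
  tmax <- (imax - 1) * dt
  aif_area <- trapz_uniform(aif$curve, dt)
  if (aif_area <= 0) abort("AIF has non-positive area")
  cbv_raw <- pmax(trapz_uniform_cols(cm, dt) / aif_area, 0)
  mtt <- ifelse(cbf_raw > 0, cbv_raw / cbf_raw, NA_real_)

  shp <- dim(series$data)[2:4]
  hemi <- hemisphere_masks(shp)
  in_mask <- as.logical(brain_mask)
  side <- ifelse(hemi$left[in_mask], "left",
                 ifelse(hemi$right[in_mask], "right", NA_character_))
  mean_tmax <- vapply(c("left", "right"),
                      function(s) mean(tmax[side == s & !is.na(side)]), numeric(1))
  contra <- names(mean_tmax)[which.min(mean_tmax)]
  ref_cbf <- mean(cbf_raw[side == contra & !is.na(side)])
  ref_cbv <- mean(cbv_raw[side == contra & !is.na(side)])
  if (!is.finite(ref_cbf) || ref_cbf <= 0) abort("contralateral mean CBF is not positive")

  fill <- function(vals) {
    a <- array(NA_real_, shp)
    a[in_mask] <- vals
    a
  }
  structure(
    list(cbf_rel = fill(100 * cbf_raw / ref_cbf),
         cbv_rel = fill(100 * cbv_raw / ref_cbv),
         tmax = fill(tmax),
         mtt = fill(mtt),
         cbf_raw = fill(cbf_raw),
         brain_mask = array(in_mask, shp),
         contralateral = contra,
         dt = dt, voxel_mm = series$voxel_mm,
         aif = aif, config = config),
    class = "ctp_maps"
  )
}

#' @export
print.ctp_maps <- function(x, ...) {
  cat(sprintf(
    "<ctp_maps> dt = %g s, %d brain voxels, contralateral hemisphere: %s\n",
    x$dt, sum(x$brain_mask), x$contralateral
  ))
  invisible(x)
}

## 2D cross-correlation surface (summed over slices) between two volumes.
xcorr_shift <- function(ref, mov, max_shift) {
  d <- dim(ref)
  acc <- matrix(0, d[2L], d[3L])
  for (z in seq_len(d[1L])) {
    fr <- stats::fft(ref[z, , ])
    fm <- stats::fft(mov[z, , ])
    acc <- acc + Re(stats::fft(Conj(fr) * fm, inverse = TRUE))
  }
  sh <- function(n) {
    v <- c(0:(n - 1L))
    ifelse(v > n / 2, v - n, v)  # wrap-around lags
  }
  dy <- sh(d[2L]); dx <- sh(d[3L])
  oky <- abs(dy) <= max_shift; okx <- abs(dx) <= max_shift
  sub <- acc[oky, okx, drop = FALSE]
  ij <- arrayInd(which.max(sub), dim(sub))
  c(dy[oky][ij[1L]], dx[okx][ij[2L]])
}

#' Rigid in-plane motion correction
#'
#' Aligns each frame to the first frame by an integer-voxel in-plane
#' translation maximizing the cross-correlation (computed via FFT, summed
#' over slices, mean-removed). A no-op on static series.
#'
#' @param series A [ctp_series()].
#' @param max_shift Largest in-plane shift searched (voxels).
#' @return A list with `series` (the corrected [ctp_series()]) and `shifts`,
#'   a tibble of the applied per-frame corrections `(dy, dx)` (the negative
#'   of the estimated motion).
#' @export
correct_motion <- function(series, max_shift = 8L) {
  stopifnot(inherits(series, "ctp_series"))
  d <- dim(series$data)
  nt <- d[1L]
  ref <- array(series$data[1L, , , ], d[2:4])
  ref <- ref - mean(ref)
  out <- series$data
  dy <- dx <- integer(nt)
  for (f in seq_len(nt)[-1L]) {
    mov <- array(series$data[f, , , ], d[2:4])
    est <- xcorr_shift(ref, mov - mean(mov), max_shift)
    if (any(est != 0L)) {
      dy[f] <- -est[1L]; dx[f] <- -est[2L]
      out[f, , , ] <- shift_volume(mov, dy[f], dx[f])
    }
  }
  list(
    series = ctp_series(out, series$dt, series$voxel_mm,
                        baseline_subtracted = series$baseline_subtracted),
    shifts = tibble::tibble(frame = seq_len(nt), dy = dy, dx = dx)
  )
}
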