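# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom rlang abort warn
NULL

## Trapezoidal integral on a uniform grid.
trapz_uniform <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * (sum(y) - (y[1L] + y[n]) / 2)
}

## Column-wise trapezoid for an n x p matrix.
trapz_uniform_cols <- function(m, dt) {
  n <- nrow(m)
  dt * (colSums(m) - (m[1L, ] + m[n, ]) / 2)
}

## Evaluate code with a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Normalized 1D Gaussian kernel; sigma in voxels.
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

## Centered 1D convolution along rows of a matrix with edge renormalization.
conv_rows <- function(m, kernel) {
  nk <- length(kernel)
  if (nk == 1L) return(m)
  n <- nrow(m)
  r <- (nk - 1L) %/% 2L
  out <- matrix(0, n, ncol(m))
  wsum <- numeric(n)
  for (j in seq_len(nk)) {
    off <- j - r - 1L
    dst <- seq_len(n)
    src <- dst + off
    ok <- src >= 1L & src <= n
    out[dst[ok], ] <- out[dst[ok], ] + kernel[j] * m[src[ok], , drop = FALSE]
    wsum[dst[ok]] <- wsum[dst[ok]] + kernel[j]
  }
  out / wsum
}

## Separable 3D Gaussian smoothing of a (z, y, x) array; fwhm in voxels.
smooth_3d <- function(vol, fwhm_vox) {
  if (fwhm_vox <= 0) return(vol)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  k <- gaussian_kernel_1d(sigma)
  d <- dim(vol)
  out <- vol
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(out, perm)
    da <- dim(a)
    a <- conv_rows(matrix(a, nrow = da[1L]), k)
    dim(a) <- da
    out <- aperm(a, order(perm))
  }
  out
}

## Integer in-plane translation of a (z, y, x) volume with zero fill.
shift_volume <- function(vol, dy, dx) {
  d <- dim(vol)
  out <- array(0, d)
  ys <- seq_len(d[2L]) - dy
  xs <- seq_len(d[3L]) - dx
  oky <- ys >= 1L & ys <= d[2L]
  okx <- xs >= 1L & xs <= d[3L]
  out[, which(oky), which(okx)] <- vol[, ys[oky], xs[okx], drop = FALSE]
  out
}

## Round with an explicit half-way rule (doses are printed as integers).
round_mode <- function(x, digits = 0, mode = c("half-even", "half-up", "half-down", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(x)
  s <- 10^digits
  switch(mode,
    "half-even" = round(x, digits),
    "half-up"   = floor(x * s + 0.5) / s,
    "half-down" = ceiling(x * s - 0.5) / s
  )
}

## Morphological box dilation/erosion by one voxel (26-neighborhood).
dilate1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    zi <- pmin(pmax(seq_len(d[1L]) + dz, 1L), d[1L])
    yi <- pmin(pmax(seq_len(d[2L]) + dy, 1L), d[2L])
    xi <- pmin(pmax(seq_len(d[3L]) + dx, 1L), d[3L])
    out <- out | mask[zi, yi, xi]
  }
  out
}

erode1 <- function(mask) !dilate1(!mask)

assert_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if ((strict && x <= lower) || (!strict && x < lower)) {
    abort(sprintf("`%s` must be %s %s", name, if (strict) ">" else ">=", lower))
  }
  invisible(x)
}
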