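# Small phantom fixtures shared across test files. The reduced grid keeps a
# realistic brain/lesion layout while holding per-case processing well under
# a second.

small_spec <- function(lesion = lesion_spec(core_ml = 20, hypoperfusion_ml = 45), ...) {
  phantom_spec(
    shape = c(z = 4L, y = 24L, x = 24L),
    voxel_mm = c(z = 10, y = 8, x = 8),
    lesion = lesion,
    ...
  )
}

small_phantom <- function(seed = 2, ...) build_phantom(small_spec(...), seed = seed)

# maps object with hand-set values, for threshold tests that need no
# deconvolution
fake_maps <- function(tmax, cbf_rel, voxel_mm = c(10, 8, 8)) {
  stopifnot(identical(dim(tmax), dim(cbf_rel)))
  structure(
    list(cbf_rel = cbf_rel, cbv_rel = cbf_rel, tmax = tmax,
         mtt = array(4, dim(tmax)),
         brain_mask = array(TRUE, dim(tmax)),
         contralateral = "right", dt = 1.5, voxel_mm = voxel_mm,
         aif = NULL, config = deconv_config()),
    class = "ctp_maps"
  )
}

# independent ICC(2,1) oracle from explicit sums of squares
icc21_oracle <- function(x, y) {
  n <- length(x); k <- 2
  m <- cbind(x, y)
  gm <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  msr <- k * sum((rowm - gm)^2) / (n - 1)
  msc <- n * sum((colm - gm)^2) / (k - 1)
  mse <- sum((m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + gm)^2) /
    ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# dense circulant operator matching the deconvolution's embedding
circulant_operator <- function(aif, dt, L) {
  a <- c(aif, rep(0, L - length(aif)))
  dt * sapply(seq_len(L), function(j) a[((seq_len(L) - j) %% L) + 1])
}
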