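#' Gamma-variate bolus parameters
#'
#' Standard parameterization of a first-pass contrast bolus. The curve is
#' zero up to the arrival time `t0`, rises as a power law and decays
#' exponentially, with its single maximum at `t0 + alpha * beta`.
#'
#' @param t0 Bolus arrival time (s).
#' @param alpha Shape exponent (> 0, dimensionless).
#' @param beta Time scale (s, > 0).
#' @param amplitude Peak height (HU-equivalent concentration).
#' @return A list of class `gamma_variate_params`.
#' @export
gamma_variate_params <- function(t0 = 7, alpha = 3, beta = 1.5, amplitude = 300) {
  assert_scalar_number(t0, "t0")
  assert_scalar_number(alpha, "alpha", lower = 0, strict = TRUE)
  assert_scalar_number(beta, "beta", lower = 0, strict = TRUE)
  assert_scalar_number(amplitude, "amplitude", lower = 0)
  structure(list(t0 = t0, alpha = alpha, beta = beta, amplitude = amplitude),
            class = "gamma_variate_params")
}

#' Gamma-variate concentration curve
#'
#' Evaluates the bolus model
#' \deqn{c(t) = A \left(\frac{t - t_0}{\alpha\beta}\right)^{\alpha}
#'       \exp\!\left(\alpha - \frac{t - t_0}{\beta}\right)}
#' for `t > t0` and 0 otherwise. The normalization is such that the curve
#' maximum equals `amplitude` exactly (attained at `t0 + alpha * beta`).
#'
#' @param t Time grid (s).
#' @param params A [gamma_variate_params()] object.
#' @return Concentration values, same length as `t`.
#' @export
#' @examples
#' p <- gamma_variate_params(t0 = 5, alpha = 3, beta = 1.5, amplitude = 10)
#' max(gamma_variate(seq(0, 40, 0.01), p))  # 10
gamma_variate <- function(t, params) {
  if (!inherits(params, "gamma_variate_params")) {
    params <- do.call(gamma_variate_params, as.list(params))
  }
  u <- (t - params$t0) / (params$alpha * params$beta)
  out <- numeric(length(t))
  pos <- t > params$t0
  out[pos] <- params$amplitude * u[pos]^params$alpha *
    exp(params$alpha * (1 - u[pos]))
  out
}

#' Tissue parameters for the perfusion forward model
#'
#' @param cbf_rel Relative cerebral blood flow as a fraction of normal
#'   tissue (0--1.5; 1 = normal).
#' @param mtt Mean transit time (s, > 0).
#' @param delay Bolus arrival delay relative to the arterial input (s, >= 0);
#'   0 for normal tissue.
#' @param reference_mtt Normal-tissue MTT (s) used to express the implied
#'   relative CBV.
#' @return A list of class `tissue_params` with the implied
#'   `cbv_rel = cbf_rel * mtt / reference_mtt`.
#' @export
tissue_params <- function(cbf_rel = 1, mtt = 4, delay = 0, reference_mtt = 4) {
  assert_scalar_number(cbf_rel, "cbf_rel", lower = 0)
  if (cbf_rel > 1.5) abort("`cbf_rel` must be <= 1.5")
  assert_scalar_number(mtt, "mtt", lower = 0, strict = TRUE)
  assert_scalar_number(delay, "delay", lower = 0)
  structure(
    list(cbf_rel = cbf_rel, mtt = mtt, delay = delay,
         cbv_rel = cbf_rel * mtt / reference_mtt),
    class = "tissue_params"
  )
}

#' Tissue concentration curve from the indicator-dilution forward model
#'
#' Convolves a (possibly delayed) arterial input with a residue function and
#' scales by flow:
#' \deqn{c_{tissue}(t) = \mathrm{CBF} \; (a(\cdot - delay) \ast R)(t)\,}
#' discretized as a cumulative sum scaled by `dt`. The exponential residue
#' \eqn{R(t) = e^{-t/\mathrm{MTT}}} is the default; a boxcar residue
#' (plug flow, \eqn{R = 1} for \eqn{t < \mathrm{MTT}}) is available. Both
#' satisfy the central-volume theorem: the area ratio tissue/arterial equals
#' `cbf * mtt`.
#'
#' @param aif Arterial input curve sampled on a uniform grid.
#' @param dt Sampling interval of `aif` (s).
#' @param cbf Flow scale (s^-1); for relative phantoms pass
#'   `flow_scale * cbf_rel`.
#' @param mtt Mean transit time (s, > 0).
#' @param delay Arrival delay (s, >= 0); applied by linear interpolation of
#'   the input, so it need not be a grid multiple.
#' @param residue `"exponential"` (default) or `"boxcar"`.
#' @return Tissue concentration curve, same length as `aif`.
#' @export
tissue_curve <- function(aif, dt, cbf, mtt, delay = 0,
                         residue = c("exponential", "boxcar")) {
  residue <- match.arg(residue)
  assert_scalar_number(dt, "dt", lower = 0, strict = TRUE)
  assert_scalar_number(mtt, "mtt", lower = 0, strict = TRUE)
  assert_scalar_number(delay, "delay", lower = 0)
  assert_scalar_number(cbf, "cbf", lower = 0)
  n <- length(aif)
  t <- (seq_len(n) - 1) * dt
  a <- if (delay > 0) {
    stats::approx(t, aif, xout = t - delay, yleft = 0, rule = 2)$y
  } else {
    aif
  }
  r <- switch(residue,
    exponential = exp(-t / mtt),
    boxcar = as.numeric(t < mtt)
  )
  conv <- stats::convolve(a, rev(r), type = "open")[seq_len(n)]
  cbf * dt * conv
}

#' Phantom acquisition specification
#'
#' Describes a synthetic 4D CTP acquisition: grid and voxel geometry, time
#' grid, bolus and tissue physiology, an optional two-compartment ischemic
#' lesion (core nested in the hypoperfused region, confined to the left
#' hemisphere), and an artifact scenario. The `clean` defaults are chosen to
#' clear every automated quality-control threshold; each artifact scenario is
#' constructed to violate exactly one of them.
#'
#' @param shape Grid shape, integer `(z, y, x)`.
#' @param voxel_mm Voxel edge lengths (mm), `(z, y, x)`.
#' @param n_frames Number of dynamic frames.
#' @param dt Sampling interval (s).
#' @param baseline_hu Pre-contrast parenchyma attenuation (HU).
#' @param noise_sigma Additive Gaussian noise SD (HU).
#' @param texture_sigma SD (HU) of the static smooth anatomical texture that
#'   gives frames spatial structure (needed for meaningful frame-to-frame
#'   correlation); `texture_fwhm_vox` is its correlation length.
#' @param texture_fwhm_vox Smoothing FWHM (voxels) of the texture field.
#' @param aif [gamma_variate_params()] of the arterial bolus.
#' @param flow_scale Absolute flow scale (s^-1) multiplying relative CBF;
#'   default 0.025 yields a normal-tissue peak enhancement of about 20 HU
#'   with the default bolus.
#' @param normal [tissue_params()] of normal tissue.
#' @param lesion `NULL` for a lesion-free phantom, otherwise a list with
#'   `core_ml`, `hypoperfusion_ml`, `center_mm` (z, y, x; left hemisphere),
#'   `core` and `penumbra` [tissue_params()].
#' @param scenario One of `"clean"`, `"low_cnr"`, `"late_bolus"`, `"motion"`.
#' @param low_cnr_peak_hu Target mean-brain bolus peak (HU) for the
#'   `low_cnr` scenario (below the 8 HU QC threshold).
#' @param late_peak_fraction Target mean-brain peak position as a fraction of
#'   the acquisition window for the `late_bolus` scenario (> 0.9).
#' @param motion_frames Frame indices (1-based) affected by the `motion`
#'   scenario.
#' @param motion_shift Integer in-plane `(y, x)` voxel shift applied to the
#'   affected frames.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(z = 6L, y = 48L, x = 48L),
                         voxel_mm = c(z = 10, y = 4, x = 4),
                         n_frames = 27L,
                         dt = 1.5,
                         baseline_hu = 35,
                         noise_sigma = 0.5,
                         texture_sigma = 12,
                         texture_fwhm_vox = 4,
                         aif = gamma_variate_params(),
                         flow_scale = 0.025,
                         normal = tissue_params(1, 4, 0),
                         lesion = lesion_spec(),
                         scenario = c("clean", "low_cnr", "late_bolus", "motion"),
                         low_cnr_peak_hu = 5,
                         late_peak_fraction = 0.95,
                         motion_frames = 11:21,
                         motion_shift = c(y = 0L, x = 3L)) {
  scenario <- match.arg(scenario)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L)) abort("`shape` must be 3 sizes >= 2")
  if (n_frames < 3L) abort("`n_frames` must be >= 3")
  assert_scalar_number(dt, "dt", lower = 0, strict = TRUE)
  structure(
    list(shape = shape, voxel_mm = as.numeric(voxel_mm),
         n_frames = as.integer(n_frames), dt = dt,
         baseline_hu = baseline_hu, noise_sigma = noise_sigma,
         texture_sigma = texture_sigma, texture_fwhm_vox = texture_fwhm_vox,
         aif = aif, flow_scale = flow_scale, normal = normal, lesion = lesion,
         scenario = scenario, low_cnr_peak_hu = low_cnr_peak_hu,
         late_peak_fraction = late_peak_fraction,
         motion_frames = as.integer(motion_frames),
         motion_shift = as.integer(motion_shift)),
    class = "phantom_spec"
  )
}

#' Lesion specification for the phantom
#'
#' Two nested ellipsoidal compartments in the left hemisphere: an outer
#' hypoperfused region (delayed arrival, Tmax above the 6 s threshold) and an
#' inner infarct core (additionally relative CBF below 30%). Target volumes
#' are realized exactly (to one voxel) by rank-thresholding the ellipsoidal
#' distance, so ground-truth mask volumes equal `count * voxel volume`.
#'
#' @param core_ml Target core volume (mL, >= 0).
#' @param hypoperfusion_ml Target hypoperfusion volume (mL, >= core).
#' @param center_mm Lesion center (mm, `(z, y, x)` from grid center); must be
#'   in the left hemisphere (negative x).
#' @param core,penumbra [tissue_params()] of the two compartments.
#' @return A list of class `lesion_spec`.
#' @export
lesion_spec <- function(core_ml = 40, hypoperfusion_ml = 90,
                        center_mm = c(z = 0, y = 10, x = -48),
                        core = tissue_params(0.1, 8, 10),
                        penumbra = tissue_params(0.55, 6, 8)) {
  if (hypoperfusion_ml < core_ml) abort("`hypoperfusion_ml` must be >= `core_ml`")
  if (center_mm[3L] >= 0) abort("lesion center must lie in the left hemisphere (x < 0)")
  structure(list(core_ml = core_ml, hypoperfusion_ml = hypoperfusion_ml,
                 center_mm = center_mm, core = core, penumbra = penumbra),
            class = "lesion_spec")
}

## Voxel-center coordinates (mm) relative to the grid center, per axis.
grid_coords_mm <- function(shape, voxel_mm) {
  lapply(1:3, function(ax) {
    (seq_len(shape[ax]) - 0.5 - shape[ax] / 2) * voxel_mm[ax]
  })
}

## 3D arrays of voxel-center coordinates.
coord_arrays <- function(shape, voxel_mm) {
  co <- grid_coords_mm(shape, voxel_mm)
  list(
    z = array(co[[1L]], shape),
    y = array(rep(co[[2L]], each = shape[1L]), shape),
    x = array(rep(co[[3L]], each = shape[1L] * shape[2L]), shape)
  )
}

## Rank-threshold an ellipsoidal distance so the mask hits the target count.
rank_mask <- function(dist, eligible, n_target) {
  m <- array(FALSE, dim(dist))
  if (n_target == 0L) return(m)
  idx <- which(eligible)
  if (length(idx) < n_target) abort("lesion does not fit inside the hemisphere")
  sel <- idx[order(dist[idx])[seq_len(n_target)]]
  m[sel] <- TRUE
  m
}

#' Build a synthetic 4D CTP acquisition with known ground truth
#'
#' Assembles per-voxel time curves as `baseline + tissue_curve(AIF, voxel
#' params) + noise` over an ellipsoidal two-hemisphere brain slab, with a
#' designated arterial region (undelayed, full-amplitude bolus), an optional
#' nested core/hypoperfusion lesion in the left hemisphere, and one of four
#' artifact scenarios. Class curves are generated on a 0.1 s grid and sampled
#' onto the acquisition grid, so the forward model is not tied to the
#' reconstruction grid. Deterministic for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer RNG seed; recorded in the output.
#' @return A list of class `ctp_phantom` with elements
#'   \describe{
#'     \item{series}{the [ctp_series()] acquisition}
#'     \item{truth}{3D arrays `cbf_rel`, `cbv_rel`, `mtt`, `delay` (NA outside
#'       the parenchyma)}
#'     \item{masks}{logical arrays `brain` (parenchyma, artery excluded),
#'       `artery`, `core`, `hypoperfusion`}
#'     \item{aif_true}{the noise-free arterial curve on the acquisition grid}
#'     \item{applied_shifts}{per-frame `(y, x)` shifts for the motion scenario}
#'     \item{spec, seed}{provenance}
#'   }
#' @export
build_phantom <- function(spec = phantom_spec(), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(seed, {
    shp <- spec$shape
    nt <- spec$n_frames
    nvox <- prod(shp)
    co <- coord_arrays(shp, spec$voxel_mm)
    half <- shp * spec$voxel_mm / 2

    # brain: ellipsoid nearly filling the slab
    semi <- half * c(0.97, 0.92, 0.92)
    brain_all <- (co$z / semi[1L])^2 + (co$y / semi[2L])^2 + (co$x / semi[3L])^2 <= 1

    # arterial region: small anterior block straddling the midline
    zi <- array(rep(seq_len(shp[1L]), times = nvox / shp[1L]), shp)
    yi <- array(rep(seq_len(shp[2L]), each = shp[1L]), shp)
    xi <- array(rep(seq_len(shp[3L]), each = shp[1L] * shp[2L]), shp)
    zc <- max(1L, shp[1L] %/% 2L)
    yc <- max(2L, round(shp[2L] * 0.3))
    xm <- shp[3L] %/% 2L
    artery <- zi %in% c(zc, zc + 1L) & yi %in% c(yc, yc + 1L) & xi %in% c(xm, xm + 1L) & brain_all
    if (!any(artery)) abort("arterial region fell outside the brain mask")
    # analysis (parenchyma) mask: drop the one-voxel partial-volume shell at
    # the brain surface and a perivascular ring, as clinical map software does
    brain <- erode1(brain_all) & !dilate1(artery)

    vox_ml <- voxel_volume_ml(spec$voxel_mm)
    core <- hypo <- array(FALSE, shp)
    if (!is.null(spec$lesion)) {
      les <- spec$lesion
      ctr <- les$center_mm
      if (abs(ctr[1L]) > half[1L] || abs(ctr[2L]) > half[2L] || abs(ctr[3L]) > half[3L]) {
        abort("lesion center lies outside the grid")
      }
      # anisotropic ellipsoidal distance (flattened in z), volume-preserving
      sh <- c(0.62, 1.27, 1.27)
      dist <- sqrt(((co$z - ctr[1L]) / sh[1L])^2 +
                   ((co$y - ctr[2L]) / sh[2L])^2 +
                   ((co$x - ctr[3L]) / sh[3L])^2)
      left <- hemisphere_masks(shp)$left
      eligible <- brain & left
      n_hypo <- round(les$hypoperfusion_ml / vox_ml)
      n_core <- round(les$core_ml / vox_ml)
      hypo <- rank_mask(dist, eligible, n_hypo)
      core <- rank_mask(dist, eligible, n_core)  # same ranking => nested
    }
    penumbra <- hypo & !core
    # every tissue voxel (including the excluded shell) carries a bolus curve
    normal <- brain_all & !artery & !hypo

    # class curves on a fine grid, sampled at acquisition times
    t_acq <- (seq_len(nt) - 1) * spec$dt
    t_fine <- seq(0, (nt - 1) * spec$dt, by = 0.1)
    aif_par <- spec$aif
    amp_scale <- 1

    classes <- list(
      normal = spec$normal,
      penumbra = if (is.null(spec$lesion)) NULL else spec$lesion$penumbra,
      core = if (is.null(spec$lesion)) NULL else spec$lesion$core
    )
    class_masks <- list(normal = normal, penumbra = penumbra, core = core)

    make_curves <- function(par) {
      aif_fine <- gamma_variate(t_fine, par)
      curves <- lapply(classes, function(p) {
        if (is.null(p)) return(NULL)
        cf <- tissue_curve(aif_fine, 0.1, spec$flow_scale * p$cbf_rel, p$mtt, p$delay)
        stats::approx(t_fine, cf, xout = t_acq)$y
      })
      list(aif = stats::approx(t_fine, aif_fine, xout = t_acq)$y, tissue = curves)
    }
    cv <- make_curves(aif_par)

    mean_brain_curve <- function(cv) {
      num <- numeric(nt)
      nn <- 0L
      for (cl in names(classes)) {
        if (is.null(cv$tissue[[cl]])) next
        nc <- sum(class_masks[[cl]])
        num <- num + nc * cv$tissue[[cl]]
        nn <- nn + nc
      }
      num / nn
    }

    if (spec$scenario == "low_cnr") {
      peak <- max(mean_brain_curve(cv))
      amp_scale <- spec$low_cnr_peak_hu / peak
      cv$aif <- cv$aif * amp_scale
      cv$tissue <- lapply(cv$tissue, function(c) if (is.null(c)) NULL else c * amp_scale)
    } else if (spec$scenario == "late_bolus") {
      window <- (nt - 1) * spec$dt
      peak_t <- t_acq[which.max(mean_brain_curve(cv))]
      shift <- spec$late_peak_fraction * window - peak_t
      aif_par <- gamma_variate_params(aif_par$t0 + shift, aif_par$alpha,
                                      aif_par$beta, aif_par$amplitude)
      cv <- make_curves(aif_par)
    }

    # assemble baseline + texture + bolus enhancement
    tex <- smooth_3d(array(stats::rnorm(nvox), shp), spec$texture_fwhm_vox)
    tex <- tex / stats::sd(tex[brain_all]) * spec$texture_sigma
    base <- array(0, shp)
    base[brain_all] <- spec$baseline_hu + tex[brain_all]

    dmat <- matrix(rep(as.vector(base), each = nt), nrow = nt)
    for (cl in names(classes)) {
      if (is.null(cv$tissue[[cl]])) next
      idx <- which(as.vector(class_masks[[cl]]))
      if (length(idx)) dmat[, idx] <- dmat[, idx] + cv$tissue[[cl]]
    }
    dmat[, which(as.vector(artery))] <- dmat[, which(as.vector(artery))] + cv$aif

    applied <- matrix(0L, nrow = nt, ncol = 2L,
                      dimnames = list(NULL, c("y", "x")))
    if (spec$scenario == "motion") {
      frames <- spec$motion_frames[spec$motion_frames <= nt]
      applied[frames, 1L] <- spec$motion_shift[1L]
      applied[frames, 2L] <- spec$motion_shift[2L]
      for (f in frames) {
        vol <- array(dmat[f, ], shp)
        dmat[f, ] <- as.vector(shift_volume(vol, spec$motion_shift[1L], spec$motion_shift[2L]))
      }
    }

    if (spec$noise_sigma > 0) {
      dmat <- dmat + stats::rnorm(length(dmat), sd = spec$noise_sigma)
    }

    series <- ctp_series(array(dmat, c(nt, shp)), spec$dt, spec$voxel_mm)

    na_fill <- function(vals) {
      a <- array(NA_real_, shp)
      for (cl in names(classes)) {
        if (is.null(classes[[cl]])) next
        a[class_masks[[cl]]] <- vals[[cl]]
      }
      a
    }
    truth <- list(
      cbf_rel = na_fill(lapply(classes, function(p) p$cbf_rel)),
      cbv_rel = na_fill(lapply(classes, function(p) p$cbv_rel)),
      mtt = na_fill(lapply(classes, function(p) p$mtt)),
      delay = na_fill(lapply(classes, function(p) p$delay))
    )

    structure(
      list(series = series, truth = truth,
           masks = list(brain = brain, artery = artery, core = core,
                        hypoperfusion = hypo),
           aif_true = cv$aif, applied_shifts = applied,
           spec = spec, seed = as.integer(seed)),
      class = "ctp_phantom"
    )
  })
}

#' @export
print.ctp_phantom <- function(x, ...) {
  vml <- voxel_volume_ml(x$spec$voxel_mm)
  cat(sprintf(
    "<ctp_phantom> scenario '%s', seed %d: core %.1f mL, hypoperfusion %.1f mL, brain %.0f mL\n",
    x$spec$scenario, x$seed, sum(x$masks$core) * vml,
    sum(x$masks$hypoperfusion) * vml, sum(x$masks$brain) * vml
  ))
  print(x$series)
  invisible(x)
}

#' Generate a synthetic cohort of phantom cases
#'
#' Samples lesion sizes, severities and artifact scenarios for `n_subjects`
#' phantom acquisitions. Core-volume targets are drawn uniformly over
#' `core_range` so the DEFUSE-3 volume thresholds are straddled; a fraction
#' of cases carries no lesion (no vascular occlusion). Deterministic for a
#' fixed seed; each case receives its own derived seed so results do not
#' depend on processing order.
#'
#' @param n_subjects Number of cases (>= 1).
#' @param seed Master RNG seed.
#' @param base_spec [phantom_spec()] supplying geometry, bolus and noise.
#' @param scenario_mix Named probabilities over
#'   `c("clean", "low_cnr", "late_bolus", "motion")`; default 90% clean.
#' @param lesion_prob Probability a case carries an ischemic lesion.
#' @param core_range,mismatch_range Uniform sampling ranges (mL) for the
#'   ground-truth core volume and mismatch (hypoperfusion - core) volume.
#' @return A tibble with one row per case: identifiers, per-case seed,
#'   scenario, ground-truth targets and tissue severities, and a `spec`
#'   list-column of [phantom_spec()] objects ready for [build_phantom()].
#' @export
cohort_generate <- function(n_subjects, seed = 1L,
                            base_spec = phantom_spec(),
                            scenario_mix = c(clean = 0.9, low_cnr = 1 / 30,
                                             late_bolus = 1 / 30, motion = 1 / 30),
                            lesion_prob = 0.85,
                            core_range = c(0, 100),
                            mismatch_range = c(0, 90)) {
  if (n_subjects < 1L) abort("`n_subjects` must be >= 1")
  scenario_mix <- scenario_mix / sum(scenario_mix)
  with_seed(seed, {
    case_seed <- sample.int(.Machine$integer.max - 1L, n_subjects)
    scenario <- sample(names(scenario_mix), n_subjects, replace = TRUE,
                       prob = scenario_mix)
    has_lesion <- stats::runif(n_subjects) < lesion_prob
    core_ml <- ifelse(has_lesion, stats::runif(n_subjects, core_range[1L], core_range[2L]), 0)
    mismatch_ml <- ifelse(has_lesion, stats::runif(n_subjects, mismatch_range[1L], mismatch_range[2L]), 0)
    pen_delay <- stats::runif(n_subjects, 7, 10)
    core_delay <- pen_delay + stats::runif(n_subjects, 1, 3)
    core_cbf <- stats::runif(n_subjects, 0.08, 0.14)
    pen_cbf <- stats::runif(n_subjects, 0.45, 0.65)
    core_mtt <- stats::runif(n_subjects, 7, 9)
    pen_mtt <- stats::runif(n_subjects, 5, 7)

    specs <- lapply(seq_len(n_subjects), function(i) {
      sp <- base_spec
      sp$scenario <- scenario[i]
      sp$lesion <- if (has_lesion[i]) {
        lesion_spec(core_ml = core_ml[i],
                    hypoperfusion_ml = core_ml[i] + mismatch_ml[i],
                    core = tissue_params(core_cbf[i], core_mtt[i], core_delay[i]),
                    penumbra = tissue_params(pen_cbf[i], pen_mtt[i], pen_delay[i]))
      } else {
        NULL
      }
      sp
    })

    tibble::tibble(
      case_id = seq_len(n_subjects),
      seed = case_seed,
      scenario = scenario,
      has_lesion = has_lesion,
      core_target_ml = core_ml,
      hypoperfusion_target_ml = core_ml + mismatch_ml,
      core_cbf_rel = ifelse(has_lesion, core_cbf, NA_real_),
      penumbra_cbf_rel = ifelse(has_lesion, pen_cbf, NA_real_),
      core_delay_s = ifelse(has_lesion, core_delay, NA_real_),
      penumbra_delay_s = ifelse(has_lesion, pen_delay, NA_real_),
      spec = specs
    )
  })
}
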