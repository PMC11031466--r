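test_that("gamma-variate curve is zero before arrival, peaks at t0 + alpha*beta with height amplitude", {
  p <- gamma_variate_params(t0 = 5, alpha = 3, beta = 1.5, amplitude = 10)
  t <- seq(0, 40, by = 0.001)
  c_ <- gamma_variate(t, p)
  expect_equal(gamma_variate(5, p), 0)
  expect_true(all(c_[t <= 5] == 0))
  expect_true(all(c_ >= 0))
  expect_equal(t[which.max(c_)], 5 + 3 * 1.5, tolerance = 1e-3)
  expect_equal(max(c_), 10, tolerance = 1e-6)
  # single interior maximum: derivative changes sign once
  d <- diff(c_[t > 5])
  expect_equal(sum(diff(sign(d[d != 0])) != 0), 1L)
})

test_that("gamma-variate parameters are validated", {
  expect_error(gamma_variate_params(alpha = 0), "alpha")
  expect_error(gamma_variate_params(beta = -1), "beta")
})

test_that("tissue curve follows the indicator-dilution forward model", {
  t <- seq(0, 90, by = 0.1)
  aif <- gamma_variate(t, gamma_variate_params())
  expect_equal(tissue_curve(aif, 0.1, cbf = 0, mtt = 4), rep(0, length(t)))
  # central-volume theorem: area ratio = cbf * mtt (both residues)
  for (res in c("exponential", "boxcar")) {
    tc <- tissue_curve(aif, 0.1, cbf = 0.012, mtt = 5, residue = res)
    expect_equal(sum(tc) / sum(aif), 0.012 * 5, tolerance = 0.02)
  }
  # a delay shifts the curve maximum by the same amount (dense-grid oracle)
  t0 <- tissue_curve(aif, 0.1, 0.012, 5, delay = 0)
  t5 <- tissue_curve(aif, 0.1, 0.012, 5, delay = 5.3)
  expect_equal(0.1 * (which.max(t5) - which.max(t0)), 5.3, tolerance = 0.1)
  expect_error(tissue_curve(aif, 0.1, 0.012, mtt = 0), "mtt")
})

test_that("phantom ground-truth mask volumes match their targets to one voxel", {
  ph <- build_phantom(phantom_spec(noise_sigma = 0), seed = 1)
  vml <- voxel_volume_ml(ph$spec$voxel_mm)
  expect_equal(sum(ph$masks$core) * vml, 40, tolerance = vml / 40)
  expect_equal(sum(ph$masks$hypoperfusion) * vml, 90, tolerance = vml / 90)
  # nesting and hemisphere confinement
  expect_true(all(ph$masks$hypoperfusion[ph$masks$core]))
  left <- hemisphere_masks(ph$spec$shape)$left
  expect_true(all(left[ph$masks$hypoperfusion]))
  # ground truth stored per compartment
  expect_true(all(ph$truth$cbf_rel[ph$masks$core] == ph$spec$lesion$core$cbf_rel))
  expect_true(all(ph$truth$delay[ph$masks$brain & !ph$masks$hypoperfusion] == 0))
})

test_that("clean phantom clears the 8 HU bolus-peak threshold and is reproducible", {
  ph <- build_phantom(phantom_spec(), seed = 42)
  bs <- baseline_subtract(ph$series)
  peak <- max(mean_bolus_curve(bs, ph$masks$brain))
  expect_gte(peak, 8)
  ph2 <- build_phantom(phantom_spec(), seed = 42)
  expect_identical(ph$series$data, ph2$series$data)
  ph3 <- build_phantom(phantom_spec(), seed = 43)
  expect_false(identical(ph$series$data, ph3$series$data))
})

test_that("artifact scenarios reshape the acquisition as designed", {
  lc <- build_phantom(phantom_spec(scenario = "low_cnr"), seed = 5)
  peak_lc <- max(mean_bolus_curve(baseline_subtract(lc$series), lc$masks$brain))
  expect_lt(peak_lc, 8)

  lb <- build_phantom(phantom_spec(scenario = "late_bolus", noise_sigma = 0), seed = 5)
  curve <- mean_bolus_curve(baseline_subtract(lb$series, 2), lb$masks$brain)
  frac <- (which.max(curve) - 1) / (n_frames(lb$series) - 1)
  expect_gt(frac, 0.9)

  mo <- build_phantom(phantom_spec(scenario = "motion"), seed = 5)
  expect_true(all(mo$applied_shifts[11:21, "x"] == mo$spec$motion_shift[2]))
  expect_true(all(mo$applied_shifts[-(11:21), "x"] == 0))
})

test_that("a lesion that cannot fit raises an error", {
  expect_error(
    build_phantom(phantom_spec(
      lesion = lesion_spec(core_ml = 400, hypoperfusion_ml = 500)
    ), seed = 1),
    "does not fit"
  )
  expect_error(
    build_phantom(phantom_spec(
      lesion = lesion_spec(center_mm = c(0, 300, -48))
    ), seed = 1),
    "outside the grid"
  )
  expect_error(lesion_spec(center_mm = c(0, 0, 20)), "left hemisphere")
  expect_error(lesion_spec(core_ml = 50, hypoperfusion_ml = 40), "hypoperfusion_ml")
})

test_that("cohort generation is seeded, sized and straddles the DEFUSE-3 core threshold", {
  expect_equal(nrow(cohort_generate(1, seed = 3)), 1L)
  co1 <- cohort_generate(50, seed = 11)
  co2 <- cohort_generate(50, seed = 11)
  expect_identical(co1[setdiff(names(co1), "spec")], co2[setdiff(names(co2), "spec")])
  expect_true(any(co1$core_target_ml > 70))
  expect_true(any(co1$core_target_ml < 70))
  expect_true(any(!co1$has_lesion))
  expect_true(mean(co1$scenario == "clean") > 0.7)
  expect_error(cohort_generate(0), "n_subjects")
})
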