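test_that("segmentation applies strict thresholds and nesting", {
  shp <- c(2L, 4L, 4L)
  tmax <- array(0, shp); cbf <- array(100, shp)
  m0 <- segment_lesions(fake_maps(tmax, cbf))
  expect_equal(sum(m0$hypoperfusion), 0)
  expect_equal(sum(m0$core), 0)
  # a voxel at exactly Tmax = 6 s is NOT hypoperfused
  tmax[1, 1, 1] <- 6; tmax[1, 2, 1] <- 6.01
  cbf[1, 1, 1] <- 10; cbf[1, 2, 1] <- 10
  m1 <- segment_lesions(fake_maps(tmax, cbf))
  expect_false(m1$hypoperfusion[1, 1, 1])
  expect_true(m1$hypoperfusion[1, 2, 1])
  expect_true(m1$core[1, 2, 1])
  expect_false(m1$core[1, 1, 1])  # nested: low CBF outside hypoperfusion
  # exactly 30% CBF is not core
  tmax[2, 1, 1] <- 8; cbf[2, 1, 1] <- 30
  m2 <- segment_lesions(fake_maps(tmax, cbf))
  expect_false(m2$core[2, 1, 1])
  # un-nested variant
  m3 <- segment_lesions(fake_maps(tmax, cbf), nested = FALSE)
  expect_true(m3$core[1, 1, 1])
})

test_that("clean phantom segmentation recovers the ground-truth masks", {
  ph <- build_phantom(phantom_spec(noise_sigma = 0), seed = 21)
  maps <- compute_maps(ph$series, ph$masks$brain,
                       aif_search_mask = ph$masks$brain | ph$masks$artery)
  seg <- segment_lesions(maps)
  expect_gte(dice(seg$core, ph$masks$core), 0.9)
  expect_gte(dice(seg$hypoperfusion, ph$masks$hypoperfusion), 0.9)
})

test_that("volumetry arithmetic and evaluability rules", {
  mk <- function(n_hypo, n_core) {
    h <- array(FALSE, c(1, 5, 5)); h[seq_len(n_hypo)] <- TRUE
    c_ <- array(FALSE, c(1, 5, 5)); c_[seq_len(n_core)] <- TRUE
    list(hypoperfusion = h, core = c_, voxel_ml = 1)
  }
  v <- volumetry(mk(20, 5))
  expect_equal(v$mismatch_ml, 15)
  expect_equal(v$mismatch_ratio, 4)
  expect_true(v$ratio_evaluable)
  v2 <- volumetry(mk(10, 2))
  expect_false(v2$ratio_evaluable)
  expect_equal(v2$mismatch_ratio, 5)  # defined, just not analyzed for agreement
  v3 <- volumetry(mk(0, 0))
  expect_equal(v3$hypoperfusion_ml, 0)
  expect_true(is.na(v3$mismatch_ratio))
  bad <- mk(3, 5)
  expect_error(volumetry(bad), "invariant")
})

test_that("DEFUSE-3 decision follows strict criteria with the margin zone", {
  row_ <- function(core, hypo) tibble::tibble(
    hypoperfusion_ml = hypo, core_ml = core, mismatch_ml = hypo - core,
    mismatch_ratio = ifelse(core > 0, hypo / core, NA_real_)
  )
  d <- defuse3_decide(row_(50, 110))
  expect_equal(d$eligible, "treat")
  expect_false(d$in_margin_zone)
  expect_equal(defuse3_decide(row_(80, 200))$eligible, "no_treat")
  expect_true(defuse3_decide(row_(68, 200))$in_margin_zone)
  # zero-core hypoperfused case: ratio criterion satisfied in the limit
  d0 <- defuse3_decide(row_(0, 40))
  expect_equal(d0$eligible, "treat")
  d00 <- defuse3_decide(row_(0, 0))
  expect_equal(d00$eligible, "no_treat")
})

test_that("decision grid around every threshold matches an independent rule oracle", {
  grid <- tidyr::expand_grid(
    core = c(0, 3, 64.9, 65, 69.9, 70, 70.1, 75, 75.1),
    mismatch = c(9.9, 10, 14.9, 15, 15.1, 20, 20.1),
    ratio = c(1.59, 1.6, 1.79, 1.8, 1.81, 2, 2.01)
  )
  # hypoperfusion implied by core + mismatch; ratio stated independently to
  # probe the rule logic itself
  rep_ <- tibble::tibble(
    core_ml = grid$core, mismatch_ml = grid$mismatch,
    hypoperfusion_ml = grid$core + grid$mismatch,
    mismatch_ratio = ifelse(grid$core > 0, grid$ratio, NA_real_)
  )
  d <- defuse3_decide(rep_)
  oracle_treat <- grid$core < 70 & grid$mismatch > 15 &
    ifelse(grid$core > 0, grid$ratio > 1.8, grid$core + grid$mismatch > 0)
  oracle_margin <- (grid$core >= 65 & grid$core <= 75) |
    (grid$mismatch >= 10 & grid$mismatch <= 20) |
    (grid$core > 0 & grid$ratio >= 1.6 & grid$ratio <= 2.0)
  expect_equal(d$eligible == "treat", oracle_treat)
  expect_equal(d$in_margin_zone, oracle_margin)
})

test_that("lowering core volume outside the margin zone never flips treat to no-treat", {
  cores <- c(64, 60, 50, 30, 10, 4)
  for (i in seq_along(cores)[-1]) {
    prev <- defuse3_decide(tibble::tibble(
      core_ml = cores[i - 1], hypoperfusion_ml = 130,
      mismatch_ml = 130 - cores[i - 1], mismatch_ratio = 130 / cores[i - 1]
    ))
    cur <- defuse3_decide(tibble::tibble(
      core_ml = cores[i], hypoperfusion_ml = 130,
      mismatch_ml = 130 - cores[i], mismatch_ratio = 130 / cores[i]
    ))
    if (prev$eligible == "treat") expect_equal(cur$eligible, "treat")
  }
})

test_that("confusion matrix counts, margin exclusion and normalization", {
  mk <- function(elig, margin = rep(FALSE, length(elig))) {
    tibble::tibble(eligible = elig, in_margin_zone = margin)
  }
  cm <- compare_decisions(mk(c("treat", "no_treat")), mk(c("treat", "no_treat")))
  expect_equal(cm$counts[1, 2] + cm$counts[2, 1], 0)
  expect_equal(unname(diag(cm$percent)), c(100, 100))
  cm2 <- compare_decisions(
    mk(c("treat", "treat", "no_treat")),
    mk(c("treat", "no_treat", "no_treat"))
  )
  expect_equal(as.vector(cm2$counts), c(1, 0, 1, 1))  # TP FP FN TN (column-major)
  expect_equal(cm2$n_discordant, 1)
  all_margin <- compare_decisions(
    mk(c("treat", "no_treat"), margin = c(TRUE, TRUE)),
    mk(c("no_treat", "treat"))
  )
  expect_equal(sum(all_margin$counts), 0)
  expect_equal(all_margin$n_excluded_margin, 2)
  expect_error(compare_decisions(mk("treat"), mk(c("treat", "treat"))), "same number")
})

test_that("margin exclusion never increases the discordance count", {
  set.seed(31)
  for (rep in 1:20) {
    core <- runif(30, 0, 120)
    hypo <- core + runif(30, 0, 90)
    mk_dec <- function(core, hypo) defuse3_decide(tibble::tibble(
      core_ml = core, hypoperfusion_ml = hypo, mismatch_ml = hypo - core,
      mismatch_ratio = ifelse(core > 0, hypo / core, NA_real_)
    ))
    ref <- mk_dec(core, hypo)
    test <- mk_dec(core + rnorm(30, sd = 6), hypo + rnorm(30, sd = 6))
    with_excl <- compare_decisions(ref, test, exclude_margin = TRUE)
    without <- compare_decisions(ref, test, exclude_margin = FALSE)
    expect_lte(with_excl$n_discordant, without$n_discordant)
  }
})

test_that("tidy() lays the confusion matrix out in Table-1 form", {
  mk <- function(elig) tibble::tibble(eligible = elig, in_margin_zone = FALSE)
  cm <- compare_decisions(mk(c("treat", "treat", "no_treat")),
                          mk(c("treat", "no_treat", "no_treat")))
  td <- tidy(cm)
  expect_equal(td$cell, c("TP", "FN", "FP", "TN"))
  expect_equal(td$n, c(1, 1, 0, 1))
  expect_equal(td$pct, c(50, 50, 0, 100))
})
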