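#' Experiment configuration
#'
#' Bundles every tunable of the end-to-end experiment: cohort composition,
#' subsampling factors, deconvolution settings, QC and decision thresholds,
#' and the master seed. All thresholds default to the established clinical
#' values (Tmax > 6 s, CBF < 30%, core < 70 mL, mismatch > 15 mL, ratio
#' > 1.8, margins 5 mL / 0.2, ratio evaluable above 3 mL) and are carried in
#' the run manifest.
#'
#' @param n_subjects Cohort size.
#' @param factors Subsampling factors; 1 (the reference) is always included.
#' @param seed Master seed; per-case seeds are derived from it so results do
#'   not depend on processing order.
#' @param base_spec [phantom_spec()] shared by all cases.
#' @param scenario_mix,lesion_prob,core_range,mismatch_range Passed to
#'   [cohort_generate()].
#' @param deconv A [deconv_config()].
#' @param qc A [qc_thresholds()].
#' @param defuse3 A [defuse3_thresholds()].
#' @param tmax_threshold,cbf_threshold Segmentation thresholds (s, %).
#' @param ratio_min_core_ml Core volume above which the mismatch ratio is
#'   evaluable.
#' @param motion_correct Apply rigid motion correction before processing.
#' @param occlusion_only Restrict decision confusion matrices to cases with
#'   a ground-truth lesion (the vessel-occlusion subgroup).
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_subjects = 50L, factors = 1:4, seed = 1L,
                       base_spec = phantom_spec(),
                       scenario_mix = c(clean = 0.9, low_cnr = 1 / 30,
                                        late_bolus = 1 / 30, motion = 1 / 30),
                       lesion_prob = 0.85,
                       core_range = c(0, 100), mismatch_range = c(0, 90),
                       deconv = deconv_config(),
                       qc = qc_thresholds(),
                       defuse3 = defuse3_thresholds(),
                       tmax_threshold = 6, cbf_threshold = 30,
                       ratio_min_core_ml = 3,
                       motion_correct = TRUE,
                       occlusion_only = TRUE) {
  factors <- sort(unique(c(1L, as.integer(factors))))
  structure(
    list(n_subjects = as.integer(n_subjects), factors = factors,
         seed = as.integer(seed), base_spec = base_spec,
         scenario_mix = scenario_mix, lesion_prob = lesion_prob,
         core_range = core_range, mismatch_range = mismatch_range,
         deconv = deconv, qc = qc, defuse3 = defuse3,
         tmax_threshold = tmax_threshold, cbf_threshold = cbf_threshold,
         ratio_min_core_ml = ratio_min_core_ml,
         motion_correct = motion_correct, occlusion_only = occlusion_only),
    class = "run_config"
  )
}

#' Process one phantom case at every sampling scheme
#'
#' For each factor: decimates the series, optionally applies motion
#' correction, evaluates QC, computes perfusion maps, segments hypoperfusion
#' and core, and derives the lesion report and DEFUSE-3 decision. The
#' factor-1 row is the reference; a case whose reference acquisition is
#' uninterpretable is flagged `excluded` (mirroring visual exclusion of
#' fatally flawed scans).
#'
#' @param phantom A [build_phantom()] result.
#' @param config A [run_config()].
#' @param factors Subsampling factors (default from `config`).
#' @param keep_maps Keep the `ctp_maps` objects in a list-column (memory
#'   heavy; default drops them).
#' @return A tibble with one row per factor: sampling descriptors, QC
#'   summary columns, lesion volumes, decision columns and `excluded`.
#' @export
run_case <- function(phantom, config = run_config(), factors = config$factors,
                     keep_maps = FALSE) {
  stopifnot(inherits(phantom, "ctp_phantom"))
  masks <- phantom$masks
  search_mask <- masks$brain | masks$artery
  rows <- lapply(factors, function(f) {
    s <- decimate(phantom$series, f)
    qc <- evaluate_qc(s, masks$brain, config$qc)  # on the acquired frames
    if (isTRUE(config$motion_correct)) {
      s <- correct_motion(s)$series
    }
    maps <- compute_maps(s, masks$brain, config = config$deconv,
                         aif_search_mask = search_mask)
    seg <- segment_lesions(maps, config$tmax_threshold, config$cbf_threshold)
    rep_ <- volumetry(seg, ratio_min_core_ml = config$ratio_min_core_ml)
    dec <- defuse3_decide(rep_, config$defuse3)
    row <- dplyr::bind_cols(
      tibble::tibble(factor = as.integer(f), dt = s$dt, n_frames = n_frames(s)),
      tidy(qc), dec
    )
    if (keep_maps) row$maps <- list(maps)
    row
  })
  out <- dplyr::bind_rows(rows)
  out$excluded <- out$uninterpretable[out$factor == 1L][1L]
  out
}

#' Run the full temporal-sampling experiment
#'
#' Generates a seeded phantom cohort, processes every case at every
#' sampling factor, and assembles the report bundle: the per-case results
#' table, quality-stratified agreement statistics, per-factor DEFUSE-3
#' confusion matrices (on the occlusion subgroup, reference margin zone
#' excluded), a QC summary, the dose table and a run manifest. Deterministic
#' for a fixed seed.
#'
#' @param config A [run_config()].
#' @param progress Print one line per processed case.
#' @return A list of class `ctp_experiment`: `results`, `cohort`,
#'   `agreement`, `confusion` (named by factor), `qc_summary`, `dose`,
#'   `excluded_cases` and `manifest`.
#' @export
run_experiment <- function(config = run_config(), progress = FALSE) {
  cohort <- cohort_generate(
    config$n_subjects, seed = config$seed, base_spec = config$base_spec,
    scenario_mix = config$scenario_mix, lesion_prob = config$lesion_prob,
    core_range = config$core_range, mismatch_range = config$mismatch_range
  )
  if (nrow(cohort) == 0L) abort("empty cohort")
  vml <- voxel_volume_ml(config$base_spec$voxel_mm)
  results <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    ph <- build_phantom(cohort$spec[[i]], seed = cohort$seed[i])
    res <- run_case(ph, config)
    res$case_id <- cohort$case_id[i]
    res$scenario <- cohort$scenario[i]
    res$has_lesion <- cohort$has_lesion[i]
    res$truth_core_ml <- sum(ph$masks$core) * vml
    res$truth_hypoperfusion_ml <- sum(ph$masks$hypoperfusion) * vml
    if (progress) {
      message(sprintf("case %d/%d (%s) done", i, nrow(cohort), cohort$scenario[i]))
    }
    res
  })
  results <- dplyr::relocate(results, "case_id", "scenario")

  excluded <- unique(results$case_id[results$excluded])
  analyzed <- dplyr::filter(results, !.data$excluded)
  ref_quality <- analyzed$quality_class[analyzed$factor == 1L]
  names(ref_quality) <- analyzed$case_id[analyzed$factor == 1L]
  analyzed$quality_class <- ref_quality[as.character(analyzed$case_id)]

  agreement <- cohort_agreement(analyzed)

  conf_ids <- if (config$occlusion_only) {
    unique(analyzed$case_id[analyzed$has_lesion])
  } else {
    unique(analyzed$case_id)
  }
  ref <- dplyr::filter(analyzed, .data$factor == 1L, .data$case_id %in% conf_ids)
  confusion <- lapply(setdiff(config$factors, 1L), function(f) {
    test <- dplyr::filter(analyzed, .data$factor == f, .data$case_id %in% conf_ids)
    test <- test[match(ref$case_id, test$case_id), ]
    compare_decisions(ref, test)
  })
  names(confusion) <- paste0("factor_", setdiff(config$factors, 1L))

  qc_summary <- dplyr::summarise(
    dplyr::group_by(results, .data$scenario, .data$factor),
    n = dplyr::n(),
    n_truncated = sum(.data$flag_truncated_bolus),
    n_low_cnr = sum(.data$flag_low_cnr),
    n_motion = sum(.data$flag_motion),
    n_high_quality = sum(.data$quality_class == "high"),
    .groups = "drop"
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("ctperfusion")),
    seed = config$seed, n_subjects = config$n_subjects,
    factors = config$factors,
    thresholds = list(
      tmax_s = config$tmax_threshold, cbf_pct = config$cbf_threshold,
      ratio_min_core_ml = config$ratio_min_core_ml,
      defuse3 = unclass(config$defuse3), qc = unclass(config$qc)
    ),
    deconv = unclass(config$deconv),
    phantom = list(
      shape = config$base_spec$shape, voxel_mm = config$base_spec$voxel_mm,
      n_frames = config$base_spec$n_frames, dt = config$base_spec$dt,
      noise_sigma = config$base_spec$noise_sigma,
      flow_scale = config$base_spec$flow_scale,
      scenario_mix = as.list(config$scenario_mix)
    )
  )

  structure(
    list(results = results, cohort = cohort, agreement = agreement,
         confusion = confusion, qc_summary = qc_summary,
         dose = dose_table(), excluded_cases = excluded, manifest = manifest),
    class = "ctp_experiment"
  )
}

#' @export
print.ctp_experiment <- function(x, ...) {
  cat(sprintf("<ctp_experiment> %d cases x factors {%s}, %d excluded\n",
              x$manifest$n_subjects,
              paste(x$manifest$factors, collapse = ", "),
              length(x$excluded_cases)))
  cat("\nAgreement (high-quality stratum):\n")
  print(dplyr::filter(x$agreement, .data$stratum == "high"), n = Inf)
  for (nm in names(x$confusion)) {
    cat("\n", nm, ": ", sep = "")
    print(x$confusion[[nm]])
  }
  invisible(x)
}

#' @export
tidy.ctp_experiment <- function(x, ...) x$agreement

#' @export
glance.ctp_experiment <- function(x, ...) {
  ag <- dplyr::filter(x$agreement, .data$stratum == "high",
                      .data$metric == "core_ml")
  f2 <- dplyr::filter(ag, .data$factor == 2L)
  tibble::tibble(
    n_cases = x$manifest$n_subjects,
    n_excluded = length(x$excluded_cases),
    icc_core_f2 = if (nrow(f2)) f2$icc else NA_real_,
    median_diff_core_f2 = if (nrow(f2)) f2$median_diff else NA_real_,
    discordance_pct_f2 = if ("factor_2" %in% names(x$confusion)) {
      x$confusion$factor_2$discordance_pct
    } else {
      NA_real_
    }
  )
}

#' Write the experiment report bundle to disk
#'
#' Serializes the per-case results, agreement tables, confusion matrices,
#' QC summary and dose table as CSV, and the manifest as JSON, into a run
#' directory.
#'
#' @param experiment A [run_experiment()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  drop_lists <- function(d) d[, !vapply(d, is.list, logical(1)), drop = FALSE]
  utils::write.csv(drop_lists(experiment$results),
                   file.path(dir, "results.csv"), row.names = FALSE)
  utils::write.csv(experiment$agreement, file.path(dir, "agreement.csv"),
                   row.names = FALSE)
  utils::write.csv(dplyr::bind_rows(lapply(names(experiment$confusion), function(nm) {
    dplyr::mutate(tidy(experiment$confusion[[nm]]), comparison = nm)
  })), file.path(dir, "confusion.csv"), row.names = FALSE)
  utils::write.csv(experiment$qc_summary, file.path(dir, "qc_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(experiment$dose, file.path(dir, "dose_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(experiment$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
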