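#' Threshold segmentation of hypoperfusion and infarct core
#'
#' Applies the established perfusion thresholds: hypoperfusion is
#' `Tmax > 6 s` (strict) and infarct core is relative `CBF < 30%` of the
#' contralateral mean. By the operational convention the core is nested
#' inside the hypoperfused region, which guarantees a non-negative mismatch;
#' set `nested = FALSE` to threshold CBF over the whole brain mask instead.
#'
#' @param maps A [compute_maps()] result.
#' @param tmax_threshold Hypoperfusion threshold (s); voxels strictly above
#'   it are hypoperfused.
#' @param cbf_threshold Core threshold (% of contralateral mean); voxels
#'   strictly below it (within hypoperfusion when nested) are core.
#' @param nested Enforce core within hypoperfusion (default).
#' @return A list of class `ctp_masks`: logical arrays `hypoperfusion` and
#'   `core`, and `voxel_ml`.
#' @export
segment_lesions <- function(maps, tmax_threshold = 6, cbf_threshold = 30,
                            nested = TRUE) {
  stopifnot(inherits(maps, "ctp_maps"))
  bm <- maps$brain_mask
  hypo <- !is.na(maps$tmax) & maps$tmax > tmax_threshold & bm
  low_cbf <- !is.na(maps$cbf_rel) & maps$cbf_rel < cbf_threshold & bm
  core <- if (nested) low_cbf & hypo else low_cbf
  structure(list(hypoperfusion = hypo, core = core,
                 voxel_ml = voxel_volume_ml(maps$voxel_mm)),
            class = "ctp_masks")
}

#' Lesion volumetry and mismatch
#'
#' Volumes are voxel counts times the voxel volume; the mismatch (penumbra)
#' volume is hypoperfusion minus core, and the mismatch ratio is
#' hypoperfusion over core. The ratio is `NA` for zero core; cases with
#' core volume of 3 mL or less are marked not `ratio_evaluable` (small cores
#' make the ratio singular) and are excluded from ratio agreement analyses.
#'
#' @param masks A [segment_lesions()] result (or a list with logical
#'   `hypoperfusion` and `core` arrays).
#' @param voxel_ml Voxel volume (mL); taken from `masks` when present.
#' @param ratio_min_core_ml Core volume (mL) above which the mismatch ratio
#'   is considered evaluable.
#' @return A one-row tibble: `hypoperfusion_ml`, `core_ml`, `mismatch_ml`,
#'   `mismatch_ratio`, `ratio_evaluable`.
#' @export
volumetry <- function(masks, voxel_ml = masks$voxel_ml, ratio_min_core_ml = 3) {
  if (!all(masks$hypoperfusion[masks$core])) {
    abort("invariant breach: core mask is not contained in hypoperfusion mask")
  }
  hypo <- sum(masks$hypoperfusion) * voxel_ml
  core <- sum(masks$core) * voxel_ml
  tibble::tibble(
    hypoperfusion_ml = hypo,
    core_ml = core,
    mismatch_ml = hypo - core,
    mismatch_ratio = if (core > 0) hypo / core else NA_real_,
    ratio_evaluable = core > ratio_min_core_ml
  )
}

#' DEFUSE-3 decision thresholds and margin zone
#'
#' Thrombectomy is appropriate when the core is smaller than 70 mL, the
#' mismatch volume greater than 15 mL and the mismatch ratio larger than
#' 1.8. To acknowledge measurement precision, cases within an error margin
#' of the thresholds (5 mL for volumes, 0.2 for the ratio: core 65--75 mL,
#' mismatch 10--20 mL, ratio 1.6--2.0) fall in an indistinct margin zone
#' and are excluded from decision comparisons.
#'
#' @param core_max,mismatch_min,ratio_min Decision thresholds.
#' @param volume_margin_ml,ratio_margin Half-widths of the margin zone.
#' @return A list of class `defuse3_thresholds`.
#' @export
defuse3_thresholds <- function(core_max = 70, mismatch_min = 15,
                               ratio_min = 1.8, volume_margin_ml = 5,
                               ratio_margin = 0.2) {
  structure(list(core_max = core_max, mismatch_min = mismatch_min,
                 ratio_min = ratio_min, volume_margin_ml = volume_margin_ml,
                 ratio_margin = ratio_margin),
            class = "defuse3_thresholds")
}

#' Hypothetical DEFUSE-3 treatment decision
#'
#' Vectorized over the rows of a lesion report: `treat` iff core < 70 mL and
#' mismatch > 15 mL and mismatch ratio > 1.8 (all strict). A hypoperfused
#' case with zero core has an undefined ratio; its ratio criterion is taken
#' as satisfied when hypoperfusion is positive (the limit as core -> 0).
#' `in_margin_zone` marks values within the measurement-precision margins of
#' any threshold (undefined ratios do not enter the ratio margin).
#'
#' @param report A data frame with columns `core_ml`, `mismatch_ml`,
#'   `hypoperfusion_ml`, `mismatch_ratio` (e.g. from [volumetry()]).
#' @param thresholds A [defuse3_thresholds()].
#' @return `report` with added columns `crit_core`, `crit_mismatch`,
#'   `crit_ratio`, `eligible` (`"treat"`/`"no_treat"`) and `in_margin_zone`.
#' @export
defuse3_decide <- function(report, thresholds = defuse3_thresholds()) {
  th <- thresholds
  crit_core <- report$core_ml < th$core_max
  crit_mismatch <- report$mismatch_ml > th$mismatch_min
  ratio <- report$mismatch_ratio
  crit_ratio <- ifelse(is.na(ratio), report$hypoperfusion_ml > 0,
                       ratio > th$ratio_min)
  vm <- th$volume_margin_ml
  rm_ <- th$ratio_margin
  in_margin <-
    (report$core_ml >= th$core_max - vm & report$core_ml <= th$core_max + vm) |
    (report$mismatch_ml >= th$mismatch_min - vm & report$mismatch_ml <= th$mismatch_min + vm) |
    (!is.na(ratio) & ratio >= th$ratio_min - rm_ & ratio <= th$ratio_min + rm_)
  dplyr::mutate(
    tibble::as_tibble(report),
    crit_core = crit_core,
    crit_mismatch = crit_mismatch,
    crit_ratio = crit_ratio,
    eligible = ifelse(crit_core & crit_mismatch & crit_ratio, "treat", "no_treat"),
    in_margin_zone = in_margin
  )
}

#' Confusion matrix of paired treatment decisions
#'
#' Compares decisions at a reduced sampling against the reference sampling.
#' Cases in the reference margin zone are excluded before counting; the
#' remaining pairs are tallied as TP (treat/treat), FN (treat at reference,
#' no-treat at test), FP and TN, with percentages normalized within each
#' reference row.
#'
#' @param reference,test Data frames from [defuse3_decide()] (equal length,
#'   same case order); `reference` must carry `in_margin_zone`.
#' @param exclude_margin Exclude reference margin-zone cases (default TRUE).
#' @return A list of class `ctp_confusion`: `counts` and `percent` (2 x 2
#'   matrices, reference in rows), `n_excluded_margin`, `n_counted`,
#'   `n_discordant` and `discordance_pct`.
#' @export
compare_decisions <- function(reference, test, exclude_margin = TRUE) {
  if (nrow(reference) != nrow(test)) {
    abort("`reference` and `test` must have the same number of cases")
  }
  keep <- if (exclude_margin) !reference$in_margin_zone else rep(TRUE, nrow(reference))
  r <- reference$eligible[keep]
  t_ <- test$eligible[keep]
  counts <- matrix(
    c(sum(r == "treat" & t_ == "treat"), sum(r == "treat" & t_ == "no_treat"),
      sum(r == "no_treat" & t_ == "treat"), sum(r == "no_treat" & t_ == "no_treat")),
    nrow = 2L, byrow = TRUE,
    dimnames = list(reference = c("treat", "no_treat"),
                    test = c("treat", "no_treat"))
  )
  rs <- rowSums(counts)
  percent <- 100 * counts / ifelse(rs > 0, rs, NA_real_)[row(counts)]
  n_disc <- counts[1L, 2L] + counts[2L, 1L]
  structure(
    list(counts = counts, percent = percent,
         n_excluded_margin = sum(!keep), n_counted = sum(keep),
         n_discordant = n_disc,
         discordance_pct = if (sum(keep) > 0) 100 * n_disc / sum(keep) else NA_real_),
    class = "ctp_confusion"
  )
}

#' @export
print.ctp_confusion <- function(x, ...) {
  cat("DEFUSE-3 decisions vs reference sampling",
      sprintf("(%d counted, %d excluded in margin zone)\n",
              x$n_counted, x$n_excluded_margin))
  m <- cbind(x$counts, round(x$percent, 1))
  colnames(m) <- c("+ (n)", "- (n)", "+ (%)", "- (%)")
  rownames(m) <- c("ref +", "ref -")
  print(m)
  cat(sprintf("discordant: %d (%.1f%%)\n", x$n_discordant, x$discordance_pct))
  invisible(x)
}

#' @export
tidy.ctp_confusion <- function(x, ...) {
  tibble::tibble(
    reference = rep(rownames(x$counts), each = 2L),
    test = rep(colnames(x$counts), 2L),
    cell = c("TP", "FN", "FP", "TN"),
    n = as.vector(t(x$counts)),
    pct = as.vector(t(x$percent))
  )
}

#' Dice overlap between two masks
#'
#' @param a,b Logical arrays of equal dimension.
#' @return The Dice coefficient `2|A n B| / (|A| + |B|)`; 1 when both are
#'   empty.
#' @export
dice <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
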