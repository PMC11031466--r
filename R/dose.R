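#' Reference acquisition protocols and doses
#'
#' The two Siemens CTP protocols of a multimodal stroke work-up (Somatom
#' Definition Flash: 27 frames every 1.5 s over 100 mm; Somatom Definition
#' 64 AS: 30 frames every 1.5 s over 90 mm; both 80 kV / 180 mAs) together
#' with the static non-contrast CT and CT-angiography reference rows.
#' Protocols can also be supplied from a YAML file with the same columns.
#'
#' @param file Optional path to a YAML file holding a list of protocol
#'   records; default returns the built-in protocols.
#' @return A tibble with columns `protocol`, `modality`, `kv`, `mas`,
#'   `n_frames`, `dt`, `z_coverage_mm`, `ctdi_vol` (mGy), `dlp` (mGy cm) and
#'   `effective_dose` (mSv).
#' @export
dose_protocols <- function(file = NULL) {
  if (!is.null(file)) {
    recs <- yaml::read_yaml(file)
    return(dplyr::bind_rows(lapply(recs, tibble::as_tibble)))
  }
  tibble::tribble(
    ~protocol, ~modality, ~kv, ~mas, ~n_frames, ~dt, ~z_coverage_mm, ~ctdi_vol, ~dlp, ~effective_dose,
    "somatom_flash", "ncct", NA, NA, NA, NA, 160, 45, 724, 1.59,
    "somatom_flash", "cta", NA, NA, NA, NA, 320, 6.5, 207, 1.13,
    "somatom_flash", "ctp", 80, 180, 27L, 1.5, 100, 210, 2103, 4.61,
    "somatom_definition_as", "ncct", NA, NA, NA, NA, 160, 45, 727, 1.59,
    "somatom_definition_as", "cta", NA, NA, NA, NA, 320, 7.7, 247, 1.35,
    "somatom_definition_as", "ctp", 80, 180, 30L, 1.5, 90, 259, 2331, 5.11
  )
}

#' Scale a CTP protocol dose to a reduced temporal sampling
#'
#' Doses for subsampled schemes are obtained by multiplying each dose
#' quantity by the proportion of retained timepoints,
#' `ceiling(n / factor) / n`. CTDIvol and DLP are rounded to the nearest
#' mGy / mGy cm and the effective dose to two decimals; the half-way rule
#' is configurable because printed vendor tables differ in boundary cells
#' (e.g. 129.5 mGy).
#'
#' @param protocol One or more CTP rows of [dose_protocols()] (must have
#'   `n_frames`).
#' @param factor Subsampling factor in `{1, 2, 3, 4}`.
#' @param rounding Half-way rule for rounding, see [round_mode()] modes:
#'   `"half-even"` (default), `"half-up"`, `"half-down"`, `"none"`.
#' @return The protocol rows with `factor`, `n_frames_retained`, effective
#'   `dt`, scaled `ctdi_vol`, `dlp`, `effective_dose` and the achieved
#'   `dose_reduction_pct`.
#' @export
scale_dose <- function(protocol, factor,
                       rounding = c("half-even", "half-up", "half-down", "none")) {
  rounding <- match.arg(rounding)
  if (!is.numeric(factor) || length(factor) != 1L || !(factor %in% 1:4)) {
    abort("`factor` must be one of 1, 2, 3, 4")
  }
  if (any(is.na(protocol$n_frames))) {
    abort("`protocol` must be dynamic (CTP) rows with `n_frames`")
  }
  factor <- as.integer(factor)
  n <- protocol$n_frames
  n_sub <- ceiling(n / factor)
  prop <- n_sub / n
  dplyr::mutate(
    tibble::as_tibble(protocol),
    factor = factor,
    n_frames_retained = as.integer(n_sub),
    dt = .data$dt * factor,
    ctdi_vol = round_mode(.data$ctdi_vol * prop, 0, rounding),
    dlp = round_mode(.data$dlp * prop, 0, rounding),
    effective_dose = round_mode(.data$effective_dose * prop, 2, rounding),
    dose_reduction_pct = 100 * (1 - prop)
  )
}

#' Dose table across protocols and subsampling factors
#'
#' Emits per-protocol, per-factor frame counts and frame-proportion-scaled
#' doses for the dynamic (CTP) rows, with the static NCCT/CTA reference rows
#' passed through unscaled.
#'
#' @param protocols A [dose_protocols()]-shaped tibble.
#' @param factors Integer subsampling factors to tabulate.
#' @inheritParams scale_dose
#' @return A tibble in long layout.
#' @export
dose_table <- function(protocols = dose_protocols(), factors = 1:4,
                       rounding = c("half-even", "half-up", "half-down", "none")) {
  rounding <- match.arg(rounding)
  static <- dplyr::filter(protocols, is.na(.data$n_frames))
  dynamic <- dplyr::filter(protocols, !is.na(.data$n_frames))
  scaled <- purrr::map_dfr(factors, function(f) scale_dose(dynamic, f, rounding))
  dplyr::bind_rows(
    dplyr::mutate(static, factor = NA_integer_,
                  n_frames_retained = NA_integer_,
                  dose_reduction_pct = NA_real_),
    scaled
  )
}
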