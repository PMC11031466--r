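#' Write a dynamic series as 4D NIfTI-1
#'
#' Data are stored in NIfTI `(x, y, z, t)` axis order with voxel sizes and
#' the frame interval in `pixdim`.
#'
#' @param series A [ctp_series()].
#' @param path Output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_series_nifti <- function(series, path) {
  stopifnot(inherits(series, "ctp_series"))
  arr <- aperm(series$data, c(4L, 3L, 2L, 1L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rev(series$voxel_mm), series$dt)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a dynamic series from 4D NIfTI-1
#'
#' @param path NIfTI file written by [write_series_nifti()] (or any 4D
#'   `(x, y, z, t)` NIfTI).
#' @param dt Frame interval override (s); default taken from `pixdim`.
#' @return A [ctp_series()].
#' @export
read_series_nifti <- function(path, dt = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L) abort("expected a 4D NIfTI series")
  pd <- RNifti::pixdim(img)
  ctp_series(aperm(unclass(img), c(4L, 3L, 2L, 1L)),
             dt = dt %||% pd[4L],
             voxel_mm = rev(pd[1:3]))
}

## One 3D map volume to NIfTI, matching the series axis convention.
write_volume_nifti <- function(vol, voxel_mm, path) {
  arr <- aperm(vol, c(3L, 2L, 1L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(voxel_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write perfusion maps as 3D NIfTI with a JSON sidecar
#'
#' Writes one volume per map (`cbf_rel`, `cbv_rel`, `tmax`, `mtt`) plus a
#' sidecar recording the sampling interval, regularization, AIF source,
#' contralateral side and software version.
#'
#' @param maps A [compute_maps()] result.
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix.
#' @return `dir`, invisibly.
#' @export
write_maps_nifti <- function(maps, dir, prefix = "perfusion") {
  stopifnot(inherits(maps, "ctp_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("cbf_rel", "cbv_rel", "tmax", "mtt")) {
    write_volume_nifti(maps[[nm]], maps$voxel_mm,
                       file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm)))
  }
  sidecar <- list(
    dt_s = maps$dt,
    lambda_rel = maps$config$lambda_rel,
    penalty = maps$config$penalty,
    smooth_fwhm_vox = maps$config$smooth_fwhm_vox,
    aif_source = maps$aif$source,
    contralateral = maps$contralateral,
    software = paste0("ctperfusion ", utils::packageVersion("ctperfusion"))
  )
  jsonlite::write_json(sidecar, file.path(dir, paste0(prefix, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write a phantom case to disk
#'
#' Series and ground-truth maps as NIfTI, masks as NIfTI, the ground-truth
#' parameter table as CSV and the specification as YAML.
#'
#' @param phantom A [build_phantom()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "ctp_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_series_nifti(phantom$series, file.path(dir, "series.nii.gz"))
  vm <- phantom$spec$voxel_mm
  for (nm in names(phantom$truth)) {
    write_volume_nifti(phantom$truth[[nm]], vm,
                       file.path(dir, sprintf("truth_%s.nii.gz", nm)))
  }
  for (nm in names(phantom$masks)) {
    write_volume_nifti(phantom$masks[[nm]] * 1, vm,
                       file.path(dir, sprintf("mask_%s.nii.gz", nm)))
  }
  vml <- voxel_volume_ml(vm)
  utils::write.csv(
    data.frame(
      quantity = c("core_ml", "hypoperfusion_ml", "brain_ml", "seed"),
      value = c(sum(phantom$masks$core) * vml,
                sum(phantom$masks$hypoperfusion) * vml,
                sum(phantom$masks$brain) * vml,
                phantom$seed)
    ),
    file.path(dir, "ground_truth.csv"), row.names = FALSE
  )
  sp <- phantom$spec
  sp_plain <- rapply(unclass(sp), unclass, how = "replace")
  yaml::write_yaml(sp_plain, file.path(dir, "phantom_spec.yaml"))
  invisible(dir)
}
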