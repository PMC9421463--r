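#' Read a 3D NIfTI volume
#'
#' Thin wrapper around RNifti that returns the package's [volume_image()]
#' container with voxel sizes and axis orientation taken from the header.
#'
#' @param path Path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  nii <- RNifti::readNifti(path)
  d <- dim(nii)
  if (length(d) > 3L) {
    if (all(d[-(1:3)] == 1L)) d <- d[1:3] else stop("expected a 3D volume", call. = FALSE)
  }
  vox <- RNifti::pixdim(nii)[1:3]
  orient <- tryCatch(RNifti::orientation(nii), error = function(e) "RAS")
  volume_image(array(as.numeric(nii), d), voxel_size = vox, orientation = orient)
}

#' Write a 3D volume to NIfTI
#'
#' @param img A [volume_image()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(img, path) {
  stopifnot(inherits(img, "volume_image"))
  nii <- RNifti::asNifti(img$data, pixdim = img$voxel_size)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read tissue probability maps from NIfTI files
#'
#' @param gm_path,wm_path,csf_path Paths to the GM/WM/CSF probability maps.
#' @param ... Passed to [tissue_maps()] (thresholds, explicit masks).
#' @return A [tissue_maps()].
#' @export
read_tissue_maps <- function(gm_path, wm_path, csf_path, ...) {
  tissue_maps(gm = read_volume(gm_path)$data,
              wm = read_volume(wm_path)$data,
              csf = read_volume(csf_path)$data, ...)
}

#' Write a rigid-body motion trace as plain text
#'
#' Six whitespace-delimited columns (`tx ty tz` in mm, `rx ry rz` in
#' radians), one row per volume, with a header comment declaring order and
#' units.
#'
#' @param trace Motion tibble (see [framewise_displacement()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_motion_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# tx ty tz (mm) rx ry rz (radians), one row per volume", con)
  utils::write.table(as.data.frame(trace)[, c("tx", "ty", "tz", "rx", "ry", "rz")],
                     con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Append tidy QC records to a cohort feature TSV
#'
#' Widens the records (one row per scan) and appends to `path`, writing a
#' header if the file does not exist; a JSON sidecar per scan mirroring the
#' record can be written alongside.
#'
#' @param records Tidy QC records (from the feature extractors).
#' @param path TSV path.
#' @param json_dir Optional directory for per-scan JSON sidecars.
#' @return Invisibly, `path`.
#' @export
append_qc_records <- function(records, path, json_dir = NULL) {
  wide <- qc_records_to_cohort(records)
  readr::write_tsv(wide, path, append = file.exists(path))
  if (!is.null(json_dir)) {
    dir.create(json_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in unique(records$scan_id)) {
      rec <- records[records$scan_id == id, ]
      jsonlite::write_json(
        list(scan_id = id, modality = rec$modality[1],
             features = as.list(stats::setNames(rec$value, rec$feature)),
             domains = as.list(stats::setNames(rec$domain, rec$feature))),
        file.path(json_dir, paste0(id, "_qc.json")), auto_unbox = TRUE)
    }
  }
  invisible(path)
}

#' Read a cohort feature table from TSV
#'
#' @param path TSV path with one row per scan.
#' @return A tibble.
#' @export
read_cohort_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a review batch and its sealed key
#'
#' The batch file carries only position and scan id (statuses withheld for
#' blinding); the key file maps position to status for post-hoc unblinding.
#'
#' @param batch A `review_batch` from [build_review_batch()].
#' @param dir Output directory.
#' @return Invisibly, the two paths.
#' @export
write_review_batch <- function(batch, dir) {
  stopifnot(inherits(batch, "review_batch"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bp <- file.path(dir, "review_batch.tsv")
  kp <- file.path(dir, "review_key_sealed.tsv")
  readr::write_tsv(batch$batch, bp)
  readr::write_tsv(batch$key, kp)
  invisible(c(bp, kp))
}
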