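#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers around RNifti with descriptive errors. Floating-point
#' maps are stored as `float32`, label grids as `int16`.
#'
#' @param volume Numeric or integer array.
#' @param path File path (`.nii` or `.nii.gz`).
#' @param spacing_mm Voxel spacing written into the header.
#' @param datatype NIfTI storage type.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns
#'   an array.
#' @export
write_volume <- function(volume, path, spacing_mm = c(2, 2, 2),
                         datatype = "float") {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- spacing_mm[seq_len(min(3L, length(dim(volume))))]
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("volume file not found: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    stopf("cannot read NIfTI volume %s: %s", path,
                          conditionMessage(e))
                  },
                  warning = function(w) {
                    stopf("cannot read NIfTI volume %s: %s", path,
                          conditionMessage(w))
                  })
  as.array(img)
}

#' Write a phantom or fitted map set as NIfTI volumes with a JSON legend
#'
#' Writes `<prefix>_t1.nii.gz`, `_t2.nii.gz`, `_pd.nii.gz`, `_b1.nii.gz`
#' (float, ms / percent / ratio) and `<prefix>_labels.nii.gz` (integer)
#' with a `<prefix>_labels.json` legend sidecar.
#'
#' @param maps A `ground_truth_maps` object.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_qmaps <- function(maps, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- maps$spacing_mm %||% c(2, 2, 2)
  paths <- c(
    t1 = file.path(dir, paste0(prefix, "_t1.nii.gz")),
    t2 = file.path(dir, paste0(prefix, "_t2.nii.gz")),
    pd = file.path(dir, paste0(prefix, "_pd.nii.gz")),
    b1 = file.path(dir, paste0(prefix, "_b1.nii.gz")),
    labels = file.path(dir, paste0(prefix, "_labels.nii.gz"))
  )
  write_volume(maps$t1, paths[["t1"]], sp)
  write_volume(maps$t2, paths[["t2"]], sp)
  write_volume(maps$pd, paths[["pd"]], sp)
  write_volume(maps$b1, paths[["b1"]], sp)
  write_volume(maps$labels, paths[["labels"]], sp, datatype = "int16")
  legend_path <- file.path(dir, paste0(prefix, "_labels.json"))
  jsonlite::write_json(as.list(maps$legend), legend_path, auto_unbox = TRUE)
  invisible(c(paths, legend = legend_path))
}

#' Write subject scores as a flat CSV
#'
#' One row per region per subject/modality/rater plus a `total` row,
#' in deterministic order.
#'
#' @param score_table Data frame with columns `subject_id`, `modality`,
#'   `rater`, `region`, `hemisphere_used`, `score`, `total`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(score_table, path) {
  utils::write.csv(score_table, path, row.names = FALSE)
  invisible(path)
}
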