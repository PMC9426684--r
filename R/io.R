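# Portable on-disk study representation: NIfTI volumes plus a JSON sidecar
# with trigger times, spacing, label and the true misalignment (phantom
# ground truth).

affine_to_list <- function(p) {
  list(translation = p$translation, rotation = p$rotation,
       scale = p$scale, shear = p$shear)
}

affine_from_list <- function(l) {
  affine_params(translation = unlist(l$translation), rotation = l$rotation,
                scale = unlist(l$scale), shear = l$shear)
}

#' Write a phantom study to disk
#'
#' Emits `cine.nii.gz` (frames stacked along the third axis),
#' `masks.nii.gz`, `lge.nii.gz`, `lge_mask.nii.gz` and a `study.json`
#' sidecar (trigger times, spacing, label, true misalignment, identifiers).
#'
#' @param study one element of [generate_cohort()]`$studies`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the sidecar path.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(study$cine$frames[[1]])
  stack <- function(lst) {
    a <- array(0, c(d, length(lst)))
    for (i in seq_along(lst)) a[, , i] <- lst[[i]]
    a
  }
  RNifti::writeNifti(RNifti::asNifti(stack(study$cine$frames)),
                     file.path(dir, "cine.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(stack(study$masks)),
                     file.path(dir, "masks.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(study$lge$image),
                     file.path(dir, "lge.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(study$lge$true_mask),
                     file.path(dir, "lge_mask.nii.gz"))
  sidecar <- list(
    subject_id = study$cine$subject_id,
    slice_id = study$cine$slice_id,
    trigger_times_ms = study$cine$trigger_times_ms,
    pixel_spacing_mm = study$cine$pixel_spacing_mm,
    lge_trigger_time_ms = study$lge$trigger_time_ms,
    label = study$label,
    true_misalignment = affine_to_list(study$lge$true_misalignment))
  path <- file.path(dir, "study.json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a study written by [write_study()]
#'
#' @param dir study directory.
#' @return List with `cine` ([cine_sequence()]), `masks`, `lge`
#'   (`lge_record`) and `label`.
#' @export
read_study <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "study.json"),
                              simplifyVector = TRUE)
  unstack <- function(a) lapply(seq_len(dim(a)[3]), function(i)
    matrix(a[, , i], dim(a)[1], dim(a)[2]))
  cine_arr <- as.array(RNifti::readNifti(file.path(dir, "cine.nii.gz")))
  mask_arr <- as.array(RNifti::readNifti(file.path(dir, "masks.nii.gz")))
  lge_img <- as.array(RNifti::readNifti(file.path(dir, "lge.nii.gz")))
  lge_mask <- as.array(RNifti::readNifti(file.path(dir, "lge_mask.nii.gz")))
  cine <- cine_sequence(unstack(cine_arr), side$trigger_times_ms,
                        side$pixel_spacing_mm, side$subject_id, side$slice_id)
  masks <- lapply(unstack(mask_arr), function(m) matrix(as.integer(m), nrow(m)))
  lge <- structure(list(image = matrix(lge_img, nrow(lge_img)),
                        trigger_time_ms = side$lge_trigger_time_ms,
                        true_mask = matrix(as.integer(lge_mask), nrow(lge_mask)),
                        true_misalignment = affine_from_list(side$true_misalignment)),
                   class = "lge_record")
  list(cine = cine, masks = masks, lge = lge, label = side$label)
}
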