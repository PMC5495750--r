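## File interchange: NIfTI volumes, BIDS-style events tables, PNG stimuli.

#' Write / read a BOLD dataset directory
#'
#' Writes `bold.nii.gz` (4D), `mask.nii.gz`, a BIDS-style `events.tsv` and
#' a JSON sidecar with repetition time, voxel size and seed; planted
#' ground-truth ROIs are written as additional NIfTI masks with their
#' target RDMs as labeled CSV.
#'
#' @param data a `bold_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bold_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(data$data,
                                     pixdim = c(rep(data$voxel_size, 3), data$TR)),
                     file.path(dir, "bold.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(data$mask), dim(data$mask)),
                                     pixdim = rep(data$voxel_size, 3)),
                     file.path(dir, "mask.nii.gz"))
  write_events_tsv(data$events, file.path(dir, "events.tsv"))
  jsonlite::write_json(list(RepetitionTime = data$TR,
                            VoxelSize = data$voxel_size,
                            SubjectID = data$subject_id,
                            Seed = data$seed,
                            GroundTruthEffects = names(data$ground_truth)),
                       file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(data$ground_truth)) {
    gt <- data$ground_truth[[nm]]
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(gt$roi), dim(gt$roi)),
                                       pixdim = rep(data$voxel_size, 3)),
                       file.path(dir, sprintf("truth_%s_roi.nii.gz", nm)))
    write_rdm_csv(gt$target, file.path(dir, sprintf("truth_%s_rdm.csv", nm)))
  }
  invisible(dir)
}

#' @rdname write_bold_dataset
#' @export
read_bold_dataset <- function(dir) {
  vol <- RNifti::readNifti(file.path(dir, "bold.nii.gz"))
  mask <- RNifti::readNifti(file.path(dir, "mask.nii.gz"))
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"), simplifyVector = TRUE)
  structure(list(data = unclass(vol)[, , , , drop = FALSE],
                 TR = meta$RepetitionTime,
                 mask = array(unclass(mask) > 0, dim(mask)),
                 events = read_events_tsv(file.path(dir, "events.tsv")),
                 voxel_size = meta$VoxelSize,
                 affine = default_affine(dim(vol)[1:3], meta$VoxelSize),
                 ground_truth = list(), seed = meta$Seed,
                 subject_id = meta$SubjectID),
            class = "bold_dataset")
}

#' Write / read a BIDS-style events table
#'
#' @param events event data frame (columns `onset`, `duration`,
#'   `trial_type`, ...).
#' @param path path to a `.tsv` file.
#' @return The path (write) or the events data frame (read).
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a searchlight map as NIfTI
#'
#' @param map a `searchlight_map` (or `rsa_group` group map).
#' @param path output `.nii.gz` path.
#' @param voxel_size voxel size in mm.
#' @return `path`, invisibly.
#' @export
write_searchlight_map <- function(map, path, voxel_size = 3) {
  vol <- if (inherits(map, "rsa_group")) map$group_map else map$values
  RNifti::writeNifti(RNifti::asNifti(vol, pixdim = rep(voxel_size, 3)), path)
  invisible(path)
}

#' Write a rendered stimulus as 8-bit grayscale PNG
#'
#' @param image a `stimulus_image`.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_stimulus_png <- function(image, path) {
  px <- pmin(pmax(image$pixels, 0), 1)
  png::writePNG(px, path)
  invisible(path)
}
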