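#' Write an image stack to a directory of NIfTI files
#'
#' Writes one 4-D NIfTI for the measurement volumes (`volumes.nii.gz`), the
#' B1+ ratio map (`b1_ratio.nii.gz`), the mask (`mask.nii.gz`), and, when the
#' stack carries a simulated ground truth, the true T1/T2/M0 maps
#' (`truth_T1.nii.gz`, ...). A JSON sidecar (`stack.json`) records the
#' protocol, noise SD, and voxel size.
#'
#' @param stack An [image_stack()].
#' @param dir Output directory (created if missing).
#' @param voxel_size Voxel size in mm written to the NIfTI headers; taken
#'   from an attached phantom truth when available.
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir, voxel_size = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- attr(stack, "truth")
  if (is.null(voxel_size))
    voxel_size <- if (!is.null(truth)) truth$voxel_size else c(1, 1, 1)
  wr <- function(x, name) {
    img <- RNifti::asNifti(x)
    RNifti::pixdim(img) <- c(voxel_size, rep(1, length(dim(x)) - 3))[
      seq_len(length(dim(x)))]
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  wr(stack$volumes, "volumes")
  wr(stack$b1_ratio, "b1_ratio")
  wr(stack$mask, "mask")
  if (!is.null(truth)) {
    wr(truth$T1, "truth_T1")
    wr(truth$T2, "truth_T2")
    wr(truth$M0, "truth_M0")
  }
  protocol <- attr(stack, "protocol")
  sidecar <- list(voxel_size = voxel_size,
                  sigma = attr(stack, "sigma"),
                  n_measurements = dim(stack$volumes)[4],
                  protocol = if (!is.null(protocol))
                    list(name = protocol$name, TR = protocol$TR,
                         k = protocol$k, T_FS = protocol$T_FS,
                         measurements = protocol$measurements))
  jsonlite::write_json(sidecar, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an image stack written by [write_stack()]
#'
#' @param dir Directory containing `volumes.nii.gz`, `b1_ratio.nii.gz`, and
#'   `mask.nii.gz`.
#' @return An [image_stack()].
#' @export
read_stack <- function(dir) {
  rd <- function(name) {
    x <- RNifti::readNifti(file.path(dir, paste0(name, ".nii.gz")))
    array(as.numeric(x), dim(x))
  }
  image_stack(rd("volumes"), b1_ratio = rd("b1_ratio"), mask = rd("mask"))
}

#' Write fitted parameter maps as NIfTI files plus a CSV ROI summary
#'
#' Writes `T1.nii.gz`, `T2.nii.gz`, `M0.nii.gz`, `residual_norm.nii.gz`,
#' `converged.nii.gz`, and `at_bound.nii.gz` to `dir`, plus `roi_summary.csv`
#' (from [roi_summary()]) and a JSON metadata sidecar.
#'
#' @param maps A [fit_volume()] result.
#' @param dir Output directory.
#' @param voxel_size Voxel size (mm) for the NIfTI headers.
#' @return `dir`, invisibly.
#' @export
write_parameter_maps <- function(maps, dir, voxel_size = c(1, 1, 1)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (name in c("T1", "T2", "M0", "residual_norm")) {
    img <- RNifti::asNifti(maps[[name]])
    RNifti::pixdim(img) <- voxel_size
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  for (name in c("converged", "at_bound")) {
    img <- RNifti::asNifti(array(as.integer(maps[[name]]), dim(maps[[name]])))
    RNifti::pixdim(img) <- voxel_size
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  write.csv(roi_summary(maps), file.path(dir, "roi_summary.csv"),
            row.names = FALSE)
  md <- maps$metadata
  jsonlite::write_json(list(model = md$model, b1_sigma = md$b1_sigma,
                            n_voxels = md$n_voxels,
                            protocol_name = md$protocol$name),
                       file.path(dir, "maps.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
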