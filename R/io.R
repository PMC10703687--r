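# Volume I/O and provenance records shared by the command-line tools.

#' Write a volume as NIfTI
#'
#' @param vol numeric array (3D).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing_mm voxel spacing (scalar or length 3).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, spacing_mm = 1) {
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path input path.
#' @return numeric array with attribute `spacing_mm`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  structure(as.array(img), spacing_mm = RNifti::pixdim(img))
}

#' Write a machine-readable provenance record
#'
#' Records the call's inputs, constants and seeds alongside any run
#' artifact, so every number is re-derivable.
#'
#' @param path output JSON path.
#' @param ... named fields to record.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, ...) {
  rec <- list(
    package = "gradepi",
    version = as.character(utils::packageVersion("gradepi")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    ...)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
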