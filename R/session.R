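#' A single subject's 4D BOLD session
#'
#' Wraps a 4D array (x, y, z, acquisition) with its repetition time, voxel
#' size and cohort metadata. Acquisition indices are 1-based throughout the
#' user-facing API (the first baseline volume is acquisition 1).
#'
#' @param data 4D numeric array, dimensions (x, y, z, t).
#' @param tr_seconds repetition time between volumes, seconds.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @param subject_id character scalar.
#' @param treatment treatment-group label, e.g. "vehicle".
#' @return An object of class `bold_session`.
#' @export
bold_session <- function(data, tr_seconds, voxel_size,
                         subject_id = "subject", treatment = "vehicle") {
  if (length(dim(data)) != 4L)
    stop("data must be a 4D array (x, y, z, t)")
  tr_seconds <- as.numeric(tr_seconds)
  if (!is.finite(tr_seconds) || tr_seconds <= 0)
    stop("tr_seconds must be positive")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three strictly positive lengths (mm)")
  structure(list(data = data, tr_seconds = tr_seconds,
                 voxel_size = voxel_size,
                 subject_id = as.character(subject_id),
                 treatment = as.character(treatment)),
            class = "bold_session")
}

#' @export
print.bold_session <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "BOLD session '%s' (%s): %d x %d x %d voxels, %d acquisitions, TR %.3g s\n",
    x$subject_id, x$treatment, d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

n_acquisitions <- function(session) dim(session$data)[4]

#' Read a 4D BOLD session from a NIfTI-1 file
#'
#' @param path NIfTI file. Voxel sizes and TR are read from `pixdim` unless
#'   overridden.
#' @param subject_id,treatment metadata attached to the session.
#' @param tr_seconds override for the repetition time (seconds); defaults to
#'   the 4th pixdim entry of the file.
#' @return A [bold_session()].
#' @export
read_session <- function(path, subject_id = "subject",
                         treatment = "vehicle", tr_seconds = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim(arr))   # drop image attributes
  if (length(dim(arr)) != 4L)
    stop("expected a 4D volume in ", path)
  pd <- RNifti::pixdim(img)
  if (is.null(tr_seconds)) {
    tr_seconds <- if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0)
      pd[4] else stop("TR not present in header; pass tr_seconds")
  }
  bold_session(arr, tr_seconds, pd[1:3], subject_id, treatment)
}

#' Write a BOLD session as NIfTI-1
#'
#' @param session a [bold_session()].
#' @param path output path (.nii or .nii.gz).
#' @return Invisibly, `path`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "bold_session"))
  img <- RNifti::asNifti(session$data)
  RNifti::pixdim(img) <- c(session$voxel_size, session$tr_seconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# acquisition index (1-based) -> minutes since scan start
acq_minutes <- function(k, tr_seconds) (k - 1) * tr_seconds / 60
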