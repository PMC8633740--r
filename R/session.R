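#' BOLD session container
#'
#' One subject-session 4D resting-state time series on a voxel grid, with its
#' mask, repetition time and provenance labels. Data units are arbitrary BOLD
#' units; motion parameters, when present, are a T x 6 matrix of 3
#' translations (mm) and 3 rotations (radians).
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param mask 3D logical/0-1 array matching the spatial dimensions.
#' @param tr_seconds repetition time in seconds (positive).
#' @param subject_id,condition provenance labels; `condition` is typically
#'   `"placebo"` or `"drug"`.
#' @param motion_params optional T x 6 numeric matrix.
#' @return object of class `bold_session`.
#' @export
bold_session <- function(data, mask, tr_seconds, subject_id = NA_character_,
                         condition = NA_character_, motion_params = NULL) {
  stopifnot(length(dim(data)) == 4L, length(dim(mask)) == 3L)
  if (!all(dim(data)[1:3] == dim(mask)))
    stop("mask shape does not match the spatial dimensions of data")
  if (dim(data)[4] < 2L) stop("a session needs at least 2 volumes")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) stop("tr_seconds must be > 0")
  if (!is.null(motion_params)) {
    motion_params <- as.matrix(motion_params)
    if (nrow(motion_params) != dim(data)[4] || ncol(motion_params) != 6L)
      stop("motion_params must be T x 6")
  }
  structure(
    list(data = data, mask = array(as.logical(mask), dim(mask)),
         tr_seconds = tr_seconds, subject_id = as.character(subject_id),
         condition = as.character(condition), motion_params = motion_params),
    class = "bold_session")
}

#' @export
print.bold_session <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf(
    "<bold_session> subject %s, condition %s\n  grid %s, %d volumes, TR %.3g s, %d mask voxels%s\n",
    x$subject_id, x$condition, paste(dm[1:3], collapse = "x"), dm[4],
    x$tr_seconds, sum(x$mask),
    if (is.null(x$motion_params)) "" else ", motion params present"))
  invisible(x)
}

#' @export
dim.bold_session <- function(x) dim(x$data)

n_volumes <- function(session) dim(session$data)[4]

#' Session length in seconds
#'
#' @param session a [bold_session()].
#' @return number of volumes times the repetition time.
#' @export
session_duration <- function(session) n_volumes(session) * session$tr_seconds

#' Write / read a BOLD session as NIfTI-1
#'
#' The 4D series and the mask are written as sibling NIfTI files; labels and
#' the motion table travel in a JSON sidecar (`<stem>.json`) and a
#' whitespace-delimited 6-column text file (`<stem>_motion.txt`).
#'
#' @param session a [bold_session()].
#' @param stem output path stem (no extension); `gz = TRUE` appends `.nii.gz`.
#' @param gz compress the images.
#' @return the data-image path, invisibly.
#' @export
write_session <- function(session, stem, gz = FALSE) {
  ext <- if (gz) ".nii.gz" else ".nii"
  write_nifti(session$data, paste0(stem, ext), tr_seconds = session$tr_seconds)
  write_nifti(array(as.numeric(session$mask), dim(session$mask)),
              paste0(stem, "_mask", ext))
  jsonlite::write_json(
    list(subject_id = session$subject_id, condition = session$condition,
         tr_seconds = session$tr_seconds),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(session$motion_params))
    write.table(session$motion_params, paste0(stem, "_motion.txt"),
                row.names = FALSE, col.names = FALSE)
  invisible(paste0(stem, ext))
}

#' @rdname write_session
#' @export
read_session <- function(stem, gz = FALSE) {
  ext <- if (gz) ".nii.gz" else ".nii"
  data <- read_nifti(paste0(stem, ext))
  mask <- read_nifti(paste0(stem, "_mask", ext))
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  mp <- NULL
  mp_path <- paste0(stem, "_motion.txt")
  if (file.exists(mp_path)) mp <- as.matrix(read.table(mp_path))
  bold_session(data, array(mask > 0.5, dim(mask)), meta$tr_seconds,
               meta$subject_id, meta$condition, mp)
}
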