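#' Construct a CT volume
#'
#' A `ct_volume` is a 3-D scalar field in Hounsfield units together with its
#' physical voxel spacing and a respiratory-phase label.  Voxels are indexed
#' `[slice, row, col]`; slice 1 is the most superior slice (lung apex).
#'
#' @param voxels 3-D numeric array of Hounsfield units, `[slice, row, col]`.
#' @param spacing numeric length-3, `c(dz, dy, dx)` in mm, all positive.
#' @param phase `"inspiration"` or `"expiration"`.
#' @param subject_id opaque subject identifier.
#' @return an object of class `ct_volume`.
#' @seealso [lung_mask()], [read_volume()], [write_volume()]
#' @export
ct_volume <- function(voxels, spacing, phase = c("inspiration", "expiration"),
                      subject_id = "subject") {
  phase <- match.arg(phase)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    abort("voxels must be a 3-D array [slice, row, col]", "airtrapcad_input_error")
  if (any(dim(voxels) < 1L))
    abort("all three dimensions must be >= 1", "airtrapcad_input_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("spacing must be 3 strictly positive values (dz, dy, dx) in mm",
          "airtrapcad_input_error")
  if (any(!is.finite(voxels)))
    abort("voxel values must be finite Hounsfield units", "airtrapcad_input_error")
  structure(list(voxels = voxels, spacing = spacing, phase = phase,
                 subject_id = as.character(subject_id)),
            class = "ct_volume")
}

#' Construct a binary lung mask
#'
#' A `lung_mask` shares the shape, spacing and phase of the `ct_volume` it was
#' derived from; voxel values are 0/1.
#'
#' @inheritParams ct_volume
#' @param voxels 3-D array with values in \{0, 1\} (logical accepted).
#' @return an object of class `lung_mask`.
#' @export
lung_mask <- function(voxels, spacing, phase = c("inspiration", "expiration"),
                      subject_id = "subject") {
  phase <- match.arg(phase)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    abort("voxels must be a 3-D array [slice, row, col]", "airtrapcad_input_error")
  if (is.logical(voxels)) {
    v <- voxels
    storage.mode(v) <- "integer"
  } else {
    v <- voxels
    if (!all(v %in% c(0, 1)))
      abort("mask values must be 0 or 1", "airtrapcad_input_error")
    storage.mode(v) <- "integer"
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("spacing must be 3 strictly positive values (dz, dy, dx) in mm",
          "airtrapcad_input_error")
  structure(list(voxels = v, spacing = spacing, phase = phase,
                 subject_id = as.character(subject_id)),
            class = "lung_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %s, %s: %d x %d x %d voxels, spacing (%g, %g, %g) mm, HU [%g, %g]\n",
              x$subject_id, x$phase, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.lung_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<lung_mask> %s, %s: %d x %d x %d voxels, spacing (%g, %g, %g) mm, %d foreground voxels\n",
              x$subject_id, x$phase, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3], sum(x$voxels)))
  invisible(x)
}

#' Read a CT volume or mask from NIfTI
#'
#' Reads a NIfTI-1 file (`.nii` / `.nii.gz`) into the package's axis
#' convention: slices ordered superior to inferior (slice 1 = apex) regardless
#' of on-disk order, which is inferred from the NIfTI orientation metadata.
#' Values are returned as stored (for CT exports the scanner's rescale
#' slope/intercept has already been applied by the NIfTI writer, so values are
#' Hounsfield units).
#'
#' DICOM series directories are not supported; convert to NIfTI first (e.g.
#' with `dcm2niix`).
#'
#' @param path path to a NIfTI file.
#' @param phase respiratory phase label to attach.
#' @param subject_id subject identifier to attach.
#' @param mask logical; read as a binary [lung_mask()] instead of a
#'   [ct_volume()].
#' @return a `ct_volume` (or `lung_mask` when `mask = TRUE`).
#' @export
read_volume <- function(path, phase = c("inspiration", "expiration"),
                        subject_id = "subject", mask = FALSE) {
  phase <- match.arg(phase)
  if (!file.exists(path))
    abort(sprintf("cannot read '%s': no such file or directory", path),
          "airtrapcad_input_error")
  if (dir.exists(path))
    abort(paste0("'", path, "' is a directory: DICOM series input is not ",
                 "supported; convert the series to NIfTI first"),
          "airtrapcad_format_error")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    abort(sprintf("cannot read '%s' as NIfTI: %s", path,
                                  conditionMessage(e)),
                          "airtrapcad_format_error"))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    abort(sprintf("'%s': expected a 3-D volume, got %d dimensions", path,
                  length(dim(arr))),
          "airtrapcad_format_error")
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    abort(sprintf("'%s': missing or invalid spacing metadata (pixdim)", path),
          "airtrapcad_metadata_error")
  # on disk: [x, y, z]; orientation string's 3rd letter says which way z points
  orient <- tryCatch(RNifti::orientation(img), error = function(e) "RAS")
  voxels <- aperm(arr, c(3L, 2L, 1L))            # -> [z, y, x] = [slice, row, col]
  if (!is.character(orient) || nchar(orient) != 3L) orient <- "RAS"
  if (substr(orient, 3L, 3L) == "S")             # z index increases superior
    voxels <- voxels[rev(seq_len(dim(voxels)[1])), , , drop = FALSE]
  spacing <- c(pd[3], pd[2], pd[1])
  if (mask) lung_mask(round(voxels), spacing, phase, subject_id)
  else ct_volume(voxels, spacing, phase, subject_id)
}

#' Write a CT volume or mask to NIfTI
#'
#' Volumes are written as double precision (bit-exact round trip through
#' [read_volume()]); masks as unsigned 8-bit.  Spacing is encoded in the
#' NIfTI header, and slices are stored inferior-to-superior with matching
#' orientation metadata so that readers honouring the header recover the
#' package's superior-first ordering.
#'
#' @param v a [ct_volume()] or [lung_mask()].
#' @param path output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  if (!inherits(v, c("ct_volume", "lung_mask")))
    abort("v must be a ct_volume or lung_mask", "airtrapcad_input_error")
  if (!dir.exists(dirname(path)))
    abort(sprintf("cannot write '%s': parent directory does not exist", path),
          "airtrapcad_io_error")
  vox <- v$voxels
  # store inferior -> superior (the conventional +S direction)
  vox <- vox[rev(seq_len(dim(vox)[1])), , , drop = FALSE]
  arr <- aperm(vox, c(3L, 2L, 1L))               # [col, row, slice] = [x, y, z]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(v$spacing[3], v$spacing[2], v$spacing[1])
  dt <- if (inherits(v, "lung_mask")) "uint8" else "double"
  tryCatch(RNifti::writeNifti(img, path, datatype = dt),
           error = function(e)
             abort(sprintf("cannot write '%s': %s", path, conditionMessage(e)),
                   "airtrapcad_io_error"))
  invisible(path)
}
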