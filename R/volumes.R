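#' Organ label codes
#'
#' Voxel label conventions used throughout the package: 0 background,
#' 1 prostate, 2 rectum, 3 air.
#'
#' @format Named integer vector.
#' @export
ORGAN_LABELS <- c(background = 0L, prostate = 1L, rectum = 2L, air = 3L)

#' Construct a label volume
#'
#' A `label_volume` is a 3D integer array of organ labels on an anisotropic
#' voxel grid.  Axis order is (slice k, row j, column i) with the fixed
#' anatomical convention: row index increases anterior to posterior, column
#' index increases patient-right to patient-left, slice index increases apex
#' to base.  Voxel centres sit at `index * spacing` with 0-based indices, so
#' physical coordinates are voxel-centre based.
#'
#' @param voxels 3D array of integer labels (values must be in
#'   `ORGAN_LABELS`).
#' @param spacing Numeric length-3 `(dz, dy, dx)` voxel spacing in mm, all
#'   positive.
#' @return An object of class `label_volume` with elements `voxels` and
#'   `spacing`.
#' @seealso [read_label_volume()], [mask_from_contours()]
#' @export
label_volume <- function(voxels, spacing) {
  if (length(dim(voxels)) != 3L)
    dd_stop("`voxels` must be a 3D array", "dwidistort_format_error")
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    dd_stop("`spacing` must be 3 positive finite values (dz, dy, dx)",
            "dwidistort_format_error")
  v <- as.vector(voxels)
  if (!all(is_wholenumber(v)))
    dd_stop("label volume contains non-integer voxel values",
            "dwidistort_label_error")
  voxels <- array(as.integer(round(voxels)), dim = dim(voxels))
  bad <- setdiff(unique(as.vector(voxels)), unname(ORGAN_LABELS))
  if (length(bad))
    dd_stop(sprintf("invalid voxel label(s): %s (allowed: %s)",
                    paste(bad, collapse = ", "),
                    paste(ORGAN_LABELS, collapse = ", ")),
            "dwidistort_label_error")
  structure(list(voxels = voxels, spacing = as.numeric(spacing)),
            class = "label_volume")
}

#' Construct an intensity volume
#'
#' Scalar signal volume on the same grid convention as [label_volume()].
#'
#' @param voxels 3D numeric array of finite signal values.
#' @inheritParams label_volume
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(voxels, spacing) {
  if (length(dim(voxels)) != 3L)
    dd_stop("`voxels` must be a 3D array", "dwidistort_format_error")
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    dd_stop("`spacing` must be 3 positive finite values (dz, dy, dx)",
            "dwidistort_format_error")
  if (!all(is.finite(voxels)))
    dd_stop("intensity volume contains non-finite values",
            "dwidistort_format_error")
  structure(list(voxels = array(as.numeric(voxels), dim = dim(voxels)),
                 spacing = as.numeric(spacing)),
            class = "intensity_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- table(factor(x$voxels, levels = unname(ORGAN_LABELS),
                      labels = names(ORGAN_LABELS)))
  cat(sprintf("<label_volume> %s voxels @ (%.3g, %.3g, %.3g) mm\n",
              paste(dim(x$voxels), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  print(tab)
  invisible(x)
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf("<intensity_volume> %s voxels @ (%.3g, %.3g, %.3g) mm, range [%.3g, %.3g]\n",
              paste(dim(x$voxels), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

# Shared NIfTI reader: returns list(voxels (k,j,i), spacing (dz,dy,dx),
# reoriented_from).  Storage convention on disk is x fastest; we normalize to
# LPS ("column -> patient-left, row -> posterior, slice -> superior") and
# permute to the package's (slice, row, column) order.
read_nifti_normalized <- function(path) {
  if (!file.exists(path))
    dd_stop(sprintf("file not found: %s", path), "dwidistort_format_error")
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    dd_stop(sprintf("unreadable volume file '%s': %s", path, conditionMessage(e)),
            "dwidistort_format_error"))
  if (length(dim(img)) != 3L)
    dd_stop(sprintf("expected a 3D volume, got %dD", length(dim(img))),
            "dwidistort_format_error")
  ori <- RNifti::orientation(img)
  if (!identical(ori, "LPS")) {
    RNifti::orientation(img) <- "LPS"
    message(sprintf("read_nifti: reoriented from %s to LPS", ori))
  }
  pd <- RNifti::pixdim(img)  # (dx, dy, dz) after normalization
  list(voxels = aperm(as.array(img), c(3L, 2L, 1L)),
       spacing = rev(pd[1:3]),
       reoriented_from = if (identical(ori, "LPS")) NULL else ori)
}

write_nifti_normalized <- function(voxels, spacing, path) {
  arr <- aperm(voxels, c(3L, 2L, 1L))  # (i, j, k), x fastest
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(spacing)  # (dx, dy, dz)
  aff <- diag(c(-rev(spacing)[1], -rev(spacing)[2], rev(spacing)[3], 1))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label volume from a NIfTI-1 file
#'
#' Reads `.nii`/`.nii.gz`, normalizes the on-disk axis ordering to the fixed
#' anatomical convention (any permutation/flip is reported via a message),
#' takes voxel spacing from the header and validates the label set.
#'
#' @param path Path to a NIfTI-1 file.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path) {
  n <- read_nifti_normalized(path)
  label_volume(n$voxels, n$spacing)
}

#' Write a label volume to a NIfTI-1 file
#'
#' @param vol A [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  write_nifti_normalized(vol$voxels, vol$spacing, path)
}

#' Read an intensity volume from a NIfTI-1 file
#'
#' @inheritParams read_label_volume
#' @return An [intensity_volume()].
#' @export
read_intensity_volume <- function(path) {
  n <- read_nifti_normalized(path)
  intensity_volume(n$voxels, n$spacing)
}

#' Write an intensity volume to a NIfTI-1 file
#'
#' @param vol An [intensity_volume()].
#' @inheritParams write_label_volume
#' @return `path`, invisibly.
#' @export
write_intensity_volume <- function(vol, path) {
  stopifnot(inherits(vol, "intensity_volume"))
  write_nifti_normalized(vol$voxels, vol$spacing, path)
}

# Binary mask (logical array) for one organ of a label volume.
organ_mask <- function(vol, organ) {
  lab <- if (is.character(organ)) ORGAN_LABELS[[organ]] else as.integer(organ)
  vol$voxels == lab
}
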