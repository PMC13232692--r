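# Mask-based co-registration of ADC and reference prostate volumes.
#
# EPI susceptibility distortion is predominantly a local shift/stretch along
# the phase-encode direction, so the default registration removes only bulk
# translation (centre-of-mass alignment); an optional rigid mode additionally
# aligns in-plane principal axes.  Registration works on the binary masks
# only; the resulting transform is applied to contours in continuous mm
# space so the distortion metric is free of resampling noise.

#' Construct a mask transform
#'
#' @param translation `(tz, ty, tx)` mm.
#' @param rotation In-plane rotation, degrees in `(-180, 180]`,
#'   counterclockwise in the (x, y = posterior) plane.
#' @param center `(y_mm, x_mm)` in-plane rotation centre (ignored when
#'   `rotation == 0`).
#' @param mode `"translation"` or `"rigid"`.
#' @return Object of class `mask_transform`.
#' @export
mask_transform <- function(translation = c(0, 0, 0), rotation = 0,
                           center = c(0, 0),
                           mode = c("translation", "rigid")) {
  mode <- match.arg(mode)
  if (length(translation) != 3L || !all(is.finite(translation)))
    dd_stop("`translation` must be 3 finite values (tz, ty, tx)",
            "dwidistort_transform_error")
  if (!is.finite(rotation) || rotation <= -180 || rotation > 180)
    dd_stop("`rotation` must be finite and in (-180, 180]",
            "dwidistort_transform_error")
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 center = as.numeric(center), mode = mode),
            class = "mask_transform")
}

#' @export
print.mask_transform <- function(x, ...) {
  cat(sprintf("<mask_transform> %s: t = (%.3f, %.3f, %.3f) mm, rot = %.2f deg\n",
              x$mode, x$translation[1], x$translation[2], x$translation[3],
              x$rotation))
  invisible(x)
}

# Centre of mass of the nonzero voxels, in mm (z, y, x).
mask_com <- function(vol) {
  idx <- which(vol$voxels != 0L, arr.ind = TRUE)
  if (!nrow(idx))
    dd_stop("empty mask", "dwidistort_degenerate_error")
  colMeans((idx - 1) * rep(vol$spacing, each = nrow(idx)))
}

#' Dice overlap coefficient of two masks
#'
#' @param a,b [label_volume()] masks on the same grid (any nonzero voxel
#'   counts).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  av <- a$voxels != 0L; bv <- b$voxels != 0L
  s <- sum(av) + sum(bv)
  if (s == 0) return(NA_real_)
  2 * sum(av & bv) / s
}

# Apply a mask_transform to a binary mask by nearest-neighbour voxel mapping
# (used only to score candidate transforms; metric-path transforms act on
# contours).
transform_mask_nn <- function(vol, t) {
  idx <- which(vol$voxels != 0L, arr.ind = TRUE)
  mm <- (idx - 1) * rep(vol$spacing, each = nrow(idx))  # (z, y, x)
  if (t$rotation != 0) {
    th <- deg2rad(t$rotation)
    yx <- cbind(mm[, 2] - t$center[1], mm[, 3] - t$center[2])
    # rotation is CCW in (x, y): x' = x cos - y sin ; y' = x sin + y cos
    xr <- yx[, 2] * cos(th) - yx[, 1] * sin(th)
    yr <- yx[, 2] * sin(th) + yx[, 1] * cos(th)
    mm[, 2] <- yr + t$center[1]
    mm[, 3] <- xr + t$center[2]
  }
  mm <- mm + rep(t$translation, each = nrow(mm))
  new_idx <- round(mm / rep(vol$spacing, each = nrow(mm))) + 1
  dims <- dim(vol$voxels)
  keep <- new_idx[, 1] >= 1 & new_idx[, 1] <= dims[1] &
          new_idx[, 2] >= 1 & new_idx[, 2] <= dims[2] &
          new_idx[, 3] >= 1 & new_idx[, 3] <= dims[3]
  out <- array(0L, dims)
  out[new_idx[keep, , drop = FALSE]] <- 1L
  label_volume(out, vol$spacing)
}

# Dice estimate robust to resampling noise: each moving voxel is split into
# 2x2 in-plane subvoxels which are transformed and tested against the
# reference mask; for the identity transform this reduces to the exact Dice.
dice_supersampled <- function(reference, moving, t) {
  idx <- which(moving$voxels != 0L, arr.ind = TRUE)
  n_mov <- nrow(idx)
  n_ref <- sum(reference$voxels != 0L)
  sp <- moving$spacing
  mm0 <- (idx - 1) * rep(sp, each = n_mov)
  inter <- 0
  dims <- dim(reference$voxels)
  th <- deg2rad(t$rotation)
  for (oy in c(-0.25, 0.25)) for (ox in c(-0.25, 0.25)) {
    mm <- mm0
    mm[, 2] <- mm[, 2] + oy * sp[2]
    mm[, 3] <- mm[, 3] + ox * sp[3]
    if (t$rotation != 0) {
      xs <- mm[, 3] - t$center[2]; ys <- mm[, 2] - t$center[1]
      mm[, 3] <- xs * cos(th) - ys * sin(th) + t$center[2]
      mm[, 2] <- xs * sin(th) + ys * cos(th) + t$center[1]
    }
    mm <- mm + rep(t$translation, each = n_mov)
    ni <- round(mm / rep(sp, each = n_mov)) + 1
    keep <- ni[, 1] >= 1 & ni[, 1] <= dims[1] &
            ni[, 2] >= 1 & ni[, 2] <= dims[2] &
            ni[, 3] >= 1 & ni[, 3] <= dims[3]
    inter <- inter + sum(reference$voxels[ni[keep, , drop = FALSE]] != 0L) / 4
  }
  2 * inter / (n_mov + n_ref)
}

# In-plane principal-axis angle (degrees) from the second moments of the
# mask voxel centres.
principal_angle <- function(vol) {
  idx <- which(vol$voxels != 0L, arr.ind = TRUE)
  y <- (idx[, 2] - 1) * vol$spacing[2]
  x <- (idx[, 3] - 1) * vol$spacing[3]
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  atan2(2 * sxy, sxx - syy) / 2 * 180 / pi
}

#' Co-register two volume masks
#'
#' Translation mode maps the moving mask's centre of mass onto the
#' reference's, a sub-voxel estimator that makes the distortion metric
#' exactly invariant to bulk shifts of the moving set.  Rigid mode
#' additionally rotates in-plane to align principal axes, resolving the
#' 180-degree axis ambiguity by the candidate that maximizes Dice overlap;
#' rigid candidates that fail to reach the identity's Dice are rejected in
#' favour of the identity transform.
#'
#' @param reference,moving Non-empty [label_volume()] masks on the same grid.
#' @param mode `"translation"` (default) or `"rigid"`.
#' @return A [mask_transform()] that maps `moving` onto `reference`.
#' @export
coregister_masks <- function(reference, moving,
                             mode = c("translation", "rigid")) {
  mode <- match.arg(mode)
  com_ref <- mask_com(reference)
  com_mov <- mask_com(moving)
  tr <- com_ref - com_mov
  com_t <- mask_transform(tr, 0, com_mov[2:3], mode = mode)
  # centre-of-mass alignment is a sub-voxel estimator; return it directly in
  # translation mode so the metric is exactly invariant to bulk shifts
  if (mode == "translation") return(com_t)
  rot <- principal_angle(reference) - principal_angle(moving)
  rot <- ((rot + 90) %% 180) - 90       # axis angle, (-90, 90]
  candidates <- list(com_t)
  for (r in c(rot, rot + 180)) {
    r <- ((r + 180) %% 360) - 180
    if (r <= -180) r <- r + 360
    candidates <- c(candidates,
                    list(mask_transform(tr, r, com_mov[2:3], mode = mode)))
  }
  # the rotation candidates are accepted only if they beat both the identity
  # and plain translation on supersampled Dice overlap (supersampling keeps
  # the comparison with the unresampled identity fair)
  dice0 <- dice_supersampled(reference, moving, mask_transform(mode = mode))
  scores <- vapply(candidates, function(t)
    dice_supersampled(reference, moving, t), numeric(1))
  if (max(scores) < dice0) return(mask_transform(mode = mode))
  candidates[[which.max(scores)]]
}

#' Apply a mask transform to contours
#'
#' Vertices are mapped by the rigid motion in continuous mm space; slices
#' are reassigned by rounding the transformed slice coordinate to the
#' nearest slice index.
#'
#' @param contours A [contour_set()].
#' @param t A [mask_transform()].
#' @param dz Slice spacing in mm (defaults to the contour set's stored
#'   spacing).
#' @return Transformed [contour_set()].
#' @export
apply_transform <- function(contours, t, dz = NULL) {
  stopifnot(inherits(contours, "contour_set"), inherits(t, "mask_transform"))
  dz <- dz %||% contours$spacing[1]
  if (is.null(dz))
    dd_stop("slice spacing `dz` unknown; pass it or set contour spacing",
            "dwidistort_transform_error")
  th <- deg2rad(t$rotation)
  slices <- lapply(contours$slices, function(s) {
    xy <- s$xy
    if (t$rotation != 0) {
      xs <- xy[, 1] - t$center[2]; ys <- xy[, 2] - t$center[1]
      xy <- cbind(xs * cos(th) - ys * sin(th) + t$center[2],
                  xs * sin(th) + ys * cos(th) + t$center[1])
    }
    xy <- cbind(xy[, 1] + t$translation[3], xy[, 2] + t$translation[2])
    z <- s$slice_index * dz + t$translation[1]
    # nearest slice; exact half-slice ties stay on the lower slice
    list(slice_index = as.integer(ceiling(z / dz - 0.5)), xy = xy)
  })
  idx <- vapply(slices, `[[`, integer(1), "slice_index")
  if (anyDuplicated(idx)) {
    dd_warn("slice reassignment collapsed contours onto the same slice; keeping first")
    slices <- slices[!duplicated(idx)]
    idx <- idx[!duplicated(idx)]
  }
  slices <- slices[order(idx)]
  contour_set(slices, organ = contours$organ, position = contours$position,
              spacing = contours$spacing)
}
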