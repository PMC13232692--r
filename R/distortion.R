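# Polar radial distortion metric.
#
# For each paired slice the reference contour's area centroid serves as a
# common polar origin; both outlines are sampled at 1-degree increments and
# the signed radial residual dr(theta) = r_adc(theta) - r_ref(theta) is
# reduced to a whole-gland RMS and a posterior-half RMS (both in mm).
# Angle convention: 0 deg = +x (patient left), counterclockwise in the
# (x, y = posterior) plane, so 90 deg points posteriorly; the posterior half
# is theta in [1, 180] degrees.

POSTERIOR_ANGLES <- 1:180  # degrees

#' Area centroid of a closed polygon
#'
#' @param xy n x 2 vertex matrix (open polygon), columns `(x_mm, y_mm)`.
#' @return Named vector `c(y_mm =, x_mm =)`.
#' @export
slice_centroid <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  cr <- xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12)
    dd_stop("degenerate (zero-area) polygon has no centroid",
            "dwidistort_degenerate_error")
  cx <- sum((xy[, 1] + xy[j, 1]) * cr) / (6 * a)
  cy <- sum((xy[, 2] + xy[j, 2]) * cr) / (6 * a)
  c(y_mm = cy, x_mm = cx)
}

#' Polar radial profile of a contour
#'
#' Casts a ray from the origin at each angle of the 1-degree grid and
#' records the distance to the farthest boundary intersection (robust to
#' minor non-star-shapedness; rays crossing the boundary more than twice are
#' flagged).
#'
#' @param xy n x 2 vertex matrix (open polygon).
#' @param origin Named or plain vector `(y_mm, x_mm)`: the polar origin,
#'   normally the reference contour centroid.
#' @param n_angles Number of equally spaced angles (default 360).
#' @param require_inside Error if the origin is not inside the polygon
#'   (default `TRUE`); when `FALSE`, angles with no intersection get `NA`.
#' @return Object of class `radial_profile` with `angles` (degrees), `radii`
#'   (mm), `origin`, and `n_crossings` per angle.
#' @export
radial_profile <- function(xy, origin, n_angles = 360L,
                           require_inside = TRUE) {
  oy <- origin[[1]]; ox <- origin[[2]]
  if (require_inside && !point_in_polygon(ox, oy, xy))
    dd_stop("polar origin lies outside the polygon",
            "dwidistort_precondition_error")
  n <- nrow(xy)
  x1 <- xy[, 1]; y1 <- xy[, 2]
  x2 <- xy[c(2:n, 1L), 1]; y2 <- xy[c(2:n, 1L), 2]
  dx <- x2 - x1; dy <- y2 - y1
  wx <- x1 - ox; wy <- y1 - oy
  angles <- (seq_len(n_angles) - 1) * (360 / n_angles)
  radii <- rep(NA_real_, n_angles)
  ncross <- integer(n_angles)
  for (a in seq_len(n_angles)) {
    th <- deg2rad(angles[a])
    ux <- cos(th); uy <- sin(th)
    denom <- ux * dy - uy * dx          # cross(u, d)
    ok <- abs(denom) > 1e-14
    t <- (wx * dy - wy * dx) / denom    # cross(w, d) / cross(u, d)
    s <- -(ux * wy - uy * wx) / denom   # -cross(u, w) / cross(u, d)
    # slight tolerance so rays through a shared vertex register on at least
    # one of the adjacent edges; duplicate hits are harmless under max()
    hit <- ok & s >= -1e-9 & s <= 1 + 1e-9 & t > 1e-12
    if (any(hit)) {
      radii[a] <- max(t[hit])
      ncross[a] <- sum(hit)
    }
  }
  if (require_inside && anyNA(radii))
    dd_stop("ray without boundary intersection despite interior origin",
            "dwidistort_precondition_error")
  structure(list(angles = angles, radii = radii,
                 origin = c(y_mm = oy, x_mm = ox), n_crossings = ncross),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %d angles, radii %.2f-%.2f mm, origin (y=%.2f, x=%.2f)\n",
              length(x$angles), min(x$radii, na.rm = TRUE),
              max(x$radii, na.rm = TRUE), x$origin[1], x$origin[2]))
  invisible(x)
}

#' Per-angle radial residuals between two profiles
#'
#' Both profiles must share the same polar origin (the reference contour
#' centroid).  Residuals are signed: positive where the ADC outline lies
#' farther from the origin than the reference.
#'
#' @param ref_profile,adc_profile [radial_profile()] objects from the same
#'   slice and origin.
#' @return Numeric vector `dr = r_adc - r_ref` (mm), one value per angle.
#' @export
slice_residuals <- function(ref_profile, adc_profile) {
  stopifnot(inherits(ref_profile, "radial_profile"),
            inherits(adc_profile, "radial_profile"))
  if (max(abs(ref_profile$origin - adc_profile$origin)) > 1e-9)
    dd_stop("profiles were computed from different polar origins",
            "dwidistort_contract_error")
  if (length(ref_profile$radii) != length(adc_profile$radii))
    dd_stop("profiles have different angle grids", "dwidistort_contract_error")
  adc_profile$radii - ref_profile$radii
}

#' Reduce per-slice residuals to whole-gland and posterior RMS
#'
#' By default all (slice, angle) samples are pooled with equal weight; the
#' `"slice_rms"` alternative first forms each slice's RMS and then takes the
#' RMS of those per-slice values.
#'
#' @param residuals List of per-slice residual vectors (360 angles each, `NA`
#'   allowed) or a slices x angles matrix.
#' @param pooling `"pooled"` (default) or `"slice_rms"`.
#' @param n_slices_dropped Count of unpaired slices, carried into the result.
#' @param slice_index Optional slice indices for the rows.
#' @return Object of class `distortion_result` with `rms_whole`,
#'   `rms_posterior` (mm), the signed residual matrix, and slice counts.
#' @export
rms_reduce <- function(residuals, pooling = c("pooled", "slice_rms"),
                       n_slices_dropped = 0L, slice_index = NULL) {
  pooling <- match.arg(pooling)
  if (is.list(residuals)) residuals <- do.call(rbind, residuals)
  if (is.null(dim(residuals))) residuals <- matrix(residuals, nrow = 1)
  if (!nrow(residuals) || !any(is.finite(residuals)))
    dd_stop("no paired slices with residuals", "dwidistort_pairing_error")
  post_cols <- POSTERIOR_ANGLES + 1L  # angle grid starts at 0 deg
  rms_of <- function(m) {
    if (pooling == "pooled") {
      sqrt(mean(m^2, na.rm = TRUE))
    } else {
      per <- apply(m, 1, function(r) mean(r^2, na.rm = TRUE))
      sqrt(mean(per, na.rm = TRUE))
    }
  }
  structure(list(residuals = residuals,
                 slice_index = slice_index %||% seq_len(nrow(residuals)) - 1L,
                 rms_whole = rms_of(residuals),
                 rms_posterior = rms_of(residuals[, post_cols, drop = FALSE]),
                 n_slices_used = nrow(residuals),
                 n_slices_dropped = as.integer(n_slices_dropped),
                 pooling = pooling),
            class = "distortion_result")
}

#' @export
print.distortion_result <- function(x, ...) {
  cat(sprintf(
    "<distortion_result> rms_whole = %.3f mm, rms_posterior = %.3f mm (%d slice(s) used, %d dropped, %s)\n",
    x$rms_whole, x$rms_posterior, x$n_slices_used, x$n_slices_dropped,
    x$pooling))
  invisible(x)
}

#' Measure radial distortion between two contour sets
#'
#' Applies the registration transform to the ADC contours, pairs slices by
#' index, and on each paired slice samples both outlines at 1-degree
#' increments about the reference contour's centroid before reducing to
#' whole-gland and posterior-half RMS.
#'
#' @param ref_contours Reference (e.g. DCE-derived) [contour_set()].
#' @param adc_contours ADC-derived [contour_set()].
#' @param transform Optional [mask_transform()] to apply to the ADC set
#'   (identity when `NULL` and `registration` is `"none"`).
#' @param registration `"none"`, `"translation"` or `"rigid"`: when
#'   `transform` is `NULL`, compute one by rasterizing both sets onto a
#'   common grid and calling [coregister_masks()].
#' @param pooling Passed to [rms_reduce()].
#' @param template Optional rasterization grid for registration (defaults to
#'   a grid covering both contour sets).
#' @return A `distortion_result`; the applied transform is attached as
#'   attribute `"transform"`.
#' @export
measure_distortion <- function(ref_contours, adc_contours, transform = NULL,
                               registration = c("none", "translation", "rigid"),
                               pooling = c("pooled", "slice_rms"),
                               template = NULL) {
  registration <- match.arg(registration)
  pooling <- match.arg(pooling)
  stopifnot(inherits(ref_contours, "contour_set"),
            inherits(adc_contours, "contour_set"))
  if (is.null(transform)) {
    if (registration == "none") {
      transform <- mask_transform()
    } else {
      template <- template %||% default_template(ref_contours, adc_contours)
      ref_mask <- mask_from_contours(ref_contours, template)
      adc_mask <- mask_from_contours(adc_contours, template)
      transform <- coregister_masks(ref_mask, adc_mask, mode = registration)
    }
  }
  dz <- ref_contours$spacing[1] %||% adc_contours$spacing[1] %||% 1
  adc <- apply_transform(adc_contours, transform, dz = dz)
  ref_idx <- slice_indices(ref_contours)
  adc_idx <- slice_indices(adc)
  common <- intersect(ref_idx, adc_idx)
  if (!length(common))
    dd_stop("no overlapping slices between reference and ADC contours",
            "dwidistort_pairing_error")
  dropped <- length(setdiff(ref_idx, adc_idx)) + length(setdiff(adc_idx, ref_idx))
  res <- lapply(sort(common), function(k) {
    rxy <- ref_contours$slices[[match(k, ref_idx)]]$xy
    axy <- adc$slices[[match(k, adc_idx)]]$xy
    origin <- slice_centroid(rxy)
    rp <- radial_profile(rxy, origin)
    ap <- radial_profile(axy, origin, require_inside = FALSE)
    slice_residuals(rp, ap)
  })
  out <- rms_reduce(res, pooling = pooling, n_slices_dropped = dropped,
                    slice_index = sort(common))
  attr(out, "transform") <- transform
  out
}

# Rasterization grid just covering both contour sets (used only when a
# registration transform has to be estimated from contours).
default_template <- function(a, b, spacing = NULL) {
  spacing <- spacing %||% a$spacing %||% b$spacing %||% c(3, 1, 1)
  allxy <- do.call(rbind, c(lapply(a$slices, `[[`, "xy"),
                            lapply(b$slices, `[[`, "xy")))
  kmax <- max(c(slice_indices(a), slice_indices(b)))
  margin <- 12  # mm of in-plane margin to absorb shifts
  nx <- ceiling((max(allxy[, 1]) + margin) / spacing[3]) + 1
  ny <- ceiling((max(allxy[, 2]) + margin) / spacing[2]) + 1
  if (min(allxy) < 0)
    dd_stop("contours with negative coordinates need an explicit template",
            "dwidistort_bounds_error")
  list(dim = c(kmax + 1L, ny, nx), spacing = spacing)
}
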