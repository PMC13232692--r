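# Rectal air segmentation and prostate-proximity volume.
#
# Air is dark on the contrast-enhanced reference images, so segmentation is
# a simple intensity threshold restricted to the rectum outline; proximity
# is Euclidean distance to the prostate surface computed with an exact
# anisotropic distance transform, equivalent to dilating the prostate by the
# proximity radius and intersecting with the air mask.

#' Euclidean distance map to a mask
#'
#' For every voxel, the anisotropic-spacing-aware Euclidean distance (mm) to
#' the nearest nonzero voxel of the mask (0 inside the mask).
#'
#' @param mask A [label_volume()]; any nonzero voxel counts as foreground.
#' @return 3D numeric array of distances in mm (`Inf` if the mask is empty).
#' @export
distance_map <- function(mask) {
  stopifnot(inherits(mask, "label_volume"))
  dims <- dim(mask$voxels)
  d <- .edt3d(as.logical(mask$voxels != 0L), as.integer(dims),
              as.numeric(mask$spacing))  # axis order (k, j, i) -> steps (dz, dy, dx)
  array(d, dims)
}

#' Default air segmentation threshold
#'
#' A low percentile of the within-body signal intensities, standing in for a
#' scanner-specific predefined threshold.
#'
#' @param intensity An [intensity_volume()].
#' @param body_mask Optional logical array restricting the percentile to
#'   body voxels (default: all voxels).
#' @param prob Percentile (default 0.025).
#' @return Threshold in signal units.
#' @export
auto_air_threshold <- function(intensity, body_mask = NULL, prob = 0.025) {
  stopifnot(inherits(intensity, "intensity_volume"))
  v <- if (is.null(body_mask)) as.vector(intensity$voxels)
       else intensity$voxels[body_mask]
  stats::quantile(v, probs = prob, names = FALSE, type = 7)
}

# Connected components of a logical 3D array under face (6-neighbour)
# connectivity.  Returns integer array of component ids (0 = background).
connected_components <- function(bin) {
  dims <- dim(bin)
  id <- array(0L, dims)
  idx <- which(bin)
  if (!length(idx)) return(id)
  id[idx] <- seq_along(idx)
  edges <- NULL
  n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
  if (n1 > 1) {
    sh <- array(FALSE, dims); sh[2:n1, , ] <- bin[1:(n1 - 1), , ]
    both <- bin & sh
    prev <- array(0L, dims); prev[2:n1, , ] <- id[1:(n1 - 1), , ]
    edges <- rbind(edges, cbind(id[both], prev[both]))
  }
  if (n2 > 1) {
    sh <- array(FALSE, dims); sh[, 2:n2, ] <- bin[, 1:(n2 - 1), ]
    both <- bin & sh
    prev <- array(0L, dims); prev[, 2:n2, ] <- id[, 1:(n2 - 1), ]
    edges <- rbind(edges, cbind(id[both], prev[both]))
  }
  if (n3 > 1) {
    sh <- array(FALSE, dims); sh[, , 2:n3] <- bin[, , 1:(n3 - 1)]
    both <- bin & sh
    prev <- array(0L, dims); prev[, , 2:n3] <- id[, , 1:(n3 - 1)]
    edges <- rbind(edges, cbind(id[both], prev[both]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  id[idx] <- as.integer(comp)
  id
}

#' Segment rectal air by intensity threshold
#'
#' Air voxels are those inside the rectum outline whose signal falls below
#' the threshold; face-connected components smaller than `min_voxels` are
#' discarded as noise.
#'
#' @param intensity An [intensity_volume()].
#' @param rectum_mask A [label_volume()] rectum mask on the same grid.
#' @param threshold Signal threshold; `NULL` uses [auto_air_threshold()].
#' @param min_voxels Minimum pocket size in voxels (default 5).
#' @return A [label_volume()] with air voxels labelled 3; attribute
#'   `n_pockets` counts retained components and `threshold` records the
#'   threshold used.
#' @export
segment_air <- function(intensity, rectum_mask, threshold = NULL,
                        min_voxels = 5L) {
  stopifnot(inherits(intensity, "intensity_volume"),
            inherits(rectum_mask, "label_volume"))
  if (!identical(dim(intensity$voxels), dim(rectum_mask$voxels)))
    dd_stop("intensity and rectum mask grids differ",
            "dwidistort_format_error")
  threshold <- threshold %||% auto_air_threshold(intensity)
  rng <- range(intensity$voxels)
  if (threshold < rng[1] || threshold > rng[2])
    dd_warn(sprintf("air threshold %.3g outside observed intensity range [%.3g, %.3g]",
                    threshold, rng[1], rng[2]))
  bin <- (rectum_mask$voxels != 0L) & (intensity$voxels < threshold)
  comp <- connected_components(bin)
  keep_ids <- integer(0)
  if (any(bin)) {
    sizes <- tabulate(comp[bin])
    keep_ids <- which(sizes >= min_voxels)
    bin <- bin & array(comp %in% keep_ids, dim(comp))
  }
  out <- label_volume(array(ifelse(bin, ORGAN_LABELS[["air"]], 0L), dim(bin)),
                      rectum_mask$spacing)
  attr(out, "n_pockets") <- length(keep_ids)
  attr(out, "threshold") <- threshold
  out
}

#' Air measure constructor
#'
#' @param total_cm3 Total rectal air volume, cm^3.
#' @param proximal_cm3 Air volume within `distance_mm` of the prostate, cm^3.
#' @param distance_mm Proximity distance, mm.
#' @param n_pockets Connected-component count of the air mask.
#' @return Object of class `air_measure`.
#' @export
air_measure <- function(total_cm3, proximal_cm3, distance_mm, n_pockets) {
  if (proximal_cm3 > total_cm3 + 1e-9)
    dd_stop("proximal air volume exceeds total air volume",
            "dwidistort_contract_error")
  structure(list(total_cm3 = total_cm3, proximal_cm3 = proximal_cm3,
                 distance_mm = distance_mm, n_pockets = as.integer(n_pockets)),
            class = "air_measure")
}

#' @export
print.air_measure <- function(x, ...) {
  cat(sprintf("<air_measure> total %.3f cm^3, %.3f cm^3 within %.0f mm of prostate (%d pocket(s))\n",
              x$total_cm3, x$proximal_cm3, x$distance_mm, x$n_pockets))
  invisible(x)
}

#' Rectal air volume proximal to the prostate
#'
#' Counts air voxels whose Euclidean distance to the nearest prostate voxel
#' is at most `distance_mm` (equivalently, air intersected with the prostate
#' dilated by `distance_mm`), and converts counts to cm^3 via the voxel
#' volume.
#'
#' @param air_mask Air [label_volume()] (e.g. from [segment_air()]).
#' @param prostate_mask Non-empty prostate [label_volume()] on the same grid.
#' @param distance_mm Proximity distance in mm (default 20).
#' @return An [air_measure()].
#' @export
air_proximity_volume <- function(air_mask, prostate_mask, distance_mm = 20) {
  stopifnot(inherits(air_mask, "label_volume"),
            inherits(prostate_mask, "label_volume"))
  if (!identical(dim(air_mask$voxels), dim(prostate_mask$voxels)))
    dd_stop("air and prostate mask grids differ", "dwidistort_format_error")
  if (!any(prostate_mask$voxels != 0L))
    dd_stop("empty prostate mask", "dwidistort_degenerate_error")
  air <- air_mask$voxels != 0L
  voxvol <- prod(air_mask$spacing) / 1000  # cm^3
  d <- distance_map(prostate_mask)
  proximal <- air & (d <= distance_mm + 1e-9)
  n_pockets <- attr(air_mask, "n_pockets")
  if (is.null(n_pockets)) {
    comp <- connected_components(air)
    n_pockets <- length(unique(comp[comp > 0L]))
  }
  air_measure(total_cm3 = sum(air) * voxvol,
              proximal_cm3 = sum(proximal) * voxvol,
              distance_mm = distance_mm, n_pockets = n_pockets)
}

#' Dichotomize rectal-air Likert scores
#'
#' The 5-point visual scale grades rectal air contact with the prostate
#' (1 = rectal walls opposed ... 5 = more than 80% contact); scores at or
#' above the cutoff denote clinically appreciable air.
#'
#' @param scores Integer scores in 1..5.
#' @param cutoff Dichotomization cutoff (default 4).
#' @return Integer vector of 0/1.
#' @export
dichotomize_likert <- function(scores, cutoff = 4L) {
  if (!all(is_wholenumber(scores)) || any(scores < 1 | scores > 5))
    dd_stop("Likert scores must be integers in 1..5",
            "dwidistort_validation_error")
  as.integer(scores >= cutoff)
}
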