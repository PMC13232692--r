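# Closed planar polygons and per-slice contour sets.
#
# Polygons are n x 2 matrices with columns (x_mm, y_mm), stored open (the
# closing edge from the last back to the first vertex is implicit).  x
# increases to patient-left, y increases posteriorly.

#' Construct a contour set
#'
#' A `contour_set` holds the closed per-slice outlines of one organ in one
#' acquisition, in physical mm within each axial slice plane.
#'
#' @param slices List of entries, each `list(slice_index =, xy =)` where
#'   `slice_index` is the 0-based slice number and `xy` an n x 2 matrix of
#'   vertices (columns `x_mm`, `y_mm`), at least 3 vertices, closed
#'   implicitly.
#' @param organ Organ name (one of `names(ORGAN_LABELS)` except background).
#' @param position Acquisition position, `"supine"` or `"prone"`.
#' @param spacing Optional `(dz, dy, dx)` mm spacing of the grid the contours
#'   were drawn on (carried as metadata for slice reassignment).
#' @return Object of class `contour_set`.
#' @export
contour_set <- function(slices, organ = "prostate",
                        position = c("supine", "prone"), spacing = NULL) {
  position <- match.arg(position)
  organ <- match.arg(organ, setdiff(names(ORGAN_LABELS), "background"))
  idx <- vapply(slices, function(s) as.integer(s$slice_index), integer(1))
  if (length(idx) && any(diff(idx) <= 0))
    dd_stop("slice indices must be strictly increasing",
            "dwidistort_contour_error")
  slices <- lapply(slices, function(s) {
    xy <- as.matrix(s$xy)
    storage.mode(xy) <- "double"
    if (nrow(xy) >= 2 && all(abs(xy[1, ] - xy[nrow(xy), ]) < 1e-12))
      xy <- xy[-nrow(xy), , drop = FALSE]  # stored open
    if (nrow(xy) < 3)
      dd_stop("each contour polygon needs at least 3 distinct vertices",
              "dwidistort_contour_error")
    if (abs(polygon_area_signed(xy)) < 1e-12)
      dd_stop("degenerate (zero-area) contour polygon",
              "dwidistort_contour_error")
    colnames(xy) <- c("x_mm", "y_mm")
    list(slice_index = as.integer(s$slice_index), xy = xy)
  })
  structure(list(slices = slices, organ = organ, position = position,
                 spacing = if (!is.null(spacing)) as.numeric(spacing)),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> %s, %s: %d slice(s)\n",
              x$organ, x$position, length(x$slices)))
  invisible(x)
}

#' @export
length.contour_set <- function(x) length(x$slices)

slice_indices <- function(cs) {
  vapply(cs$slices, `[[`, integer(1), "slice_index")
}

# ---- polygon primitives -----------------------------------------------------

polygon_area_signed <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]) / 2
}

#' Polygon area (shoelace)
#'
#' @param xy n x 2 vertex matrix (open polygon).
#' @return Absolute enclosed area (mm^2).
#' @export
polygon_area <- function(xy) abs(polygon_area_signed(xy))

#' Even-odd point-in-polygon test
#'
#' Vectorized over points; points lying exactly on an edge count as inside.
#'
#' @param px,py Point coordinates (equal-length vectors).
#' @param xy n x 2 vertex matrix (open polygon).
#' @param tol Distance tolerance for the on-edge test, in mm.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, xy, tol = 1e-9) {
  n <- nrow(xy)
  x1 <- xy[, 1]; y1 <- xy[, 2]
  x2 <- xy[c(2:n, 1L), 1]; y2 <- xy[c(2:n, 1L), 2]
  inside <- logical(length(px))
  onedge <- logical(length(px))
  for (e in seq_len(n)) {
    ex1 <- x1[e]; ey1 <- y1[e]; ex2 <- x2[e]; ey2 <- y2[e]
    crosses <- (ey1 > py) != (ey2 > py)
    if (any(crosses)) {
      xint <- ex1 + (py - ey1) / (ey2 - ey1) * (ex2 - ex1)
      inside <- xor(inside, crosses & (px < xint))
    }
    dx <- ex2 - ex1; dy <- ey2 - ey1
    len2 <- dx * dx + dy * dy
    t <- ((px - ex1) * dx + (py - ey1) * dy) / len2
    perp <- abs((px - ex1) * dy - (py - ey1) * dx) / sqrt(len2)
    onedge <- onedge | (perp <= tol & t >= -tol & t <= 1 + tol)
  }
  inside | onedge
}

# ---- contour CSV IO ---------------------------------------------------------

CONTOUR_COLUMNS <- c("position", "organ", "slice_index", "vertex_order",
                     "x_mm", "y_mm")

#' Read contour sets from CSV
#'
#' The CSV dialect has columns `position, organ, slice_index, vertex_order,
#' x_mm, y_mm` (one row per vertex); unknown columns are rejected.
#'
#' @param path CSV file path.
#' @param organ,position Optional filters; when both select a single
#'   acquisition a single [contour_set()] is returned, otherwise a named list
#'   keyed `"position.organ"`.
#' @param spacing Optional spacing metadata passed to [contour_set()].
#' @return A [contour_set()] or named list of them.
#' @export
read_contours <- function(path, organ = NULL, position = NULL, spacing = NULL) {
  if (!file.exists(path))
    dd_stop(sprintf("file not found: %s", path), "dwidistort_format_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  unknown <- setdiff(names(df), CONTOUR_COLUMNS)
  if (length(unknown))
    dd_stop(sprintf("unknown contour column(s): %s",
                    paste(unknown, collapse = ", ")),
            "dwidistort_schema_error")
  missing <- setdiff(CONTOUR_COLUMNS, names(df))
  if (length(missing))
    dd_stop(sprintf("missing contour column(s): %s",
                    paste(missing, collapse = ", ")),
            "dwidistort_schema_error")
  if (!is.null(organ)) df <- df[df$organ == organ, ]
  if (!is.null(position)) df <- df[df$position == position, ]
  if (!nrow(df))
    dd_stop("no contour rows match the requested organ/position",
            "dwidistort_format_error")
  out <- list()
  for (pos in unique(df$position)) {
    for (org in unique(df$organ[df$position == pos])) {
      sub <- df[df$position == pos & df$organ == org, ]
      sl <- lapply(sort(unique(sub$slice_index)), function(k) {
        v <- sub[sub$slice_index == k, ]
        v <- v[order(v$vertex_order), ]
        list(slice_index = k, xy = cbind(v$x_mm, v$y_mm))
      })
      out[[paste(pos, org, sep = ".")]] <-
        contour_set(sl, organ = org, position = pos, spacing = spacing)
    }
  }
  if (length(out) == 1L) out[[1L]] else out
}

#' Write contour sets to CSV
#'
#' @param contours A [contour_set()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  if (inherits(contours, "contour_set")) contours <- list(contours)
  rows <- lapply(contours, function(cs) {
    do.call(rbind, lapply(cs$slices, function(s) {
      data.frame(position = cs$position, organ = cs$organ,
                 slice_index = s$slice_index,
                 vertex_order = seq_len(nrow(s$xy)) - 1L,
                 x_mm = s$xy[, 1], y_mm = s$xy[, 2])
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# ---- rasterization and contour extraction -----------------------------------

#' Rasterize contours to a label volume
#'
#' A voxel is set iff its in-plane centre falls inside the slice polygon by
#' the even-odd rule (boundary points count as inside); slices without a
#' contour stay empty.
#'
#' @param contours A [contour_set()].
#' @param template A [label_volume()] or `list(dim =, spacing =)` defining
#'   the target grid.
#' @return A [label_volume()] with the organ's label set.
#' @export
mask_from_contours <- function(contours, template) {
  stopifnot(inherits(contours, "contour_set"))
  dims <- if (inherits(template, "label_volume")) dim(template$voxels)
          else template$dim
  spacing <- template$spacing
  dz <- spacing[1]; dy <- spacing[2]; dx <- spacing[3]
  lab <- ORGAN_LABELS[[contours$organ]]
  vox <- array(0L, dim = dims)
  xc <- (seq_len(dims[3]) - 1) * dx   # column centres, mm
  yc <- (seq_len(dims[2]) - 1) * dy   # row centres, mm
  xmax <- (dims[3] - 1) * dx; ymax <- (dims[2] - 1) * dy
  for (s in contours$slices) {
    k <- s$slice_index
    if (k < 0 || k >= dims[1])
      dd_stop(sprintf("contour slice index %d outside grid [0, %d]",
                      k, dims[1] - 1L),
              "dwidistort_bounds_error")
    xy <- s$xy
    if (min(xy[, 1]) < -dx / 2 || max(xy[, 1]) > xmax + dx / 2 ||
        min(xy[, 2]) < -dy / 2 || max(xy[, 2]) > ymax + dy / 2)
      dd_stop("contour extends outside the grid extent",
              "dwidistort_bounds_error")
    # restrict the test to the polygon's bounding box
    ji <- which(yc >= min(xy[, 2]) - dy & yc <= max(xy[, 2]) + dy)
    ii <- which(xc >= min(xy[, 1]) - dx & xc <= max(xy[, 1]) + dx)
    if (!length(ji) || !length(ii)) next
    g <- expand.grid(j = ji, i = ii)
    inside <- point_in_polygon(xc[g$i], yc[g$j], xy)
    if (any(inside)) {
      sel <- g[inside, ]
      vox[cbind(k + 1L, sel$j, sel$i)] <- lab
    }
  }
  label_volume(vox, spacing)
}

#' Extract per-slice contours from a mask
#'
#' Traces the 0.5-level isocontour of the binary organ mask on each slice.
#' When a slice holds more than one connected component, the largest-area
#' outline is kept and a warning is raised.
#'
#' @param mask A [label_volume()].
#' @param organ Organ name or label to extract.
#' @param position Position tag for the returned set.
#' @return A [contour_set()]; empty (zero slices) if the organ is absent.
#' @export
contours_from_mask <- function(mask, organ = "prostate",
                               position = c("supine", "prone")) {
  stopifnot(inherits(mask, "label_volume"))
  position <- match.arg(position)
  bin <- organ_mask(mask, organ)
  dims <- dim(bin)
  dz <- mask$spacing[1]; dy <- mask$spacing[2]; dx <- mask$spacing[3]
  yc <- c(-dy, (seq_len(dims[2]) - 1) * dy, dims[2] * dy)  # padded rows
  xc <- c(-dx, (seq_len(dims[3]) - 1) * dx, dims[3] * dx)  # padded cols
  slices <- list()
  organ_name <- if (is.character(organ)) organ
                else names(ORGAN_LABELS)[match(organ, ORGAN_LABELS)]
  for (k in seq_len(dims[1])) {
    sl <- bin[k, , ]
    if (!any(sl)) next
    pad <- matrix(0, dims[2] + 2L, dims[3] + 2L)
    pad[2:(dims[2] + 1L), 2:(dims[3] + 1L)] <- sl
    cl <- grDevices::contourLines(x = yc, y = xc, z = pad, levels = 0.5)
    if (!length(cl)) next
    polys <- lapply(cl, function(cc) cbind(cc$y, cc$x))  # (x_mm, y_mm)
    areas <- vapply(polys, polygon_area, numeric(1))
    if (length(polys) > 1L)
      dd_warn(sprintf(
        "slice %d: %d boundary components for organ '%s'; keeping largest",
        k - 1L, length(polys), organ_name))
    xy <- polys[[which.max(areas)]]
    if (nrow(xy) >= 2 && all(abs(xy[1, ] - xy[nrow(xy), ]) < 1e-12))
      xy <- xy[-nrow(xy), , drop = FALSE]
    if (nrow(xy) < 3) next
    slices[[length(slices) + 1L]] <- list(slice_index = k - 1L, xy = xy)
  }
  contour_set(slices, organ = organ_name, position = position,
              spacing = mask$spacing)
}
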