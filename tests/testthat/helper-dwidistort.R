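# Shared fixtures and independent oracles.  Oracles deliberately use
# different algebra/algorithms from the package implementation.

circle_polygon <- function(r, center = c(0, 0), n = 360L, phase = 0) {
  th <- phase + (seq_len(n) - 1) * 2 * pi / n
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

ellipse_polygon <- function(a, b, center = c(0, 0), n = 720L) {
  th <- (seq_len(n) - 1) * 2 * pi / n
  cbind(center[1] + a * cos(th), center[2] + b * sin(th))
}

square_polygon <- function(x0, y0, side) {
  cbind(c(x0, x0 + side, x0 + side, x0),
        c(y0, y0, y0 + side, y0 + side))
}

# random smooth star-shaped polygon around (0, 0), irregular vertex angles
random_star_polygon <- function(n = 60L, base = 10, wobble = 2) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- base + wobble * (sin(2 * th + stats::runif(1, 0, pi)) +
                          0.5 * cos(3 * th + stats::runif(1, 0, pi)))
  cbind(r * cos(th), r * sin(th))
}

# Brute-force even-odd point-in-polygon via winding-free crossing count on
# a ray to x = +Inf, one point at a time (textbook scalar loop).
pip_brute <- function(px, py, xy) {
  n <- nrow(xy)
  out <- logical(length(px))
  for (p in seq_along(px)) {
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- xy[i, 1]; yi <- xy[i, 2]; xj <- xy[j, 1]; yj <- xy[j, 2]
      if ((yi > py[p]) != (yj > py[p])) {
        xint <- xi + (py[p] - yi) * (xj - xi) / (yj - yi)
        if (px[p] < xint) inside <- !inside
      }
      j <- i
    }
    out[p] <- inside
  }
  out
}

# Brute-force farthest ray-boundary intersection: parametrize each edge as
# p1 + u (p2 - p1), solve the colinearity condition for u, then take the
# forward distance along the ray direction.
ray_brute <- function(xy, origin, angles_deg) {
  n <- nrow(xy)
  p1 <- xy
  p2 <- xy[c(2:n, 1L), , drop = FALSE]
  ex <- p2[, 1] - p1[, 1]; ey <- p2[, 2] - p1[, 2]
  out <- rep(NA_real_, length(angles_deg))
  for (a in seq_along(angles_deg)) {
    th <- angles_deg[a] * pi / 180
    dx <- cos(th); dy <- sin(th)
    denom <- ex * dy - ey * dx
    u <- ((origin[1] - p1[, 1]) * dy - (origin[2] - p1[, 2]) * dx) / denom
    px <- p1[, 1] + u * ex; py <- p1[, 2] + u * ey
    t <- (px - origin[1]) * dx + (py - origin[2]) * dy
    ok <- is.finite(u) & u >= 0 & u < 1 & t > 1e-12
    if (any(ok)) out[a] <- max(t[ok])
  }
  out
}

# All-pairs proximity oracle: air voxels within d mm of any prostate voxel.
proximal_count_brute <- function(air_vox, prost_vox, spacing, d) {
  ai <- which(air_vox != 0L, arr.ind = TRUE)
  pi_ <- which(prost_vox != 0L, arr.ind = TRUE)
  if (!nrow(ai) || !nrow(pi_)) return(0L)
  amm <- (ai - 1) * rep(spacing, each = nrow(ai))
  pmm <- (pi_ - 1) * rep(spacing, each = nrow(pi_))
  count <- 0L
  for (r in seq_len(nrow(amm))) {
    d2 <- (pmm[, 1] - amm[r, 1])^2 + (pmm[, 2] - amm[r, 2])^2 +
      (pmm[, 3] - amm[r, 3])^2
    if (min(d2) <= d^2 + 1e-9) count <- count + 1L
  }
  count
}

# Exhaustive signed-rank two-sided p-value over all sign assignments.
wilcoxon_enum <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wall <- as.vector(signs %*% r)
  mean(abs(wall - mu) >= abs(w - mu) - 1e-9)
}

# Fisher two-sided p by explicit enumeration over tables with fixed margins.
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  prob <- function(a) stats::dhyper(a, r1, r2, c1)
  support <- max(0, c1 - r2):min(r1, c1)
  p_obs <- prob(tab[1, 1])
  sum(prob(support)[prob(support) <= p_obs + 1e-12])
}

# Newton-Raphson logistic MLE, written independently of stats::glm.
logistic_nr <- function(x, y, iter = 100L) {
  X <- cbind(1, x)
  b <- c(0, 0)
  for (i in seq_len(iter)) {
    eta <- as.vector(X %*% b)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    H <- t(X) %*% (X * W)
    g <- t(X) %*% (y - p)
    step <- solve(H, g)
    b <- b + as.vector(step)
    if (max(abs(step)) < 1e-12) break
  }
  b
}

grid_template <- function(dim, spacing) list(dim = dim, spacing = spacing)

# small deterministic phantom used by several suites
small_phantom <- function(seed = 11, ...) {
  make_phantom(phantom_spec(seed = seed, ...))
}

sidx <- function(cs) vapply(cs$slices, function(s) s$slice_index, integer(1))
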