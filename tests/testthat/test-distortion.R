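test_that("slice centroid matches closed forms and a rasterization oracle", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_equal(unname(slice_centroid(sq)), c(5, 5))
  circ <- circle_polygon(4, c(-2, 3), n = 1440)
  expect_equal(unname(slice_centroid(circ)), c(3, -2), tolerance = 1e-6)

  # L-shape vs brute-force rasterized centre of mass on a 0.05 mm grid
  L <- cbind(c(0, 10, 10, 4, 4, 0), c(0, 0, 3, 3, 12, 12))
  g <- expand.grid(x = seq(0.025, 10, by = 0.05), y = seq(0.025, 12, by = 0.05))
  inside <- pip_brute(g$x, g$y, L)
  cen <- slice_centroid(L)
  expect_lt(abs(cen["x_mm"] - mean(g$x[inside])), 0.05)
  expect_lt(abs(cen["y_mm"] - mean(g$y[inside])), 0.05)

  expect_error(slice_centroid(cbind(c(0, 1, 2), c(0, 1, 2))),
               class = "dwidistort_degenerate_error")
})

test_that("radial profiles match circle, rectangle and polar-ellipse closed forms", {
  circ <- circle_polygon(10, n = 720)
  rp <- radial_profile(circ, c(0, 0))
  expect_equal(rp$radii, rep(10, 360), tolerance = 1e-4)

  rect <- cbind(c(-10, 10, 10, -10), c(-5, -5, 5, 5))  # 20 x 10 mm
  rr <- radial_profile(rect, c(0, 0))
  expect_equal(rr$radii[1], 10, tolerance = 1e-9)    # 0 deg: +x half-width
  expect_equal(rr$radii[91], 5, tolerance = 1e-9)    # 90 deg: +y half-height

  a <- 15; b <- 10
  ell <- ellipse_polygon(a, b, n = 3600)
  re <- radial_profile(ell, c(0, 0))
  th <- deg2rad(0:359)
  closed <- a * b / sqrt(b^2 * cos(th)^2 + a^2 * sin(th)^2)
  expect_lt(max(abs(re$radii - closed) / closed), 0.005)

  expect_error(radial_profile(circ, c(50, 50)),
               class = "dwidistort_precondition_error")
})

test_that("ray radii agree with dense segment-intersection brute force", {
  set.seed(99)
  for (i in 1:25) {
    xy <- random_star_polygon(n = 80)
    rp <- radial_profile(xy, c(0, 0))
    oracle <- ray_brute(xy, c(0, 0), rp$angles)
    expect_lt(max(abs(rp$radii - oracle)), 1e-6)
  }
  # a very dense polygon (many edges per ray sector)
  xy <- random_star_polygon(n = 5000, base = 12, wobble = 3)
  rp <- radial_profile(xy, c(0, 0))
  expect_lt(max(abs(rp$radii - ray_brute(xy, c(0, 0), rp$angles))), 1e-6)
})

test_that("slice residuals reproduce analytic offsets and enforce origins", {
  circ <- circle_polygon(10, n = 1440)
  p0 <- radial_profile(circ, c(0, 0))
  expect_equal(slice_residuals(p0, p0), rep(0, 360))

  bigger <- circle_polygon(12, n = 1440)
  p2 <- radial_profile(bigger, c(0, 0))
  expect_equal(slice_residuals(p0, p2), rep(2, 360), tolerance = 1e-3)

  # circle shifted +2 mm posterior, origin kept at the reference centre:
  # r(theta) = delta sin(theta) + sqrt(R^2 - delta^2 cos^2(theta))
  delta <- 2
  shifted <- circle_polygon(10, c(0, delta), n = 1440)
  ps <- radial_profile(shifted, c(0, 0))
  dr <- slice_residuals(p0, ps)
  th <- deg2rad(0:359)
  analytic <- delta * sin(th) + sqrt(100 - delta^2 * cos(th)^2) - 10
  expect_equal(dr, analytic, tolerance = 1e-3)
  expect_equal(dr[91], 2, tolerance = 1e-3)
  expect_equal(dr[271], -2, tolerance = 1e-3)

  off <- radial_profile(circ, c(0.5, 0))
  expect_error(slice_residuals(p0, off), class = "dwidistort_contract_error")
})

test_that("RMS reduction pools slices and splits the posterior half", {
  expect_equal(rms_reduce(matrix(2, 3, 360))$rms_whole, 2)
  expect_equal(rms_reduce(matrix(2, 3, 360))$rms_posterior, 2)

  # 2 mm on the posterior angles only
  r <- rep(0, 360)
  r[dwidistort:::POSTERIOR_ANGLES + 1] <- 2
  red <- rms_reduce(matrix(r, 1, 360, byrow = TRUE))
  expect_equal(red$rms_posterior, 2)
  expect_equal(red$rms_whole, sqrt(2))

  # posterior half has exactly 180 angles and whole = posterior + anterior
  post <- dwidistort:::POSTERIOR_ANGLES
  expect_length(post, 180)
  expect_setequal(c(post, setdiff(0:359, post)), 0:359)

  # random table equals the direct formula
  set.seed(3)
  m <- matrix(rnorm(5 * 360), 5, 360)
  red2 <- rms_reduce(m)
  expect_equal(red2$rms_whole, sqrt(mean(m^2)), tolerance = 1e-12)
  expect_equal(red2$rms_posterior, sqrt(mean(m[, post + 1]^2)),
               tolerance = 1e-12)
  expect_error(rms_reduce(matrix(NA_real_, 1, 360)),
               class = "dwidistort_pairing_error")
})

test_that("measure_distortion has an exact zero and recovers known deformations", {
  ph <- small_phantom(seed = 71)
  z <- measure_distortion(ph$contours, ph$contours)
  expect_lt(z$rms_whole, 1e-9)
  expect_lt(z$rms_posterior, 1e-9)

  # uniform radial dilation: RMS equals the dilation within 1%
  adc <- distort_contours(ph$contours, deformation_spec(2.5, mode = "dilate"))
  r <- measure_distortion(ph$contours, adc)
  expect_lt(abs(r$rms_whole - 2.5) / 2.5, 0.01)

  # rigid 5 mm shift is cancelled by translation registration
  sh <- apply_transform(ph$contours, mask_transform(c(0, 5, 0)))
  rs <- measure_distortion(ph$contours, sh, registration = "translation")
  expect_lt(rs$rms_whole, 0.2)

  # posterior bump raises the posterior RMS above the whole-gland RMS
  bump <- distort_contours(ph$contours, deformation_spec(4))
  rb <- measure_distortion(ph$contours, bump)
  expect_gt(rb$rms_posterior, rb$rms_whole)

  expect_error(
    measure_distortion(ph$contours,
                       apply_transform(ph$contours,
                                       mask_transform(c(100, 0, 0)))),
    class = "dwidistort_pairing_error")
})

test_that("the metric is invariant to joint whole-degree rotations", {
  ph <- small_phantom(seed = 81)
  adc <- distort_contours(ph$contours, deformation_spec(3))
  base <- measure_distortion(ph$contours, adc)$rms_whole
  for (ang in c(37, 180, -90)) {
    rotate_cs <- function(cs, ang) {
      sl <- lapply(cs$slices, function(s) {
        org <- slice_centroid(ph$contours$slices[[1]]$xy)
        th <- deg2rad(ang)
        xs <- s$xy[, 1] - org["x_mm"]; ys <- s$xy[, 2] - org["y_mm"]
        list(slice_index = s$slice_index,
             xy = cbind(xs * cos(th) - ys * sin(th) + org["x_mm"],
                        xs * sin(th) + ys * cos(th) + org["y_mm"]))
      })
      contour_set(sl, organ = cs$organ, position = cs$position,
                  spacing = cs$spacing)
    }
    r <- measure_distortion(rotate_cs(ph$contours, ang),
                            rotate_cs(adc, ang))$rms_whole
    expect_lt(abs(r - base), 1e-6)
  }
})
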