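test_that("NIfTI round-trip preserves voxels, spacing and label validation", {
  set.seed(42)
  vox <- array(sample(0:1, 10 * 32 * 32, replace = TRUE), c(10, 32, 32))
  vol <- label_volume(vox, c(3.0, 1.09, 1.09))
  f <- tempfile(fileext = ".nii.gz")
  write_label_volume(vol, f)
  back <- read_label_volume(f)
  expect_identical(back$voxels, vol$voxels)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-5)

  # invalid label and non-integer data are rejected
  expect_error(label_volume(array(7L, c(2, 2, 2)), c(1, 1, 1)),
               class = "dwidistort_label_error")
  iv <- intensity_volume(array(0.5, c(2, 2, 2)), c(1, 1, 1))
  f2 <- tempfile(fileext = ".nii.gz")
  write_intensity_volume(iv, f2)
  expect_error(read_label_volume(f2), class = "dwidistort_label_error")
  expect_error(read_label_volume(tempfile()), class = "dwidistort_format_error")
})

test_that("orientation normalization recovers content from permuted storage", {
  set.seed(7)
  vox <- array(sample(0:2, 6 * 8 * 10, replace = TRUE), c(6, 8, 10))
  vol <- label_volume(vox, c(3, 1.2, 1.1))

  # write the same volume with axes stored as (row, column, slice) and an
  # affine encoding that layout; normalization must undo it
  arrp <- aperm(vol$voxels, c(2, 3, 1))          # (j, i, k)
  aff <- matrix(0, 4, 4)
  aff[1, 2] <- -1.1; aff[2, 1] <- -1.2; aff[3, 3] <- 3; aff[4, 4] <- 1
  img <- RNifti::asNifti(arrp)
  RNifti::pixdim(img) <- c(1.2, 1.1, 3)
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  suppressMessages(back <- read_label_volume(f))
  expect_identical(back$voxels, vol$voxels)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-5)
})

test_that("rasterization matches brute-force point-in-polygon", {
  tpl <- grid_template(c(3L, 16L, 16L), c(3, 1, 1))
  sq <- square_polygon(0.25, 0.25, 10)
  cs <- contour_set(list(list(slice_index = 1L, xy = sq)), spacing = tpl$spacing)
  m <- mask_from_contours(cs, tpl)
  expect_equal(sum(m$voxels != 0), 100L)

  # oracle agreement on every voxel centre of the slice
  g <- expand.grid(x = 0:15, y = 0:15)
  expect_identical(as.vector(m$voxels[2, , ] != 0),
                   as.vector(matrix(pip_brute(g$x, g$y, sq), 16, 16,
                                    byrow = TRUE)))

  # circle area convergence: 2% at 0.5 mm, strictly better at finer voxels
  circ <- circle_polygon(10, c(16, 16), n = 720)
  area_err <- function(h) {
    npix <- ceiling(33 / h)
    tpl <- grid_template(c(1L, npix, npix), c(3, h, h))
    cs <- contour_set(list(list(slice_index = 0L, xy = circ)))
    m <- mask_from_contours(cs, tpl)
    abs(sum(m$voxels != 0) * h^2 - 100 * pi) / (100 * pi)
  }
  expect_lt(area_err(0.5), 0.02)
  errs <- c(area_err(1.0), area_err(0.25))
  expect_lt(errs[2], errs[1])
})

test_that("contour extraction round-trips rasterized masks", {
  ph <- small_phantom(seed = 21)
  m1 <- ph$prostate
  c2 <- contours_from_mask(m1, "prostate")
  a_ref <- vapply(ph$contours$slices, function(s) polygon_area(s$xy), numeric(1))
  a_ext <- vapply(c2$slices, function(s) polygon_area(s$xy), numeric(1))
  expect_identical(sidx(c2), sidx(ph$contours))
  # per-slice area within one voxel-area per boundary voxel
  for (i in seq_along(a_ref)) {
    boundary <- 2 * (diff(range(c2$slices[[i]]$xy[, 1])) +
                       diff(range(c2$slices[[i]]$xy[, 2])))
    expect_lt(abs(a_ext[i] - a_ref[i]), boundary * 1.0)
  }
  # rasterize-extract-rasterize is idempotent on voxel sets
  tpl <- grid_template(dim(m1$voxels), m1$spacing)
  m2 <- mask_from_contours(c2, tpl)
  m3 <- mask_from_contours(contours_from_mask(m2, "prostate"), tpl)
  expect_identical(m2$voxels, m3$voxels)
})

test_that("multi-component slices keep the largest blob with a warning", {
  vox <- array(0L, c(1, 20, 20))
  vox[1, 3:5, 3:5] <- 1L          # 3x3 blob
  vox[1, 10:16, 10:16] <- 1L      # 7x7 blob
  m <- label_volume(vox, c(3, 1, 1))
  expect_warning(cs <- contours_from_mask(m, "prostate"), "components")
  expect_length(cs$slices, 1L)
  expect_gt(polygon_area(cs$slices[[1]]$xy), 30)  # it kept the 7x7 one

  # organ absent: empty set, not an error
  empty <- contours_from_mask(label_volume(array(0L, c(2, 4, 4)), c(3, 1, 1)),
                              "prostate")
  expect_length(empty$slices, 0L)
  # and an empty contour set rasterizes to an all-zero mask
  z <- mask_from_contours(contour_set(list()), grid_template(c(2L, 4L, 4L), c(3, 1, 1)))
  expect_true(all(z$voxels == 0L))
})

test_that("contour CSV IO round-trips and rejects bad schemas", {
  ph <- small_phantom(seed = 31)
  f <- tempfile(fileext = ".csv")
  write_contours(ph$contours, f)
  back <- read_contours(f, spacing = ph$contours$spacing)
  expect_s3_class(back, "contour_set")
  expect_identical(sidx(back), sidx(ph$contours))
  expect_equal(back$slices[[3]]$xy, ph$contours$slices[[3]]$xy,
               tolerance = 1e-6, ignore_attr = TRUE)

  df <- utils::read.csv(f)
  df$extra <- 1
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, f2, row.names = FALSE)
  expect_error(read_contours(f2), class = "dwidistort_schema_error")

  # contour outside the grid extent
  big <- contour_set(list(list(slice_index = 0L,
                               xy = square_polygon(50, 50, 20))))
  expect_error(mask_from_contours(big, grid_template(c(1L, 10L, 10L), c(3, 1, 1))),
               class = "dwidistort_bounds_error")
  expect_error(mask_from_contours(
    contour_set(list(list(slice_index = 5L, xy = square_polygon(1, 1, 3)))),
    grid_template(c(2L, 10L, 10L), c(3, 1, 1))),
    class = "dwidistort_bounds_error")
})

test_that("score tables are validated against schema and scale", {
  df <- expand.grid(subject = sprintf("P%02d", 1:52), rater = 1:2)
  df$item <- "air_supine"
  set.seed(1)
  df$score <- sample(0:4, nrow(df), replace = TRUE)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  rec <- read_score_table(f, scale = 0:4)
  expect_equal(nrow(rec), 104L)
  expect_error(read_score_table(f, scale = 1:5),
               class = "dwidistort_validation_error")

  df2 <- df[, c("subject", "item", "score")]  # rater column missing
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(df2, f2, row.names = FALSE)
  expect_error(read_score_table(f2, scale = 0:4),
               class = "dwidistort_schema_error")
})
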