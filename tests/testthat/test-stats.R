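test_that("median and IQR follow the linear-interpolation convention", {
  expect_equal(median_iqr(1:5), c(median = 3, q1 = 2, q3 = 4))
  expect_equal(median_iqr(c(2, 2, 2)), c(median = 2, q1 = 2, q3 = 2))
  set.seed(12)
  x <- runif(1000)
  s <- sort(x)
  got <- median_iqr(x)
  # sorted-array oracle for type-7 quantiles
  q7 <- function(p) {
    h <- (length(s) - 1) * p
    lo <- floor(h)
    s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
  }
  expect_equal(unname(got), c(q7(0.5), q7(0.25), q7(0.75)), tolerance = 1e-12)
  expect_error(median_iqr(numeric(0)), class = "dwidistort_validation_error")
})

test_that("signed-rank test equals exhaustive sign enumeration", {
  a <- c(4.1, 5.2, 6.3, 2.2, 7.7, 3.1, 8.4, 1.9)
  b <- c(3.0, 5.9, 4.1, 2.9, 5.1, 3.0, 6.6, 2.5)
  expect_equal(wilcoxon_signed_rank(a, b)$p.value, wilcoxon_enum(a, b),
               tolerance = 1e-12)

  set.seed(31)
  for (i in 1:100) {
    n <- sample(5:10, 1)
    x <- sample(1:8, n, replace = TRUE)   # integer data: ties are common
    y <- sample(1:8, n, replace = TRUE)
    if (all(x == y)) next
    got <- suppressWarnings(wilcoxon_signed_rank(x, y)$p.value)
    expect_equal(got, wilcoxon_enum(x, y), tolerance = 1e-9)
  }

  # symmetry: flipping the pair leaves the two-sided p unchanged
  expect_equal(wilcoxon_signed_rank(a, b)$p.value,
               wilcoxon_signed_rank(b, a)$p.value)
  # identical samples
  expect_warning(r <- wilcoxon_signed_rank(a, a), "zero")
  expect_equal(r$p.value, 1)
  # large-sample path agrees closely with the base implementation
  set.seed(5)
  x <- rnorm(60); y <- x + rnorm(60, 0.3)
  expect_equal(wilcoxon_signed_rank(x, y)$p.value,
               stats::wilcox.test(x, y, paired = TRUE, correct = TRUE,
                                  exact = FALSE)$p.value,
               tolerance = 1e-9)
})

test_that("Fisher exact p equals fixed-margin enumeration and is symmetric", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2)), 0.1,
               tolerance = 1e-9)
  set.seed(8)
  for (i in 1:40) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_2x2(tab)
    expect_equal(p, fisher_enum(tab), tolerance = 1e-9)
    expect_equal(p, fisher_exact_2x2(t(tab)), tolerance = 1e-12)
    expect_equal(p, fisher_exact_2x2(tab[2:1, 2:1]), tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)),
               class = "dwidistort_validation_error")
})

test_that("Gwet's AC2 matches a hand-worked table and its boundary cases", {
  # perfect agreement on a 4-point scale
  perfect <- cbind(c(1, 2, 3, 4, 2, 3), c(1, 2, 3, 4, 2, 3))
  expect_equal(gwet_ac2(perfect, levels = 1:4)$coefficient, 1)

  # ten-subject example computed by hand:
  # r1 = 1 2 2 3 3 3 4 4 1 2 ; r2 = 1 2 3 3 3 4 4 4 2 2 (scale 1..4)
  # quadratic weights: agreement 1 for equal, 8/9 for |d| = 1
  # p_a = (7 * 1 + 3 * 8/9) / 10 = 29/30
  # pi = ((.2,.3,.3,.2) + (.1,.3,.3,.3)) / 2 = (.15,.3,.3,.25)
  # sum pi (1 - pi) = 0.735 ; T_w = 16 - 40/9 = 104/9
  # p_e = (104/9) / 12 * 0.735 = 15288/21600
  # AC2 = (29/30 - p_e) / (1 - p_e) = 5592/6312
  r1 <- c(1, 2, 2, 3, 3, 3, 4, 4, 1, 2)
  r2 <- c(1, 2, 3, 3, 3, 4, 4, 4, 2, 2)
  res <- gwet_ac2(cbind(r1, r2), levels = 1:4)
  expect_equal(res$p_a, 29 / 30, tolerance = 1e-12)
  expect_equal(res$p_e, 15288 / 21600, tolerance = 1e-12)
  expect_equal(res$coefficient, 5592 / 6312, tolerance = 1e-9)
  expect_equal(res$interpretation, "almost perfect")

  # monotone degradation with label noise (averaged over seeds)
  mean_ac2 <- function(noise) {
    mean(vapply(1:30, function(s) {
      set.seed(s)
      base <- sample(1:5, 40, replace = TRUE)
      flip <- runif(40) < noise
      other <- pmin(5, pmax(1, base + sample(c(-1, 1), 40, replace = TRUE)))
      gwet_ac2(cbind(base, ifelse(flip, other, base)),
               levels = 1:5)$coefficient
    }, numeric(1)))
  }
  curve <- vapply(c(0, 0.2, 0.5, 0.9), mean_ac2, numeric(1))
  expect_equal(curve[1], 1)
  expect_true(all(diff(curve) < 0))

  expect_error(gwet_ac2(cbind(r1, r2, r1)),
               class = "dwidistort_unsupported_error")
  expect_error(gwet_ac2(cbind(r1, r2), levels = 1:3),
               class = "dwidistort_validation_error")
})

test_that("logistic threshold handles separation and recovers the crossover", {
  # noiseless labels: perfect separation flagged, midpoint reported
  vols <- 1:10
  lab <- as.integer(vols > 5.5)
  r <- logistic_air_threshold(vols, lab)
  expect_true(r$separated)
  expect_equal(r$v_thresh_air, 5.5)

  # simulated cohorts with a probability-0.5 crossover at 4 cm^3
  set.seed(202)
  thr <- vapply(1:20, function(i) {
    air <- rlnorm(200, 0.67, 1.3)
    y <- rbinom(200, 1, plogis(air - 4))
    logistic_air_threshold(air, y)$v_thresh_air
  }, numeric(1))
  expect_lt(abs(median(thr) - 4), 0.5)

  # coefficients match an independent Newton-Raphson fit
  set.seed(7)
  air <- rlnorm(80, 0.7, 1)
  y <- rbinom(80, 1, plogis(air - 2))
  fit <- logistic_air_threshold(air, y)
  nr <- logistic_nr(air, y)
  expect_equal(c(fit$beta0, fit$beta1), nr, tolerance = 1e-6,
               ignore_attr = TRUE)

  # decreasing response is refused
  set.seed(9)
  aird <- rlnorm(40, 1, 1)
  yd <- rbinom(40, 1, plogis(4 - aird))
  expect_error(logistic_air_threshold(aird, yd),
               class = "dwidistort_model_error")
  expect_error(logistic_air_threshold(1:5, c(0, 1, 0, 1, 0)),
               class = "dwidistort_validation_error")
})

test_that("subgroup comparison reports paired medians, p-values and scatter", {
  co <- make_cohort(cohort_spec(n = 30, seed = 14))$cohort
  # prone identical to supine: p = 1 everywhere, identical medians
  same <- co
  same$air_prone <- same$air_supine
  same$distortion_prone <- same$distortion_supine
  same <- cohort_table(same)
  s <- suppressWarnings(subgroup_compare(same, v_thresh = 4))
  expect_equal(s$whole$distortion$p_value, 1)
  expect_equal(s$whole$air$p_value, 1)
  expect_equal(s$whole$distortion$supine, s$whole$distortion$prone)

  # threshold above every volume: empty subgroup is not evaluable
  s2 <- subgroup_compare(co, v_thresh = max(co$air_supine) + 1)
  expect_false(s2$subgroup$evaluable)
  expect_equal(s2$n_subgroup, 0L)

  s3 <- subgroup_compare(co, v_thresh = 4)
  expect_equal(nrow(s3$scatter), 2L * nrow(co))
  expect_true(all(s3$scatter$position %in% c("supine", "prone")))
})
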