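# Cohort statistics: descriptives, paired/unpaired nonparametric tests,
# chance-corrected inter-rater agreement, and the logistic air threshold.

#' Median and interquartile range
#'
#' Quartiles use the linear-interpolation convention (R quantile type 7).
#'
#' @param x Numeric vector with at least one finite value.
#' @return Named vector `c(median =, q1 =, q3 =)`.
#' @export
median_iqr <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) dd_stop("no finite values", "dwidistort_validation_error")
  q <- stats::quantile(x, probs = c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on paired differences.  Zero differences are dropped
#' (Wilcoxon's original convention).  The null distribution is exact for up
#' to 25 non-zero differences (full sign enumeration when the absolute
#' differences are tied and n <= 15, the signed-rank distribution
#' otherwise); larger samples use the normal approximation with tie
#' correction and continuity correction.  Two-sidedness is defined as
#' `P(|W - E[W]| >= |w - E[W]|)`, which the enumeration and distribution
#' paths share.
#'
#' @param a,b Paired numeric vectors.
#' @return List with `p.value`, `statistic` (W+, sum of positive ranks),
#'   `n` (non-zero pairs) and `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b))
    dd_stop("paired samples must have equal length",
            "dwidistort_validation_error")
  d <- a - b
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    dd_warn("all paired differences are zero; p = 1")
    return(list(p.value = 1, statistic = NA_real_, n = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties && n <= 25) {
    # symmetric exact distribution of W+ over 2^n sign assignments
    lo <- floor(min(w, 2 * mu - w))
    hi <- ceiling(max(w, 2 * mu - w))
    p <- stats::psignrank(lo, n) + (1 - stats::psignrank(hi - 1, n))
    method <- "exact (signed-rank distribution)"
  } else if (ties && n <= 15) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wall <- as.vector(signs %*% r)
    p <- mean(abs(wall - mu) >= abs(w - mu) - 1e-9)
    method <- "exact (sign enumeration, mid-ranks)"
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    z <- (w - mu - 0.5 * sign(w - mu)) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (continuity-corrected)"
  }
  if (n < 5)
    dd_warn(sprintf("only %d non-zero differences; test is uninformative", n))
  list(p.value = min(1, p), statistic = w, n = n, method = method)
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided by minimum-likelihood summation of hypergeometric
#' probabilities.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    dd_stop("table must be 2x2", "dwidistort_validation_error")
  if (any(tab < 0) || !all(is_wholenumber(tab)))
    dd_stop("table cells must be non-negative integers",
            "dwidistort_validation_error")
  stats::fisher.test(round(tab))$p.value
}

#' Interpretation bands for chance-corrected agreement
#'
#' @param coefficient Agreement coefficient in `[-1, 1]`.
#' @return Character label.
#' @export
agreement_band <- function(coefficient) {
  if (coefficient < 0) "poor"
  else if (coefficient <= 0.20) "slight"
  else if (coefficient <= 0.40) "fair"
  else if (coefficient <= 0.60) "moderate"
  else if (coefficient <= 0.80) "substantial"
  else "almost perfect"
}

#' Gwet's AC2 agreement coefficient (two raters, quadratic weights)
#'
#' Chance-corrected agreement for ordinal ratings, robust to prevalence
#' imbalance.  With categories 1..q and quadratic weights
#' `w_kl = 1 - (k - l)^2 / (q - 1)^2`, percent agreement is the mean
#' weighted agreement across subjects, and chance agreement follows Gwet's
#' AC formulation with category propensities averaged over raters:
#' `p_e = T_w / (q (q - 1)) * sum_k pi_k (1 - pi_k)` where `T_w` is the sum
#' of all weights.  AC2 = (p_a - p_e) / (1 - p_e).
#'
#' @param ratings n x 2 matrix or data.frame, one row per subject, columns =
#'   the two raters' ordinal scores.
#' @param levels The full ordinal scale (default: sorted unique observed
#'   values); scores outside it are an error.
#' @return List with `coefficient`, `p_a`, `p_e`, `q`, `n`, and
#'   `interpretation` (benchmark band).
#' @export
gwet_ac2 <- function(ratings, levels = NULL) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) != 2L)
    dd_stop("exactly two raters are supported", "dwidistort_unsupported_error")
  if (nrow(ratings) < 2L)
    dd_stop("need at least 2 subjects", "dwidistort_validation_error")
  levels <- levels %||% sort(unique(as.vector(ratings)))
  q <- length(levels)
  if (q < 2L)
    dd_stop("ordinal scale needs at least 2 categories",
            "dwidistort_validation_error")
  k1 <- match(ratings[, 1], levels)
  k2 <- match(ratings[, 2], levels)
  if (anyNA(k1) || anyNA(k2))
    dd_stop("ratings outside the declared scale", "dwidistort_validation_error")
  kk <- seq_len(q)
  w <- 1 - outer(kk, kk, function(a, b) (a - b)^2) / (q - 1)^2
  p_a <- mean(w[cbind(k1, k2)])
  pi_k <- (tabulate(k1, q) + tabulate(k2, q)) / (2 * nrow(ratings))
  p_e <- sum(w) / (q * (q - 1)) * sum(pi_k * (1 - pi_k))
  coefficient <- (p_a - p_e) / (1 - p_e)
  list(coefficient = coefficient, p_a = p_a, p_e = p_e, q = q,
       n = nrow(ratings), interpretation = agreement_band(coefficient))
}

#' Logistic-regression air-volume threshold
#'
#' Fits `P(appreciable) = plogis(b0 + b1 * air)` and reports the volume at
#' predicted probability 0.5, `v_thresh_air = -b0 / b1`, with the Wald
#' p-value of the slope.  Perfectly separated data are reported as the
#' midpoint between the class-extreme volumes with `separated = TRUE`
#' instead of divergent coefficient estimates.  A non-positive slope
#' (appreciable air *less* likely at larger volumes) is refused.
#'
#' @param air_cm3 Supine proximal air volumes, cm^3.
#' @param appreciable Binary indicator (e.g. Likert score >= 4), same
#'   length.
#' @return List with `v_thresh_air`, `beta0`, `beta1`, `p_value`,
#'   `separated`.
#' @export
logistic_air_threshold <- function(air_cm3, appreciable) {
  y <- as.integer(appreciable)
  if (length(air_cm3) != length(y))
    dd_stop("inputs must have equal length", "dwidistort_validation_error")
  if (!all(y %in% c(0L, 1L)))
    dd_stop("`appreciable` must be binary", "dwidistort_validation_error")
  if (length(y) < 10L)
    dd_stop("need at least 10 observations", "dwidistort_validation_error")
  if (length(unique(y)) < 2L)
    dd_stop("both outcome classes must be present",
            "dwidistort_validation_error")
  if (max(air_cm3[y == 0L]) < min(air_cm3[y == 1L])) {
    mid <- (max(air_cm3[y == 0L]) + min(air_cm3[y == 1L])) / 2
    return(list(v_thresh_air = mid, beta0 = NA_real_, beta1 = NA_real_,
                p_value = NA_real_, separated = TRUE))
  }
  fit <- suppressWarnings(stats::glm(y ~ air_cm3, family = stats::binomial()))
  beta <- stats::coef(fit)
  if (!is.finite(beta[2]) || beta[2] <= 0)
    dd_stop("logistic slope is not positive; no meaningful air threshold",
            "dwidistort_model_error")
  p_wald <- summary(fit)$coefficients[2, 4]
  list(v_thresh_air = unname(-beta[1] / beta[2]),
       beta0 = unname(beta[1]), beta1 = unname(beta[2]),
       p_value = unname(p_wald), separated = FALSE)
}
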