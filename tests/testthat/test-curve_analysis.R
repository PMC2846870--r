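make_curve_inputs <- function(e_vals, ratio_vals) {
  n <- length(e_vals)
  nc <- ceiling(sqrt(n))
  pad <- nc^2 - n
  list(e = matrix(c(e_vals, rep(NA_real_, pad)), ncol = nc),
       r = matrix(c(ratio_vals, rep(NA_real_, pad)), ncol = nc))
}

test_that("a constant-efficiency bin reproduces its value", {
  inp <- make_curve_inputs(rep(0.2, 100), rep(1.5, 100))
  cv <- build_ratio_curve(inp$e, inp$r, ratio_edges = c(1, 2))
  expect_lt(abs(cv$weighted_mean_e[1] - 0.2), 0.005 + 1e-12)  # half a bin
  expect_equal(cv$raw_mean_e[1], 0.2)
  expect_identical(cv$n_pixels[1], 100L)
})

test_that("rare outliers are discarded by frequency weighting but shift the raw mean", {
  e <- c(rep(0.05, 10000), rep(0.90, 10))
  inp <- make_curve_inputs(e, rep(1, length(e)))
  cv <- build_ratio_curve(inp$e, inp$r, ratio_edges = c(0.5, 2),
                          min_freq_frac = 0.05)
  # enumeration: modal bin holds 10000 at center 0.055; the 10-count outlier
  # bin is far below 5% of that and is dropped
  expect_equal(cv$weighted_mean_e[1], 0.055)
  expect_equal(cv$raw_mean_e[1], (10000 * 0.05 + 10 * 0.90) / 10010)
  expect_gt(cv$raw_mean_e[1] - 0.05, 8e-4)            # raw mean shifted up
  expect_lt(abs(cv$weighted_mean_e[1] - 0.055), 1e-12) # weighted mean did not move
})

test_that("min_freq_frac = 0 reduces the weighted mean to the raw mean", {
  set.seed(41)
  for (rep in 1:4) {
    e_vals <- runif(500, 0, 0.6)
    r_vals <- exp(runif(500, log(0.2), log(5)))
    inp <- make_curve_inputs(e_vals, r_vals)
    cv <- build_ratio_curve(inp$e, inp$r,
                            ratio_edges = log_spaced_edges(0.1, 10, 6),
                            min_freq_frac = 0)
    ok <- cv$n_pixels > 0
    expect_true(all(abs(cv$weighted_mean_e[ok] - cv$raw_mean_e[ok]) <= 0.005 + 1e-12))
  }
})

test_that("curve construction validates its inputs", {
  inp <- make_curve_inputs(rep(0.2, 10), rep(1, 10))
  expect_error(build_ratio_curve(inp$e, inp$r, ratio_edges = c(2, 1)),
               "strictly increasing")
  empty <- matrix(NA_real_, 3, 3)
  expect_error(build_ratio_curve(empty, empty, ratio_edges = c(1, 2)),
               "no evaluable")
})

test_that("sigmoid fitting recovers known parameters", {
  rho <- exp(seq(log(0.1), log(10), length.out = 8))
  pts <- data.frame(ratio = rho, e = sigmoid_efficiency(rho, 0.30, 1.0, 2),
                    n = rep(100, 8))
  fit <- fit_sigmoid(pts)
  expect_false(fit$degenerate)
  expect_equal(fit$e_max, 0.30, tolerance = 0.01 * 0.30)
  expect_equal(fit$k, 1.0, tolerance = 0.01)
  expect_equal(fit$h, 2.0, tolerance = 0.02)
  expect_lt(fit$rss, 1e-10)

  # refit tolerates sigma = 0.01 Gaussian noise on the points
  set.seed(53)
  noisy <- pts
  noisy$e <- noisy$e + rnorm(8, 0, 0.01)
  fit2 <- fit_sigmoid(noisy)
  expect_equal(fit2$e_max, 0.30, tolerance = 0.05 * 0.30)
})

test_that("flat curves yield a degenerate fit and small inputs error", {
  flat <- data.frame(ratio = c(0.5, 1, 2, 4), e = rep(0.2, 4), n = rep(10, 4))
  fit <- fit_sigmoid(flat)
  expect_true(fit$degenerate)
  expect_equal(fit$e_max, 0.2)
  expect_true(is.na(fit$h))

  expect_error(fit_sigmoid(data.frame(ratio = 1:3, e = rep(0.1, 3))),
               "at least 4")
})

test_that("the Förster relation and its inverse behave as a closed form", {
  expect_equal(estimate_distance(0.5, r0_nm = 4.9)$r_nm, 4.9)
  # limit: r -> 0 as E -> 1 (one part in 1e6 from the tenth of R0)
  expect_lt(estimate_distance(0.999999, r0_nm = 4.9)$r_nm, 0.1 * 4.9 + 1e-6)
  expect_lt(estimate_distance(0.9999999, r0_nm = 4.9)$r_nm, 0.1 * 4.9)

  # reported-magnitude check under the assumed Förster radius
  expect_equal(estimate_distance(0.168, r0_nm = 4.9)$r_nm, 6.40,
               tolerance = 0.005)

  # round-trip r -> E -> r across the whole usable range
  for (e in seq(0.01, 0.99, by = 0.01)) {
    r <- estimate_distance(e, r0_nm = 4.9)$r_nm
    e_back <- distance_to_efficiency(r, r0_nm = 4.9)
    r_back <- estimate_distance(e_back, r0_nm = 4.9)$r_nm
    expect_lt(abs(r_back - r) / r, 1e-9)
  }

  expect_error(estimate_distance(0), "inside")
  expect_error(estimate_distance(1), "inside")
  expect_error(estimate_distance(0.5, r0_nm = -1), "positive")

  # monotone: higher plateau efficiency means shorter distance
  rs <- vapply(c(0.1, 0.2, 0.4, 0.8), function(e) estimate_distance(e)$r_nm,
               numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("curve comparison flags constructed separation and not identity", {
  edges <- log_spaced_edges(0.1, 10, 8)
  mk <- function(e_max) {
    e_vals <- ratio_vals <- numeric(0)
    for (i in seq_len(8)) {
      center <- sqrt(edges[i] * edges[i + 1])
      e_vals <- c(e_vals, rep(sigmoid_efficiency(center, e_max, 1, 2), 50))
      ratio_vals <- c(ratio_vals, rep(center, 50))
    }
    inp <- make_curve_inputs(e_vals, ratio_vals)
    curve <- build_ratio_curve(inp$e, inp$r, ratio_edges = edges)
    list(fit = fit_sigmoid(curve), curve = curve)
  }
  sample <- mk(0.25)
  baseline <- mk(0.08)  # random-FRET-like level

  cmp <- compare_curves(sample, baseline)
  expect_true(cmp$specific)
  expect_gt(cmp$e_max_difference, 0.1)

  ident <- compare_curves(sample, sample)
  expect_false(ident$specific)
  expect_true(all(ident$bins$delta == 0))

  swapped <- compare_curves(baseline, sample)  # everywhere below baseline
  expect_false(swapped$specific)

  disjoint <- mk(0.25)
  disjoint$curve$ratio_low <- disjoint$curve$ratio_low + 100
  disjoint$curve$ratio_high <- disjoint$curve$ratio_high + 100
  expect_error(compare_curves(sample, disjoint), "no overlapping")
})
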