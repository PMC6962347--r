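# Time-to-peak extraction and RANSAC line fitting.

map_with_impulses <- function(peak_times, xs, ts) {
  m <- matrix(0, length(xs), length(ts))
  for (i in seq_along(xs)) {
    m[i, which.min(abs(ts - peak_times[i]))] <- 1
  }
  space_time_map(m, xs, ts, "rightward")
}

test_that("impulse peaks are located exactly, ties break earliest", {
  xs <- seq(0, 0.02, by = 1e-3)
  ts <- seq(0, 10e-3, by = 1e-4)
  map <- map_with_impulses(xs / 4, xs, ts)
  pts <- time_to_peak(map)
  expect_equal(pts$t, ts[sapply(xs / 4, function(t0) {
    which.min(abs(ts - t0))
  })])
  # constant map: every column peaks at the first sample by the tie rule
  flat <- space_time_map(matrix(1, length(xs), length(ts)), xs, ts)
  expect_equal(time_to_peak(flat)$t, rep(ts[1], length(xs)))
})

test_that("crop restricts the search window", {
  xs <- seq(0, 0.02, by = 1e-3)
  ts <- seq(0, 10e-3, by = 1e-4)
  map <- map_with_impulses(xs / 4, xs, ts)
  crop <- crop_window(lateral_range = c(0.005, 0.015))
  pts <- time_to_peak(map, crop)
  expect_true(all(pts$x >= 0.005 & pts$x <= 0.015))
  expect_error(
    time_to_peak(map, crop_window(lateral_range = c(0.1, 0.2))),
    ">= 3 lateral"
  )
})

test_that("collinear points give an exact fit with full consensus", {
  x <- seq(0, 0.018, by = 0.002)
  pts <- data.frame(x = x, t = 1e-3 + x / 5)
  est <- fit_group_velocity(pts)
  expect_equal(est$velocity, 5, tolerance = 1e-9)
  expect_equal(est$inlier_ratio, 1)
  expect_true(est$passed_quality)
})

test_that("gross outliers are rejected and flagged in the inlier ratio", {
  x <- seq(0, 0.018, by = 0.002) # 10 points
  t <- 2e-3 + x / 4
  t[c(3, 6, 9)] <- t[c(3, 6, 9)] + c(5e-3, -4e-3, 6e-3)
  pts <- data.frame(x = x, t = t)
  est <- fit_group_velocity(pts, residual_threshold = 2e-4)
  expect_equal(est$velocity, 4, tolerance = 0.01)
  expect_equal(est$inlier_ratio, 0.7)
  expect_true(est$passed_quality)
  oracle <- brute_force_fit(x, t, 2e-4)
  expect_equal(est$velocity, unname(oracle$velocity), tolerance = 1e-12)
})

test_that("consensus below one half fails the quality gate", {
  # 4 points on a line, 6 scattered far from any 5-point consensus
  x <- seq(0, 0.018, by = 0.002)
  t <- x / 5
  t[5:10] <- c(9, -7, 15, -12, 20, -18) * 1e-3
  est <- fit_group_velocity(data.frame(x = x, t = t),
    residual_threshold = 1e-4
  )
  expect_equal(est$inlier_ratio, 0.4)
  expect_false(est$passed_quality)
})

test_that("consensus equals exhaustive search on random small instances", {
  set.seed(202)
  for (rep in 1:100) {
    n <- sample(5:12, 1)
    x <- sort(runif(n, 0, 0.02))
    t <- 1e-3 + x / runif(1, 2, 8) + rnorm(n, 0, 2e-4)
    out <- runif(n) < 0.3
    t[out] <- t[out] + sample(c(-1, 1), sum(out), TRUE) * runif(sum(out),
      3e-3, 8e-3)
    thr <- 5e-4
    est <- fit_group_velocity(data.frame(x = x, t = t),
      residual_threshold = thr)
    oracle <- brute_force_fit(x, t, thr)
    expect_equal(sum(est$inlier_ratio * est$n_points), oracle$count)
    expect_equal(est$velocity, unname(oracle$velocity), tolerance = 1e-12)
  }
})

test_that("velocity is scale-equivariant in time and amplitude-invariant", {
  x <- seq(0, 0.018, by = 0.002)
  pts <- data.frame(x = x, t = 1e-3 + x / 5)
  base <- fit_group_velocity(pts)
  stretched <- fit_group_velocity(
    data.frame(x = x, t = 2 * pts$t),
    residual_threshold = 1e-3
  )
  expect_equal(stretched$velocity, base$velocity / 2, tolerance = 1e-9)
  # amplitude scaling of the map does not move the peaks
  sim <- constant_sim(grid = test_grid(n_depth = 1))
  map <- depth_average(directional_filter(sim$field)$rightward, sim$roi,
    "rightward")
  map10 <- space_time_map(10 * map$values, map$lateral_positions, map$times,
    "rightward")
  e1 <- estimate_group_velocity(map)
  e2 <- estimate_group_velocity(map10)
  expect_equal(e1$velocity, e2$velocity)
})

test_that("simulated 5 m/s packet has TTP slope 1/5 s per m", {
  sim <- constant_sim(c0 = 5, grid = test_grid(n_depth = 1))
  map <- depth_average(directional_filter(sim$field)$rightward, sim$roi,
    "rightward")
  pts <- time_to_peak(map)
  slope <- coef(lm(t ~ x, pts))[2]
  expect_equal(unname(slope), 1 / 5, tolerance = 0.05)
  est <- estimate_group_velocity(map)
  expect_equal(est$velocity, 5, tolerance = 0.05)
  expect_true(est$passed_quality)
})

test_that("noisy recovery stays within 10 percent on average", {
  vels <- sapply(1:12, function(seed) {
    sim <- constant_sim(c0 = 5, grid = test_grid(n_depth = 1),
      seed = seed, snr_db = 10)
    map <- depth_average(directional_filter(sim$field)$rightward, sim$roi,
      "rightward")
    est <- estimate_group_velocity(map, seed = seed)
    expect_true(est$passed_quality)
    est$velocity
  })
  expect_equal(mean(vels), 5, tolerance = 0.1)
})

test_that("directional estimates combine by the stated averaging rule", {
  mk <- function(v, passed) {
    structure(list(velocity = v, inlier_ratio = if (passed) 0.8 else 0.3,
      n_points = 10, passed_quality = passed, span_ok = TRUE,
      direction = "x"), class = "group_velocity_estimate")
  }
  both <- combine_direction_estimates(mk(4.0, TRUE), mk(4.4, TRUE))
  expect_equal(both$velocity, 4.2)
  one <- combine_direction_estimates(mk(4.0, TRUE), mk(9.9, FALSE))
  expect_equal(one$velocity, 4.0)
  none <- combine_direction_estimates(mk(4.0, FALSE), mk(9.9, FALSE))
  expect_true(is.na(none$velocity))
  expect_false(none$passed_quality)
})

test_that("degenerate fits return a failure estimate", {
  pts <- data.frame(x = rep(0.01, 5), t = seq(0, 4e-3, by = 1e-3))
  est <- fit_group_velocity(pts)
  expect_false(est$passed_quality)
  expect_true(is.na(est$velocity))
})
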