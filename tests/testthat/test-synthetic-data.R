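# Synthetic wave-field and cohort generators: ground-truth contracts.

test_that("non-dispersive packet envelope translates at c0", {
  c0 <- 5
  sim <- constant_sim(c0 = c0)
  # isolate the rightward packet so the counter-propagating one does not
  # bias the envelope position
  right <- directional_filter(sim$field)$rightward
  env_peak <- function(t_target) {
    ti <- which.min(abs(right$times - t_target))
    # envelope proxy: squared velocity averaged over one carrier period
    win <- max(1, ti - 12):min(length(right$times), ti + 12)
    e <- rowMeans(right$values[1, , win]^2)
    xs <- lateral_positions(sim$field$grid)
    i <- which.max(e)
    if (i > 1 && i < length(e)) { # parabolic sub-pixel refinement
      den <- e[i - 1] - 2 * e[i] + e[i + 1]
      xs[i] + 0.5 * (e[i - 1] - e[i + 1]) / den * (xs[2] - xs[1])
    } else {
      xs[i]
    }
  }
  t1 <- 4e-3
  t2 <- 6e-3
  shift <- env_peak(t2) - env_peak(t1)
  expect_lt(abs(shift - c0 * (t2 - t1)), sim$field$grid$lateral_spacing)
})

test_that("same seed gives bit-identical fields, noise is seed-pure", {
  g <- test_grid()
  cfg <- wave_sim_config(grid = g, roi = roi_rect(g), snr_db = 10, seed = 11L)
  f1 <- simulate_wavefield(cfg)
  f2 <- simulate_wavefield(cfg)
  expect_identical(f1$values, f2$values)
  cfg2 <- wave_sim_config(grid = g, roi = roi_rect(g), snr_db = 10, seed = 12L)
  expect_false(identical(simulate_wavefield(cfg2)$values, f1$values))
  # the generator does not disturb the caller's RNG stream
  set.seed(99)
  expected <- rnorm(3)
  set.seed(99)
  invisible(simulate_wavefield(cfg))
  expect_identical(rnorm(3), expected)
})

test_that("narrowband crest speeds of a dispersive field match the law", {
  law <- dispersion_law("plate_A0", h = 3e-3, c_T = 4)
  g <- test_grid(n_depth = 1)
  roi <- roi_rect(g)
  cfg <- wave_sim_config(grid = g, dispersion = law, roi = roi)
  right <- directional_filter(simulate_wavefield(cfg))$rightward
  dt <- g$frame_interval
  nt <- g$n_frames
  # crest-tracking oracle: narrowband-filter two probes 6 mm apart via an
  # FFT mask, then read the travel delay from the cross-spectrum phase
  crest_speed <- function(fc) {
    # probes 3.6 mm apart: under half a wavelength at every probed
    # frequency, so the cross-spectrum phase stays unwrapped
    i1 <- 45L
    i2 <- 57L
    dx_probe <- (i2 - i1) * g$lateral_spacing
    fax <- (seq_len(nt) - 1) / (nt * dt)
    fax[fax >= 1 / (2 * dt)] <- fax[fax >= 1 / (2 * dt)] - 1 / dt
    band <- abs(abs(fax) - fc) <= 30
    s1 <- fft(right$values[1, i1, ])
    s2 <- fft(right$values[1, i2, ])
    pos <- which(fax > 0 & band)
    # phase delay per frequency bin, weighted by cross-spectral energy:
    # the downstream probe lags, so its spectrum is rotated by -omega*tau
    wgt <- Mod(s1[pos] * s2[pos])
    dphi <- Arg(s1[pos] * Conj(s2[pos]))
    delay <- sum(wgt * dphi / (2 * pi * fax[pos])) / sum(wgt)
    dx_probe / delay
  }
  for (fc in c(250, 450)) {
    expect_equal(crest_speed(fc), evaluate_dispersion(law, fc),
      tolerance = 0.05
    )
  }
})

test_that("push positions inside the ROI are rejected", {
  g <- test_grid()
  roi <- roi_rect(g)
  xs <- lateral_positions(g)
  mid <- mean(range(xs[roi$lateral_cols]))
  expect_error(
    wave_sim_config(grid = g, roi = roi, push_positions = c(mid, mid + 1e-3)),
    "push positions"
  )
})

test_that("IQ phase increment encodes velocity by the Doppler relation", {
  g <- acquisition_grid(
    n_depth = 3, n_lateral = 8, n_frames = 10,
    center_frequency = 5e6, sound_speed = 1540, frame_interval = 1e-4
  )
  v0 <- 0.01
  f <- particle_velocity_field(
    array(v0, dim = c(3, 8, 10)), g, frame_times(g)
  )
  iq <- modulate_to_iq(f, scatter_seed = 3L)
  dphi <- Arg(iq$samples[, , 2:11] * Conj(iq$samples[, , 1:10]))
  expect_equal(
    as.vector(dphi),
    rep(4 * pi * 5e6 * v0 * 1e-4 / 1540, length(dphi)),
    tolerance = 1e-10
  )
  # zero field: constant-in-time complex samples
  f0 <- particle_velocity_field(array(0, c(3, 8, 10)), g, frame_times(g))
  iq0 <- modulate_to_iq(f0)
  expect_equal(iq0$samples[, , 1], iq0$samples[, , 10])
})

test_that("velocities at or beyond the aliasing limit are rejected", {
  g <- acquisition_grid(n_depth = 2, n_lateral = 8, n_frames = 6)
  lim <- aliasing_limit(g)
  f <- particle_velocity_field(array(lim * 1.01, c(2, 8, 6)), g, frame_times(g))
  expect_error(modulate_to_iq(f), "aliasing limit")
})

test_that("default cohort has the 27-plaque AHA group structure", {
  co <- simulate_cohort(cohort_sim_config(seed = 5L))
  one_view <- co[co$view == "L", ]
  expect_equal(nrow(one_view), 27)
  expect_equal(
    as.vector(table(one_view$aha_type)[c("III", "V", "VI", "VII")]),
    c(7, 8, 8, 4)
  )
  expect_equal(sort(unique(co$view)), c("L", "T"))
})

test_that("zero-SD noise-free cohort collapses to group means", {
  params <- default_velocity_parameters()
  cfg <- cohort_sim_config(
    velocity_sds = params$sds * 0, acquisition_sd = 0,
    components = NULL, seed = 2L
  )
  co <- simulate_cohort(cfg)
  for (v in c("L", "T")) {
    sub <- co[co$view == v & co$aha_type == "VI", ]
    expect_equal(sub$gv_mean, rep(params$means["VI", v, "gv"], nrow(sub)))
    expect_equal(sub$gv_sd, rep(0, nrow(sub)))
  }
})

test_that("component generator hits its target correlation at large n", {
  comp <- data.frame(
    name = "probe", mean = 10, sd = 3, anchor = "gv_L", target_r = 0.8,
    missing_fraction = 0, clip_lo = -Inf, clip_hi = Inf
  )
  cfg <- cohort_sim_config(
    group_sizes = c(III = 500), components = comp, seed = 31L
  )
  co <- simulate_cohort(cfg)
  sub <- co[co$view == "L", ]
  expect_equal(cor(sub$gv_mean, sub$probe), 0.8, tolerance = 0.05 / 0.8)
})

test_that("cohort generator recovers configured means and SDs at large n", {
  cfg <- cohort_sim_config(
    group_sizes = c(VI = 400), acquisition_sd = 0, components = NULL,
    seed = 17L
  )
  co <- simulate_cohort(cfg)
  sub <- co[co$view == "T", ]
  expect_equal(mean(sub$gv_mean), 7.3, tolerance = 3 * 2.5 / sqrt(400) / 7.3)
  expect_equal(sd(sub$gv_mean), 2.5, tolerance = 0.15)
})

test_that("missing fractions and seed purity hold for the cohort", {
  comp <- data.frame(
    name = "probe", mean = 10, sd = 3, anchor = "gv_L", target_r = 0,
    missing_fraction = 0.4, clip_lo = -Inf, clip_hi = Inf
  )
  cfg <- cohort_sim_config(
    group_sizes = c(III = 300), components = comp, seed = 9L
  )
  co <- simulate_cohort(cfg)
  frac <- mean(is.na(co$probe[co$view == "L"]))
  expect_gt(frac, 0.3)
  expect_lt(frac, 0.5)
  expect_identical(simulate_cohort(cfg), co)
})
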