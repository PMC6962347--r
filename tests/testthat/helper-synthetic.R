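# Shared fixtures for the synthetic-wave tests. All are built in code at
# test time; sizes are kept small where the physics allows it.

# Default-protocol grid with a shallow depth extent (fields are
# depth-uniform, so depth size only scales runtime).
test_grid <- function(n_depth = 4L, n_lateral = 128L, n_frames = 180L) {
  acquisition_grid(n_depth = n_depth, n_lateral = n_lateral,
    n_frames = n_frames)
}

# Depth-uniform field from a (lateral x time) matrix.
field_from_map <- function(m, grid, times = frame_times(grid)) {
  particle_velocity_field(
    array(rep(as.vector(m), each = grid$n_depth),
      dim = c(grid$n_depth, grid$n_lateral, length(times))),
    grid, times
  )
}

# Travelling monochromatic plane wave v(x, t) = sin(2 pi f (t - x / c)),
# sign of c sets the direction (positive = rightward).
plane_wave_field <- function(grid, f0, c0) {
  xs <- lateral_positions(grid)
  ts <- frame_times(grid)
  field_from_map(outer(xs, ts, function(x, t) sin(2 * pi * f0 * (t - x / c0))),
    grid)
}

field_energy <- function(field) sum(field$values^2)

# Noise-free constant-speed dual-push simulation used across modules.
constant_sim <- function(c0 = 5, grid = test_grid(), seed = 1L,
                         snr_db = Inf) {
  roi <- roi_rect(grid)
  cfg <- wave_sim_config(
    grid = grid, dispersion = dispersion_law("constant", c0 = c0),
    roi = roi, snr_db = snr_db, seed = seed
  )
  list(field = simulate_wavefield(cfg), roi = roi, config = cfg)
}

# Independent brute-force oracle for the consensus line fit: every
# 2-point line, inliers by the same residual gate, consensus by count
# then residual RMS, OLS refit on the consensus set.
brute_force_fit <- function(x, t, thr) {
  best <- NULL
  for (i in seq_along(x)) {
    for (j in seq_along(x)) {
      if (j <= i || x[j] == x[i]) next
      slope <- (t[j] - t[i]) / (x[j] - x[i])
      res <- abs(t - (t[i] + slope * (x - x[i])))
      inl <- res <= thr
      cnt <- sum(inl)
      rms <- sqrt(mean(res[inl]^2))
      if (is.null(best) || cnt > best$cnt ||
        (cnt == best$cnt && rms < best$rms)) {
        best <- list(cnt = cnt, rms = rms, inl = inl)
      }
    }
  }
  fit <- lm(t[best$inl] ~ x[best$inl])
  list(velocity = 1 / abs(coef(fit)[2]), count = best$cnt, inl = best$inl)
}

# Uniform-phase-increment IQ ensemble: constant speckle amplitude, phase
# advancing by dphi per frame everywhere.
uniform_increment_iq <- function(grid, dphi) {
  npx <- grid$n_depth * grid$n_lateral
  ph <- outer(rep(1, npx), (seq_len(grid$n_frames) - 1) * dphi)
  iq_ensemble(
    array(complex(modulus = 1, argument = ph),
      dim = c(grid$n_depth, grid$n_lateral, grid$n_frames)),
    grid
  )
}
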