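#' Plaque region-of-interest mask
#'
#' A boolean (depth x lateral) mask delineating the plaque in the imaging
#' plane. The lateral extent of the mask (columns containing any TRUE
#' pixel) must be contiguous, matching a visually traced plaque border.
#'
#' @param mask Logical matrix, `n_depth` rows x `n_lateral` columns.
#' @return An object of class `roi_mask`.
#' @seealso [roi_rect()] for the common rectangular case.
#' @export
roi_mask <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("ROI mask has no TRUE pixel", call. = FALSE)
  cols <- which(apply(mask, 2, any))
  if (!all(diff(cols) == 1L)) {
    stop("ROI lateral extent must be contiguous", call. = FALSE)
  }
  structure(list(mask = mask, lateral_cols = cols), class = "roi_mask")
}

#' Rectangular ROI covering index ranges of a grid
#'
#' @param grid An [acquisition_grid()].
#' @param depth_rows,lateral_cols Integer index ranges (vectors) of pixels
#'   inside the ROI; defaults cover the full depth and the central half of
#'   the lateral aperture.
#' @return An `roi_mask`.
#' @export
roi_rect <- function(grid,
                     depth_rows = seq_len(grid$n_depth),
                     lateral_cols = seq(
                       floor(grid$n_lateral / 4) + 1L,
                       floor(3 * grid$n_lateral / 4)
                     )) {
  m <- matrix(FALSE, grid$n_depth, grid$n_lateral)
  m[depth_rows, lateral_cols] <- TRUE
  roi_mask(m)
}

#' Axial particle-velocity movie
#'
#' @param values Real array (m/s) over (depth, lateral, slow-time).
#' @param grid The [acquisition_grid()] the movie was sampled on.
#' @param times Slow-time instants (s) of the frames; length `dim(values)[3]`.
#' @return An object of class `particle_velocity_field`.
#' @export
particle_velocity_field <- function(values, grid, times) {
  stopifnot(
    is.array(values), length(dim(values)) == 3,
    inherits(grid, "acquisition_grid"),
    dim(values)[1] == grid$n_depth, dim(values)[2] == grid$n_lateral,
    length(times) == dim(values)[3], all(is.finite(values))
  )
  structure(list(values = values, grid = grid, times = as.numeric(times)),
    class = "particle_velocity_field"
  )
}

#' Complex baseband (IQ) ultrasound ensemble
#'
#' @param samples Complex array over (depth, lateral, slow-time);
#'   at least 2 slow-time frames.
#' @param grid The [acquisition_grid()].
#' @return An object of class `iq_ensemble`.
#' @export
iq_ensemble <- function(samples, grid) {
  stopifnot(
    is.array(samples), is.complex(samples), length(dim(samples)) == 3,
    inherits(grid, "acquisition_grid"),
    dim(samples)[1] == grid$n_depth, dim(samples)[2] == grid$n_lateral,
    dim(samples)[3] >= 2, all(is.finite(samples))
  )
  structure(list(samples = samples, grid = grid), class = "iq_ensemble")
}

#' Configuration for the synthetic shear-wave-field generator
#'
#' Describes a dual-sided acoustic radiation force push: two focused push
#' beams triggered simultaneously on the left and right flanks of the ROI,
#' launching a rightward and a leftward travelling dispersive wave packet.
#'
#' @param grid An [acquisition_grid()].
#' @param dispersion A [dispersion_law()] giving the phase velocity of each
#'   frequency component.
#' @param roi An `roi_mask`; push positions must lie on or outside its
#'   lateral edges.
#' @param push_positions Length-2 numeric: lateral coordinates (m) of the
#'   left and right push. Default: 1.5 mm outside each ROI edge.
#' @param push_time Push trigger time (s) relative to the first frame.
#' @param push_duration Push length (s); default 400 microseconds. Acts as
#'   a mild sinc low-pass on the packet spectrum.
#' @param amplitude Peak particle velocity of the noise-free field (m/s).
#' @param snr_db Signal-to-noise ratio in dB (Gaussian noise, power ratio
#'   vs the signal RMS); `Inf` for noise-free.
#' @param center_hz,bandwidth_hz Packet spectrum: Gaussian amplitude
#'   profile centred at `center_hz` with -6 dB (half-amplitude) full width
#'   `bandwidth_hz`, so all three 200-500 Hz analysis bands carry energy.
#' @param seed Integer seed; identical seeds give bit-identical fields.
#' @return An object of class `wave_sim_config`.
#' @export
wave_sim_config <- function(grid = acquisition_grid(),
                            dispersion = dispersion_law("constant", c0 = 5),
                            roi = roi_rect(grid),
                            push_positions = NULL,
                            push_time = 1e-3,
                            push_duration = 4e-4,
                            amplitude = 0.01,
                            snr_db = Inf,
                            center_hz = 400,
                            bandwidth_hz = 500,
                            seed = 1L) {
  stopifnot(
    inherits(grid, "acquisition_grid"), inherits(dispersion, "dispersion_law"),
    inherits(roi, "roi_mask"),
    push_duration > 0, amplitude > 0, push_time >= 0,
    center_hz > 0, bandwidth_hz > 0
  )
  if (nrow(roi$mask) != grid$n_depth || ncol(roi$mask) != grid$n_lateral) {
    stop("ROI mask dimensions do not match the grid", call. = FALSE)
  }
  xs <- lateral_positions(grid)
  roi_x <- range(xs[roi$lateral_cols])
  if (is.null(push_positions)) {
    push_positions <- c(roi_x[1] - 1.5e-3, roi_x[2] + 1.5e-3)
  }
  stopifnot(length(push_positions) == 2)
  if (push_positions[1] > roi_x[1] || push_positions[2] < roi_x[2]) {
    stop("push positions must lie on or outside opposite ROI lateral edges",
      call. = FALSE
    )
  }
  structure(
    list(
      grid = grid, dispersion = dispersion, roi = roi,
      push_positions = push_positions, push_time = push_time,
      push_duration = push_duration, amplitude = amplitude,
      snr_db = snr_db, center_hz = center_hz, bandwidth_hz = bandwidth_hz,
      seed = as.integer(seed)
    ),
    class = "wave_sim_config"
  )
}

# Gaussian amplitude spectrum with -6 dB full width `bw`, multiplied by the
# |sinc| of the finite push duration.
packet_spectrum <- function(f, center, bw, push_duration) {
  sigma <- (bw / 2) / sqrt(2 * log(2))
  a <- exp(-(f - center)^2 / (2 * sigma^2))
  x <- f * push_duration
  a * abs(ifelse(x == 0, 1, sin(pi * x) / (pi * x)))
}

#' Simulate a dispersive dual-push shear-wave field
#'
#' Synthesises the axial particle-velocity movie produced by a dual-sided
#' acoustic radiation force push: one rightward-travelling packet launched
#' at the left push position and one leftward packet at the right push
#' position. Each packet is a band-limited superposition of cosines whose
#' component at frequency `f` travels at `evaluate_dispersion(law, f)`;
#' with a constant law the envelope translates rigidly at `c0`. The field
#' is uniform over depth (the depth-averaging stage is exercised by the
#' ROI mask, not by depth structure). Zero-mean Gaussian noise is added at
#' the configured SNR.
#'
#' @param config A [wave_sim_config()].
#' @return A [particle_velocity_field()] with attribute `"truth"` holding
#'   the dispersion law and push geometry.
#' @export
simulate_wavefield <- function(config) {
  stopifnot(inherits(config, "wave_sim_config"))
  g <- config$grid
  xs <- lateral_positions(g)
  ts <- frame_times(g)
  # frequency comb: fine enough that the cosine sum is aperiodic over the
  # record (period 1/df = 80 ms >> 18 ms)
  df <- 12.5
  f <- seq(df, 1000, by = df)
  amp <- packet_spectrum(f, config$center_hz, config$bandwidth_hz,
    config$push_duration)
  keep <- amp > 1e-4 * max(amp)
  f <- f[keep]
  amp <- amp[keep]
  cph <- evaluate_dispersion(config$dispersion, f)
  t0 <- config$push_time + config$push_duration / 2

  v2d <- matrix(0, g$n_lateral, g$n_frames)
  tphase <- outer(f, ts - t0) * 2 * pi # (freq, time)
  for (side in 1:2) {
    s <- if (side == 1) 1 else -1 # +1: rightward from left push
    xrel <- xs - config$push_positions[side]
    kx <- outer(2 * pi * f / cph, xrel) # angular wavenumber phase (freq, x)
    for (i in seq_along(f)) {
      v2d <- v2d + amp[i] * cos(outer(-s * kx[i, ], tphase[i, ], `+`))
    }
  }
  v2d <- v2d * (config$amplitude / max(abs(v2d)))
  values <- array(rep(as.vector(v2d), each = g$n_depth),
    dim = c(g$n_depth, g$n_lateral, g$n_frames)
  )
  if (is.finite(config$snr_db)) {
    sig_rms <- sqrt(mean(values^2))
    noise_sd <- sig_rms * 10^(-config$snr_db / 20)
    if (max(abs(values)) + 6 * noise_sd < .Machine$double.xmin * 1e6) {
      stop("SNR so low the packet amplitude is subnormal", call. = FALSE)
    }
    values <- values + with_seed(
      config$seed,
      array(stats::rnorm(length(values), sd = noise_sd), dim = dim(values))
    )
  }
  out <- particle_velocity_field(values, g, ts)
  attr(out, "truth") <- list(
    dispersion = config$dispersion,
    push_positions = config$push_positions,
    onset_time = t0
  )
  out
}

#' Encode a particle-velocity movie as a synthetic IQ ensemble
#'
#' Writes the movie onto a random speckle background: each pixel gets a
#' Rayleigh amplitude (unit mean) and uniform initial phase, constant over
#' slow time, and the frame-to-frame phase increment encodes the axial
#' velocity by the Doppler relation
#' `d_phi = 4 * pi * f0 * v * dt / c`. An `n`-frame velocity movie yields
#' an `n + 1`-frame ensemble, so the round trip through
#' [estimate_particle_velocity()] reproduces the movie.
#'
#' @param field A [particle_velocity_field()] with all |v| strictly below
#'   the grid's [aliasing_limit()].
#' @param scatter_seed Integer seed for the speckle background.
#' @return An [iq_ensemble()].
#' @export
modulate_to_iq <- function(field, scatter_seed = 1L) {
  stopifnot(inherits(field, "particle_velocity_field"))
  g <- field$grid
  vmax <- max(abs(field$values))
  lim <- aliasing_limit(g)
  if (vmax >= lim) {
    stop(sprintf(
      "particle velocity %.4g m/s reaches the aliasing limit %.4g m/s (= sound_speed / (4 * center_frequency * frame_interval))",
      vmax, lim
    ), call. = FALSE)
  }
  d <- dim(field$values)
  dphi <- 4 * pi * g$center_frequency * field$values * g$frame_interval /
    g$sound_speed
  # cumulative phase over slow time, frame 1 = speckle phase only
  phase <- array(0, dim = c(d[1], d[2], d[3] + 1L))
  for (j in seq_len(d[3])) phase[, , j + 1L] <- phase[, , j] + dphi[, , j]
  speckle <- with_seed(scatter_seed, {
    npx <- d[1] * d[2]
    amp <- sqrt(2 / pi) * sqrt(-2 * log(stats::runif(npx)))
    ph0 <- stats::runif(npx, -pi, pi)
    list(amp = amp, ph0 = ph0)
  })
  phase <- phase + array(rep(speckle$ph0, d[3] + 1L), dim = dim(phase))
  samples <- array(rep(speckle$amp, d[3] + 1L), dim = dim(phase)) *
    exp(1i * phase)
  iq_ensemble(samples, g)
}
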