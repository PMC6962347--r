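#' Acquisition grid for ultrafast shear-wave tracking
#'
#' Describes the (depth, lateral, slow-time) sampling of an ultrafast
#' plane-wave acquisition. Defaults follow a clinical carotid protocol:
#' 0.3 mm pixel pitch in both spatial axes, a 10 kHz slow-time frame rate
#' (0.1 ms frame interval) and 180 frames giving an 18 ms record, a 5 MHz
#' tracking centre frequency and 1540 m/s sound speed.
#'
#' @param depth_spacing Axial pixel pitch in metres.
#' @param lateral_spacing Lateral pixel pitch in metres.
#' @param n_depth,n_lateral Number of pixels along depth and lateral axes.
#' @param frame_interval Slow-time sampling interval in seconds
#'   (reciprocal of the tracking frame rate).
#' @param n_frames Number of slow-time frames.
#' @param center_frequency Tracking centre frequency in Hz.
#' @param sound_speed Speed of sound in m/s used for phase-to-velocity
#'   conversion.
#'
#' @return An object of class `acquisition_grid`: a list with the above
#'   fields plus `duration = n_frames * frame_interval`.
#' @examples
#' g <- acquisition_grid()
#' g$duration # 18 ms
#' aliasing_limit(g)
#' @export
acquisition_grid <- function(depth_spacing = 0.3e-3,
                             lateral_spacing = 0.3e-3,
                             n_depth = 24L,
                             n_lateral = 128L,
                             frame_interval = 1e-4,
                             n_frames = 180L,
                             center_frequency = 5e6,
                             sound_speed = 1540) {
  stopifnot(
    depth_spacing > 0, lateral_spacing > 0,
    n_depth >= 1, n_lateral >= 1,
    frame_interval > 0, n_frames >= 2,
    center_frequency > 0, sound_speed > 0
  )
  structure(
    list(
      depth_spacing = depth_spacing,
      lateral_spacing = lateral_spacing,
      n_depth = as.integer(n_depth),
      n_lateral = as.integer(n_lateral),
      frame_interval = frame_interval,
      n_frames = as.integer(n_frames),
      duration = n_frames * frame_interval,
      center_frequency = center_frequency,
      sound_speed = sound_speed
    ),
    class = "acquisition_grid"
  )
}

#' Maximum unambiguous particle velocity
#'
#' The aliasing limit of Doppler phase tracking,
#' `sound_speed / (4 * center_frequency * frame_interval)`: the particle
#' velocity at which the frame-to-frame phase shift reaches pi and wraps.
#'
#' @param grid An [acquisition_grid()].
#' @return Velocity in m/s.
#' @export
aliasing_limit <- function(grid) {
  stopifnot(inherits(grid, "acquisition_grid"))
  grid$sound_speed / (4 * grid$center_frequency * grid$frame_interval)
}

#' Lateral pixel positions of a grid, in metres
#' @param grid An [acquisition_grid()].
#' @return Numeric vector of length `n_lateral`, starting at 0.
#' @export
lateral_positions <- function(grid) {
  (seq_len(grid$n_lateral) - 1L) * grid$lateral_spacing
}

#' Slow-time sample instants of a grid, in seconds
#' @param grid An [acquisition_grid()].
#' @return Numeric vector of length `n_frames`, starting at 0.
#' @export
frame_times <- function(grid) {
  (seq_len(grid$n_frames) - 1L) * grid$frame_interval
}

#' @export
print.acquisition_grid <- function(x, ...) {
  cat(sprintf(
    "<acquisition_grid> %d x %d px @ %.2f x %.2f mm, %d frames @ %.1f kHz (%.1f ms), f0 = %.1f MHz\n",
    x$n_depth, x$n_lateral, x$depth_spacing * 1e3, x$lateral_spacing * 1e3,
    x$n_frames, 1e-3 / x$frame_interval, x$duration * 1e3,
    x$center_frequency * 1e-6
  ))
  invisible(x)
}

# Run `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards, so generators are pure functions of seed.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
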