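#' Estimate axial particle velocity by 2D autocorrelation
#'
#' Doppler-type velocity estimator: at each pixel the lag-one slow-time
#' autocorrelation `R1 = iq[t+1] * Conj(iq[t])` is averaged over a
#' (depth x lateral x slow-time) kernel, and the phase angle of the
#' average is scaled to velocity by
#' `v = sound_speed / (4 * pi * center_frequency * frame_interval) * Arg(R1)`.
#' The principal value of the angle bounds the output by the
#' [aliasing_limit()] by construction; no phase unwrapping is attempted.
#'
#' The default kernel (5 depth pixels, 1 lateral, 2 correlation pairs)
#' averages along depth only, preserving the lateral resolution needed by
#' the time-to-peak stage.
#'
#' @param iq An [iq_ensemble()] with at least 2 slow-time frames.
#' @param kernel_depth,kernel_lateral,kernel_time Averaging extents in
#'   pixels / correlation pairs; each must be >= 1 and no larger than the
#'   corresponding data extent. Edges use the partial kernel.
#' @return A [particle_velocity_field()] with `n_frames - 1` frames,
#'   timestamped at the midpoints of consecutive frame pairs. Positive
#'   velocity is motion toward the transducer.
#' @examples
#' g <- acquisition_grid(n_depth = 4, n_lateral = 4, n_frames = 6)
#' iq <- iq_ensemble(array(complex(modulus = 1, argument = 0.1 *
#'   rep(0:5, each = 16)), c(4, 4, 6)), g)
#' v <- estimate_particle_velocity(iq)
#' range(v$values) # uniform velocity from the 0.1 rad/frame increment
#' @export
estimate_particle_velocity <- function(iq, kernel_depth = 5L,
                                       kernel_lateral = 1L,
                                       kernel_time = 2L) {
  stopifnot(inherits(iq, "iq_ensemble"))
  d <- dim(iq$samples)
  if (d[3] < 2) stop("need at least 2 slow-time frames", call. = FALSE)
  k <- c(as.integer(kernel_depth), as.integer(kernel_lateral),
    as.integer(kernel_time))
  if (any(k < 1)) stop("kernel sizes must be >= 1", call. = FALSE)
  if (k[1] > d[1] || k[2] > d[2] || k[3] > d[3] - 1L) {
    stop("kernel larger than data extent", call. = FALSE)
  }
  g <- iq$grid
  r1 <- iq$samples[, , 2:d[3], drop = FALSE] *
    Conj(iq$samples[, , 1:(d[3] - 1L), drop = FALSE])
  for (axis in 1:3) r1 <- box_sum_axis(r1, k[axis], axis)
  v <- g$sound_speed / (4 * pi * g$center_frequency * g$frame_interval) *
    Arg(r1)
  # frame-pair midpoints; an even slow-time kernel shifts the effective
  # sample instant by half a frame
  shift <- if (k[3] %% 2L == 0L) 0.5 else 0
  times <- (seq_len(d[3] - 1L) - 0.5 + shift) * g$frame_interval
  particle_velocity_field(v, g, times)
}

# Centred running sum of width k along one axis of a 3D array, edges
# truncated to the available window. Complex-safe. k = 1 is the identity.
box_sum_axis <- function(arr, k, axis) {
  if (k <= 1L) return(arr)
  d <- dim(arr)
  n <- d[axis]
  lo <- pmax(seq_len(n) - (k - 1L) %/% 2L, 1L)
  hi <- pmin(seq_len(n) + k %/% 2L, n)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = n)
  cs <- apply(m, 2, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = n)
  zero <- if (is.complex(arr)) 0 + 0i else 0
  top <- cs[hi, , drop = FALSE]
  bot <- rbind(rep(zero, ncol(cs)), cs)[lo, , drop = FALSE]
  out <- array(top - bot, dim = d[perm])
  aperm(out, order(perm))
}
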