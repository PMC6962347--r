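#' Depth-averaged space-time map of one propagation direction
#'
#' @param values Real matrix (m/s), lateral positions x slow-time.
#' @param lateral_positions Strictly increasing positions (m).
#' @param times Strictly increasing, uniformly spaced instants (s).
#' @param direction `"leftward"`, `"rightward"` or `"both"`.
#' @return An object of class `space_time_map`.
#' @export
space_time_map <- function(values, lateral_positions, times,
                           direction = c("both", "leftward", "rightward")) {
  direction <- match.arg(direction)
  stopifnot(
    is.matrix(values),
    nrow(values) == length(lateral_positions),
    ncol(values) == length(times),
    all(diff(lateral_positions) > 0), all(diff(times) > 0)
  )
  dt <- diff(times)
  if (length(dt) > 1 && max(abs(dt - dt[1])) > 1e-9 * dt[1]) {
    stop("times must be uniformly spaced", call. = FALSE)
  }
  structure(
    list(
      values = values, lateral_positions = as.numeric(lateral_positions),
      times = as.numeric(times), direction = direction
    ),
    class = "space_time_map"
  )
}

# Tukey (tapered cosine) window of length n; alpha is the total fraction
# of the window inside the cosine tapers.
tukey_window <- function(n, alpha = 0.25) {
  if (n == 1) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(2 * pi / alpha * (x[lo] - alpha / 2)))
  w[hi] <- 0.5 * (1 + cos(2 * pi / alpha * (x[hi] - 1 + alpha / 2)))
  w
}

# Quadrant masks on an (n_x, n_t) DFT grid. For a wave cos(k x - w t)
# travelling toward +x, spectral energy sits where the signs of the
# spatial and temporal frequency differ; zero-frequency and Nyquist lines
# are shared half/half so that leftward + rightward = identity.
directional_masks <- function(nx, nt) {
  fx <- ifelse(seq_len(nx) - 1 < nx / 2, seq_len(nx) - 1, seq_len(nx) - 1 - nx)
  ft <- ifelse(seq_len(nt) - 1 < nt / 2, seq_len(nt) - 1, seq_len(nt) - 1 - nt)
  sx <- sign(fx)
  st <- sign(ft)
  if (nx %% 2 == 0) sx[nx / 2 + 1] <- 0 # Nyquist treated as shared
  if (nt %% 2 == 0) st[nt / 2 + 1] <- 0
  prod_sign <- outer(sx, st)
  right <- matrix(0.5, nx, nt)
  right[prod_sign < 0] <- 1
  right[prod_sign > 0] <- 0
  list(rightward = right, leftward = 1 - right)
}

#' Separate leftward- and rightward-travelling shear waves
#'
#' Per depth row, the (lateral, slow-time) plane is zero-padded along
#' both axes (suppressing circular wrap-around of the discrete
#' transform), 2D Fourier transformed, split into the quadrant pairs
#' corresponding to each propagation direction (the f = 0, k = 0 and
#' Nyquist lines are shared half/half), inverse-transformed and cropped
#' back. Because the two quadrant masks sum to one everywhere, the two
#' outputs reconstruct the input exactly, and by Parseval's identity
#' their energies never sum to more than the input energy.
#'
#' @param field A [particle_velocity_field()] with >= 8 lateral positions
#'   and >= 8 frames.
#' @param pad_factor Integer >= 1 zero-padding factor for both axes.
#' @return A list with elements `leftward` and `rightward`, both
#'   [particle_velocity_field()]s.
#' @export
directional_filter <- function(field, pad_factor = 2L) {
  stopifnot(inherits(field, "particle_velocity_field"), pad_factor >= 1)
  d <- dim(field$values)
  if (d[2] < 8 || d[3] < 8) {
    stop("need >= 8 lateral positions and >= 8 frames", call. = FALSE)
  }
  nx <- d[2] * pad_factor
  nt <- d[3] * pad_factor
  masks <- directional_masks(nx, nt)
  left <- right <- array(0, dim = d)
  padded <- matrix(0, nx, nt)
  for (z in seq_len(d[1])) {
    padded[] <- 0
    padded[seq_len(d[2]), seq_len(d[3])] <- field$values[z, , ]
    Fz <- stats::fft(padded)
    r <- Re(stats::fft(Fz * masks$rightward, inverse = TRUE)) / (nx * nt)
    l <- Re(stats::fft(Fz * masks$leftward, inverse = TRUE)) / (nx * nt)
    right[z, , ] <- r[seq_len(d[2]), seq_len(d[3])]
    left[z, , ] <- l[seq_len(d[2]), seq_len(d[3])]
  }
  list(
    leftward = particle_velocity_field(left, field$grid, field$times),
    rightward = particle_velocity_field(right, field$grid, field$times)
  )
}

#' Depth-average a masked particle-velocity movie
#'
#' For each lateral column containing at least one TRUE mask pixel, the
#' map value at each instant is the unweighted mean over the masked depth
#' pixels of that column. Columns with no masked pixel are dropped and the
#' lateral axis records only the included columns.
#'
#' @param field A [particle_velocity_field()].
#' @param roi An [roi_mask()] on the same grid.
#' @param direction Direction label to carry on the output map.
#' @return A [space_time_map()].
#' @export
depth_average <- function(field, roi,
                          direction = c("both", "leftward", "rightward")) {
  direction <- match.arg(direction)
  stopifnot(
    inherits(field, "particle_velocity_field"), inherits(roi, "roi_mask")
  )
  d <- dim(field$values)
  if (nrow(roi$mask) != d[1] || ncol(roi$mask) != d[2]) {
    stop("ROI mask does not match the field grid", call. = FALSE)
  }
  cols <- roi$lateral_cols
  vals <- matrix(0, length(cols), d[3])
  for (i in seq_along(cols)) {
    rows <- which(roi$mask[, cols[i]])
    m <- field$values[rows, cols[i], , drop = FALSE]
    dim(m) <- c(length(rows), d[3])
    vals[i, ] <- colMeans(m)
  }
  xs <- lateral_positions(field$grid)[cols]
  space_time_map(vals, xs, field$times, direction)
}
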