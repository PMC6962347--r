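#' Crop window on a space-time map
#'
#' Restricts the time-to-peak search to a lateral/time rectangle, the
#' reproducible replacement for manual cropping of an axial
#' particle-velocity map around the main wave.
#'
#' @param lateral_range,time_range Length-2 numeric `(min, max)`, metres
#'   and seconds; `min < max` on both axes.
#' @return An object of class `crop_window`.
#' @export
crop_window <- function(lateral_range = c(-Inf, Inf),
                        time_range = c(-Inf, Inf)) {
  stopifnot(
    length(lateral_range) == 2, lateral_range[1] < lateral_range[2],
    length(time_range) == 2, time_range[1] < time_range[2]
  )
  structure(list(lateral_range = lateral_range, time_range = time_range),
    class = "crop_window"
  )
}

#' Time-to-peak arrival times of a space-time map
#'
#' For each lateral position inside the crop, the time at which the map
#' value is maximal along the (cropped) time axis; ties are broken by the
#' earliest time.
#'
#' @param map A [space_time_map()].
#' @param crop Optional [crop_window()].
#' @return A data.frame with columns `x` (m) and `t` (s), one row per
#'   included lateral position.
#' @export
time_to_peak <- function(map, crop = NULL) {
  stopifnot(inherits(map, "space_time_map"))
  xi <- seq_along(map$lateral_positions)
  ti <- seq_along(map$times)
  if (!is.null(crop)) {
    stopifnot(inherits(crop, "crop_window"))
    xi <- which(map$lateral_positions >= crop$lateral_range[1] &
      map$lateral_positions <= crop$lateral_range[2])
    ti <- which(map$times >= crop$time_range[1] &
      map$times <= crop$time_range[2])
  }
  if (length(xi) < 3) {
    stop("need >= 3 lateral positions inside the crop", call. = FALSE)
  }
  if (length(ti) < 1) stop("crop excludes all time samples", call. = FALSE)
  sub <- map$values[xi, ti, drop = FALSE]
  peak <- apply(sub, 1, which.max) # which.max: earliest index on ties
  data.frame(x = map$lateral_positions[xi], t = map$times[ti][peak])
}

#' Fit group velocity to time-to-peak points by RANSAC
#'
#' Robust line fit `t = b + x / v` by random sample consensus: repeated
#' two-point model draws, inlier counting at an absolute time-residual
#' threshold, consensus = maximal inlier count (ties broken by smaller
#' inlier residual RMS), followed by an ordinary least-squares refit on
#' the consensus inlier set. When the number of point pairs does not
#' exceed `n_iter` the search is exhaustive over all pairs, making the
#' consensus deterministic and optimal; otherwise `n_iter` seeded random
#' pairs are drawn. The quality-of-fit gate is the inlier ratio: the
#' estimate passes only if it exceeds 0.5.
#'
#' @param points data.frame with columns `x` (m) and `t` (s), as returned
#'   by [time_to_peak()].
#' @param n_iter Maximum number of random model draws.
#' @param residual_threshold Inlier gate on |time residual|, seconds.
#' @param min_samples Minimum points required (>= 2).
#' @param seed Integer seed for the random draws.
#' @param direction Direction label carried to the estimate.
#' @param lateral_extent Optional full ROI lateral extent (m); when given,
#'   an estimate whose inlier span covers less than half of it is flagged
#'   (`span_ok = FALSE`), the reproducible stand-in for a visual check
#'   that the fit pertains to the main wave.
#' @return An object of class `group_velocity_estimate`: list with
#'   `velocity` (m/s, positive speed), `slope` (signed s/m), `intercept`
#'   (s), `inlier_ratio`, `n_points`, `passed_quality`, `span_ok`,
#'   `direction`.
#' @export
fit_group_velocity <- function(points, n_iter = 200L,
                               residual_threshold = 5e-4,
                               min_samples = 2L, seed = 1L,
                               direction = "both",
                               lateral_extent = NULL) {
  stopifnot(is.data.frame(points), all(c("x", "t") %in% names(points)))
  n <- nrow(points)
  if (n < min_samples) stop("fewer points than min_samples", call. = FALSE)
  x <- points$x
  t <- points$t

  pairs <- utils::combn(n, 2)
  if (ncol(pairs) > n_iter) {
    idx <- with_seed(seed, sample.int(ncol(pairs), n_iter))
    pairs <- pairs[, idx, drop = FALSE]
  }
  best <- list(count = -1L, rms = Inf, inliers = NULL)
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    dx <- x[i2] - x[i1]
    if (dx == 0) next
    slope <- (t[i2] - t[i1]) / dx
    if (!is.finite(slope)) next
    res <- abs(t - (t[i1] + slope * (x - x[i1])))
    inl <- res <= residual_threshold
    cnt <- sum(inl)
    rms <- sqrt(mean(res[inl]^2))
    if (cnt > best$count || (cnt == best$count && rms < best$rms)) {
      best <- list(count = cnt, rms = rms, inliers = inl)
    }
  }
  fail <- structure(
    list(
      velocity = NA_real_, slope = NA_real_, intercept = NA_real_,
      inlier_ratio = 0, n_points = n, passed_quality = FALSE,
      span_ok = FALSE, direction = direction
    ),
    class = "group_velocity_estimate"
  )
  if (best$count < 2) return(fail)
  inl <- best$inliers
  fit <- stats::lm.fit(cbind(1, x[inl]), t[inl])
  slope <- unname(fit$coefficients[2])
  if (!is.finite(slope) || slope == 0) return(fail)
  ratio <- best$count / n
  span_ok <- TRUE
  if (!is.null(lateral_extent) && lateral_extent > 0) {
    span_ok <- diff(range(x[inl])) >= 0.5 * lateral_extent
  }
  structure(
    list(
      velocity = 1 / abs(slope), slope = unname(slope),
      intercept = unname(fit$coefficients[1]),
      inlier_ratio = ratio, n_points = n,
      passed_quality = ratio > 0.5, span_ok = span_ok,
      direction = direction
    ),
    class = "group_velocity_estimate"
  )
}

#' Estimate group velocity from a space-time map
#'
#' Composition of [time_to_peak()] and [fit_group_velocity()]: arrival
#' times per lateral position, robust linear fit, inlier-ratio quality
#' gate.
#'
#' @param map A [space_time_map()].
#' @param crop Optional [crop_window()].
#' @param n_iter,residual_threshold,min_samples,seed RANSAC parameters,
#'   see [fit_group_velocity()].
#' @return A `group_velocity_estimate`.
#' @export
estimate_group_velocity <- function(map, crop = NULL, n_iter = 200L,
                                    residual_threshold = 5e-4,
                                    min_samples = 2L, seed = 1L) {
  pts <- time_to_peak(map, crop)
  est <- fit_group_velocity(pts,
    n_iter = n_iter, residual_threshold = residual_threshold,
    min_samples = min_samples, seed = seed, direction = map$direction,
    lateral_extent = diff(range(map$lateral_positions))
  )
  est$crop_used <- crop
  est
}

#' Combine leftward and rightward group-velocity estimates
#'
#' Per acquisition the two directional estimates that pass the quality
#' gate are averaged into a single reported value; if only one passes it
#' is used alone; if neither passes the acquisition is excluded
#' (`passed_quality = FALSE`, velocity `NA`).
#'
#' @param leftward,rightward `group_velocity_estimate` objects.
#' @return A `group_velocity_estimate` with `direction = "combined"`.
#' @export
combine_direction_estimates <- function(leftward, rightward) {
  ests <- list(leftward, rightward)
  ok <- vapply(ests, function(e) isTRUE(e$passed_quality), logical(1))
  vel <- if (any(ok)) {
    mean(vapply(ests[ok], `[[`, numeric(1), "velocity"))
  } else {
    NA_real_
  }
  structure(
    list(
      velocity = vel, slope = NA_real_, intercept = NA_real_,
      inlier_ratio = mean(vapply(ests, `[[`, numeric(1), "inlier_ratio")),
      n_points = sum(vapply(ests, `[[`, numeric(1), "n_points")),
      passed_quality = any(ok),
      span_ok = all(vapply(ests[ok], function(e) isTRUE(e$span_ok),
        logical(1))),
      direction = "combined"
    ),
    class = "group_velocity_estimate"
  )
}

#' @export
print.group_velocity_estimate <- function(x, ...) {
  cat(sprintf(
    "<group_velocity_estimate> %s: %.3f m/s (inliers %.0f%% of %d, %s)\n",
    x$direction, x$velocity, 100 * x$inlier_ratio, x$n_points,
    if (isTRUE(x$passed_quality)) "passed" else "failed quality gate"
  ))
  invisible(x)
}
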