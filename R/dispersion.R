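#' Dispersion law: phase velocity as a function of frequency
#'
#' Ground-truth dispersion behaviour for the synthetic wave-field
#' generator. Three kinds are supported:
#' \describe{
#'   \item{`constant`}{`c(f) = c0`, a non-dispersive medium.}
#'   \item{`power_law`}{`c(f) = c_ref * (f / f_ref)^exponent`.}
#'   \item{`plate_A0`}{The low-frequency asymptote of the zero-order
#'     antisymmetric (flexural) plate mode,
#'     `c(f) = sqrt(2 * pi * f * h * c_T / sqrt(3))`, for a plate of
#'     thickness `h` and bulk shear speed `c_T`. Its sqrt(f) growth is a
#'     closed-form stand-in for the guided-wave dispersion seen in thin,
#'     confined tissue layers.}
#' }
#'
#' @param kind One of `"constant"`, `"power_law"`, `"plate_A0"`.
#' @param c0 Constant phase velocity (m/s), `constant` only.
#' @param c_ref,f_ref,exponent Power-law reference speed (m/s) at
#'   reference frequency (Hz) and exponent.
#' @param h Plate thickness in metres, `plate_A0` only.
#' @param c_T Bulk shear speed in m/s, `plate_A0` only.
#' @return An object of class `dispersion_law`.
#' @examples
#' evaluate_dispersion(dispersion_law("constant", c0 = 4), 250)
#' evaluate_dispersion(dispersion_law("plate_A0", h = 3e-3, c_T = 4), c(100, 400))
#' @export
dispersion_law <- function(kind = c("constant", "power_law", "plate_A0"),
                           c0 = NULL, c_ref = NULL, f_ref = NULL,
                           exponent = NULL, h = NULL, c_T = NULL) {
  kind <- match.arg(kind)
  params <- switch(kind,
    constant = {
      stopifnot(is.numeric(c0), c0 > 0)
      list(c0 = c0)
    },
    power_law = {
      stopifnot(
        is.numeric(c_ref), c_ref > 0,
        is.numeric(f_ref), f_ref > 0, is.numeric(exponent)
      )
      list(c_ref = c_ref, f_ref = f_ref, exponent = exponent)
    },
    plate_A0 = {
      stopifnot(is.numeric(h), h > 0, is.numeric(c_T), c_T > 0)
      list(h = h, c_T = c_T)
    }
  )
  structure(list(kind = kind, parameters = params), class = "dispersion_law")
}

#' Evaluate a dispersion law
#'
#' @param law A [dispersion_law()].
#' @param f Frequency or vector of frequencies in Hz; all must be > 0.
#' @return Phase velocity in m/s, same length as `f`.
#' @export
evaluate_dispersion <- function(law, f) {
  stopifnot(inherits(law, "dispersion_law"))
  if (!is.numeric(f) || any(!is.finite(f)) || any(f <= 0)) {
    stop("frequency must be finite and strictly positive", call. = FALSE)
  }
  p <- law$parameters
  v <- switch(law$kind,
    constant = rep(p$c0, length(f)),
    power_law = p$c_ref * (f / p$f_ref)^p$exponent,
    plate_A0 = sqrt(2 * pi * f * p$h * p$c_T / sqrt(3)),
    stop("unknown dispersion law kind: ", law$kind, call. = FALSE)
  )
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("dispersion law evaluated to a non-positive or non-finite speed",
      call. = FALSE
    )
  }
  v
}

#' @export
print.dispersion_law <- function(x, ...) {
  cat(sprintf(
    "<dispersion_law> %s (%s)\n", x$kind,
    paste(names(x$parameters), unlist(x$parameters), sep = " = ", collapse = ", ")
  ))
  invisible(x)
}
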