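#' Specify an elution peak
#'
#' Parameters of one analyte's elution profile: a Gaussian of standard
#' deviation `width` (min) centred at `center` (min), optionally convolved
#' with an exponential tail of time constant `tail` (min) to model column
#' tailing (an exponentially modified Gaussian, EMG).  `amplitude` is the
#' concentration-proportional scale: it equals the peak height of the
#' untailed Gaussian, and the profile area is `amplitude * width * sqrt(2*pi)`
#' regardless of `tail` (tailing redistributes intensity in time but
#' conserves the eluted amount).
#'
#' @param center peak centre of the underlying Gaussian, min.
#' @param width Gaussian sigma, min; must be positive.
#' @param tail exponential time constant, min; 0 gives a symmetric Gaussian.
#' @param amplitude non-negative concentration-proportional scale.
#' @return an object of class `elution_profile_spec`.
#' @export
elution_profile_spec <- function(center, width, tail = 0, amplitude = 1) {
  if (width <= 0) stop("width must be positive", call. = FALSE)
  if (tail < 0) stop("tail must be >= 0", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  structure(list(center = center, width = width, tail = tail,
                 amplitude = amplitude),
            class = "elution_profile_spec")
}

# unit-area EMG density; stable log-scale evaluation
emg_density <- function(t, center, sigma, tau) {
  z <- (t - center) / sigma - sigma / tau
  lg <- -log(tau) + sigma^2 / (2 * tau^2) - (t - center) / tau +
    stats::pnorm(z, log.p = TRUE)
  exp(lg)
}

#' Evaluate an elution profile on a time axis
#'
#' For `tail = 0` the profile is `amplitude * exp(-(t-center)^2/(2 width^2))`
#' with its maximum exactly at `center`.  For `tail > 0` it is an
#' exponentially modified Gaussian with the same area as the untailed peak,
#' whose mode lies later than `center`.
#'
#' A centre outside the axis range is allowed (the peak may simply be
#' clipped) and only raises a warning.
#'
#' @param spec an [elution_profile_spec()].
#' @param taxis elution-time axis, min.
#' @return numeric intensity series along `taxis`.
#' @export
make_elution_profile <- function(spec, taxis) {
  stopifnot(inherits(spec, "elution_profile_spec"))
  taxis <- time_axis(taxis)
  if (spec$center < min(taxis) || spec$center > max(taxis))
    warning("elution centre outside the time axis; peak may be clipped",
            call. = FALSE)
  if (spec$amplitude == 0) return(numeric(length(taxis)))
  if (spec$tail == 0) {
    spec$amplitude * exp(-(taxis - spec$center)^2 / (2 * spec$width^2))
  } else {
    area <- spec$amplitude * spec$width * sqrt(2 * pi)
    area * emg_density(taxis, spec$center, spec$width, spec$tail)
  }
}
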