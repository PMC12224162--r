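#' Validate a wavenumber axis
#'
#' A wavenumber axis is the spectral grid (Raman shift, cm^-1) on which all
#' component spectra and data matrices are defined.  The grid must be
#' strictly increasing and uniformly spaced (relative tolerance 1e-9), with
#' at least two channels.
#'
#' @param values numeric vector of Raman shifts in cm^-1.
#' @return the validated numeric vector.
#' @examples
#' w <- wavenumber_axis(seq(200, 1800, length.out = 1024))
#' @export
wavenumber_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("wavenumber axis needs at least 2 channels", call. = FALSE)
  d <- diff(values)
  if (any(d <= 0))
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  if (diff(range(d)) > 1e-9 * mean(d))
    stop("wavenumber axis must be uniformly spaced", call. = FALSE)
  values
}

#' Validate an elution-time axis
#'
#' Elution times in minutes, strictly increasing, at least two points.
#'
#' @param values numeric vector of elution times in minutes.
#' @return the validated numeric vector.
#' @export
time_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("time axis needs at least 2 points", call. = FALSE)
  if (any(diff(values) <= 0))
    stop("time axis must be strictly increasing", call. = FALSE)
  values
}

#' Default spectral axis: 200-1800 cm^-1 over 1024 channels
#' @return numeric vector of length 1024.
#' @export
default_wavenumber_axis <- function() {
  wavenumber_axis(seq(200, 1800, length.out = 1024L))
}

#' Default elution-time axis: 30-55 min, one averaged spectrum per 4 s
#'
#' Spectra acquired every 0.4 s and block-averaged ten at a time give one
#' column per 4 s; the 30-55 min analysis window then holds 375 columns,
#' stamped at the centre of each averaging block.
#'
#' @return numeric vector of length 375.
#' @export
default_time_axis <- function() {
  step <- 4 / 60 # min
  time_axis(30 + (seq_len(375L) - 0.5) * step)
}
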