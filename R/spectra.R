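#' Construct a component spectrum
#'
#' A named model spectrum on a wavenumber axis.  `kind` records its role in
#' the mixture model: `"analyte"` (a sugar), `"solvent"` (acetonitrile or
#' water), `"derivative-artifact"` (the first-derivative line shape produced
#' by a small shift of a solvent band), `"constant"` (flat offset) or
#' `"baseline"` (any other slowly varying background).
#'
#' Analyte and solvent profiles must be non-negative; a derivative artifact
#' must integrate to ~0 over the full axis (it is an odd-symmetric
#' perturbation, not net intensity).
#'
#' @param name identifier, e.g. `"Fru"` or `"ACN"`.
#' @param profile numeric intensity per wavenumber channel (arbitrary counts).
#' @param wavenumber the spectral axis the profile is evaluated on.
#' @param kind one of `"analyte"`, `"solvent"`, `"derivative-artifact"`,
#'   `"constant"`, `"baseline"`.
#' @return an object of class `component_spectrum`.
#' @export
component_spectrum <- function(name, profile, wavenumber,
                               kind = c("analyte", "solvent",
                                        "derivative-artifact",
                                        "constant", "baseline")) {
  kind <- match.arg(kind)
  wavenumber <- wavenumber_axis(wavenumber)
  profile <- as.numeric(profile)
  if (length(profile) != length(wavenumber))
    stop("profile and wavenumber axis lengths differ", call. = FALSE)
  if (!all(is.finite(profile)))
    stop("profile must be finite everywhere", call. = FALSE)
  if (kind %in% c("analyte", "solvent") && any(profile < 0))
    stop(sprintf("%s profile of kind '%s' must be non-negative", name, kind),
         call. = FALSE)
  if (kind == "derivative-artifact") {
    l1 <- pracma::trapz(wavenumber, abs(profile))
    if (l1 > 0 && abs(pracma::trapz(wavenumber, profile)) > 1e-6 * l1)
      stop("derivative-artifact profile must integrate to ~0", call. = FALSE)
  }
  structure(list(name = name, profile = profile, wavenumber = wavenumber,
                 kind = kind),
            class = "component_spectrum")
}

#' @export
print.component_spectrum <- function(x, ...) {
  cat(sprintf("component_spectrum '%s' (%s), %d channels, peak %.4g\n",
              x$name, x$kind, length(x$profile), max(abs(x$profile))))
  invisible(x)
}

band_profile <- function(x, center, width, height, shape) {
  if (shape == "gaussian") {
    height * exp(-(x - center)^2 / (2 * width^2))
  } else {
    height * width^2 / ((x - center)^2 + width^2)
  }
}

band_profile_deriv <- function(x, center, width, height, shape) {
  if (shape == "gaussian") {
    -height * (x - center) / width^2 * exp(-(x - center)^2 / (2 * width^2))
  } else {
    -2 * height * width^2 * (x - center) / ((x - center)^2 + width^2)^2
  }
}

#' Build a component spectrum from a band table
#'
#' Evaluates a sum of Gaussian (default) or Lorentzian bands on a
#' wavenumber axis.  For `kind = "derivative-artifact"` the analytic first
#' derivative of the band sum is returned: this is the line shape generated
#' to first order by a small rigid shift of those bands, as happens when a
#' solvent band wanders in wavenumber.
#'
#' @param band_table a data.frame (or matrix) with columns `center` (cm^-1),
#'   `width` (cm^-1; Gaussian sigma or Lorentzian half-width) and `height`.
#' @param axis wavenumber axis.
#' @param kind passed to [component_spectrum()].
#' @param name identifier for the resulting spectrum.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return a `component_spectrum`.
#' @examples
#' ax <- default_wavenumber_axis()
#' glu_like <- make_component_spectra(
#'   data.frame(center = 1130, width = 12, height = 1), ax, name = "Glu")
#' @export
make_component_spectra <- function(band_table, axis,
                                   kind = "analyte", name = "component",
                                   shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  axis <- wavenumber_axis(axis)
  band_table <- as.data.frame(band_table)
  if (nrow(band_table) == 0L)
    stop("band table is empty", call. = FALSE)
  if (!all(c("center", "width", "height") %in% names(band_table)))
    stop("band table needs columns center, width, height", call. = FALSE)
  if (any(band_table$width <= 0))
    stop("band widths must be positive", call. = FALSE)
  rng <- range(axis)
  if (any(band_table$center < rng[1] | band_table$center > rng[2]))
    stop("band centers must lie within the wavenumber axis range",
         call. = FALSE)
  f <- if (kind == "derivative-artifact") band_profile_deriv else band_profile
  profile <- rowSums(mapply(function(c0, w, h) f(axis, c0, w, h, shape),
                            band_table$center, band_table$width,
                            band_table$height))
  component_spectrum(name, profile, axis, kind = kind)
}

#' Reference band tables for the five sugars and the running solvent
#'
#' Plausible band positions and relative heights for fructose, glucose,
#' sucrose, maltose and trehalose in the fingerprint region (each sugar
#' anchored by characteristic C-O/C-C stretch and ring modes, e.g. the
#' glucose band near 1130 cm^-1), for acetonitrile (sharp bands at 380,
#' 918 and 1375 cm^-1 inside the 200-1800 cm^-1 window) and for water
#' (broad bending band near 1640 cm^-1 over a very broad background).
#' These are synthetic stand-ins with the right qualitative structure,
#' not measured spectra.
#'
#' @param name one of `"Fru"`, `"Glu"`, `"Suc"`, `"Mal"`, `"Tre"`,
#'   `"ACN"`, `"H2O"`.
#' @return a data.frame with columns `center`, `width`, `height`.
#' @export
reference_bands <- function(name) {
  tabs <- list(
    Fru = data.frame(
      center = c(630, 825, 872, 1065, 1265, 1455),
      width  = c(14, 10, 11, 16, 15, 14),
      height = c(0.55, 1.00, 0.70, 0.65, 0.40, 0.30)),
    Glu = data.frame(
      center = c(520, 915, 1060, 1130, 1365),
      width  = c(13, 11, 14, 12, 14),
      height = c(0.50, 0.60, 0.70, 1.00, 0.35)),
    Suc = data.frame(
      center = c(545, 835, 1045, 1120, 1340, 1460),
      width  = c(13, 9, 14, 13, 14, 15),
      height = c(0.45, 1.00, 0.55, 0.60, 0.35, 0.30)),
    Mal = data.frame(
      center = c(580, 850, 1080, 1110, 1360),
      width  = c(13, 10, 13, 12, 15),
      height = c(0.40, 1.00, 0.55, 0.65, 0.35)),
    Tre = data.frame(
      center = c(540, 845, 920, 1150, 1380),
      width  = c(12, 10, 11, 13, 15),
      height = c(0.45, 1.00, 0.50, 0.70, 0.30)),
    ACN = data.frame(
      center = c(380, 918, 1375),
      width  = c(6, 5, 6),
      height = c(0.45, 1.00, 0.55)),
    H2O = data.frame(
      center = c(800, 1640),
      width  = c(300, 60),
      height = c(0.25, 1.00))
  )
  if (!name %in% names(tabs))
    stop("no reference band table for '", name, "'", call. = FALSE)
  tabs[[name]]
}

#' Library of model component spectra on an axis
#'
#' Convenience builder for the spectra used both by the synthetic generator
#' and as rotation targets: the requested sugars, the two solvents, a flat
#' constant background, and the derivative-shaped artifact of the
#' acetonitrile bands.  All profiles are peak-normalized to 1 (the
#' derivative artifact to max |value| = 1).
#'
#' @param axis wavenumber axis.
#' @param analytes character vector of sugar names.
#' @return named list of `component_spectrum` objects: the analytes plus
#'   `ACN`, `H2O`, `baseline`, `ACN-shift`.
#' @export
model_spectra <- function(axis, analytes = c("Fru", "Glu", "Suc", "Mal",
                                             "Tre")) {
  axis <- wavenumber_axis(axis)
  peak_norm <- function(cs) {
    m <- max(abs(cs$profile))
    if (m > 0) cs$profile <- cs$profile / m
    cs
  }
  out <- lapply(analytes, function(a)
    peak_norm(make_component_spectra(reference_bands(a), axis,
                                     kind = "analyte", name = a)))
  names(out) <- analytes
  out$ACN <- peak_norm(make_component_spectra(reference_bands("ACN"), axis,
                                              kind = "solvent", name = "ACN"))
  out$H2O <- peak_norm(make_component_spectra(reference_bands("H2O"), axis,
                                              kind = "solvent", name = "H2O"))
  out$baseline <- component_spectrum("baseline", rep(1, length(axis)), axis,
                                     kind = "constant")
  out[["ACN-shift"]] <- peak_norm(
    make_component_spectra(reference_bands("ACN"), axis,
                           kind = "derivative-artifact", name = "ACN-shift"))
  out
}
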