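#' Molecular weights of the five sugars
#'
#' Monosaccharides (fructose, glucose) 180.16 g/mol; disaccharides
#' (sucrose, maltose, trehalose) 342.3 g/mol.  Anhydrous forms; no hydrate
#' corrections.
#'
#' @return named numeric vector, g/mol.
#' @export
sugar_mw <- function() {
  c(Fru = 180.16, Glu = 180.16, Suc = 342.3, Mal = 342.3, Tre = 342.3)
}

#' Default integration windows for the five sugars
#'
#' Closed elution-time windows (min) bracketing each sugar's peak.  The
#' maltose and trehalose windows overlap, as their peaks do; the overlap
#' is reported with a message.
#'
#' @param quiet suppress the overlap message.
#' @return named list of `c(t_start, t_end)` windows.
#' @export
default_windows <- function(quiet = FALSE) {
  w <- list(Fru = c(35.3, 38.0), Glu = c(38.0, 40.7), Suc = c(40.7, 43.3),
            Mal = c(44.7, 47.3), Tre = c(46.0, 49.0))
  if (!quiet) {
    nm <- names(w)
    for (i in seq_along(w)[-1]) {
      for (j in seq_len(i - 1)) {
        if (w[[i]][1] < w[[j]][2] && w[[j]][1] < w[[i]][2])
          message("integration windows overlap: ", nm[j], " and ", nm[i])
      }
    }
  }
  w
}

new_elution_peak <- function(analyte, center, sigma, height, area, window,
                             converged = TRUE, detected = TRUE) {
  structure(list(analyte = analyte, center = center, sigma = sigma,
                 height = height, area = area, window = window,
                 converged = converged, detected = detected),
            class = "elution_peak")
}

#' @export
print.elution_peak <- function(x, ...) {
  if (!x$detected) {
    cat(sprintf("elution_peak '%s': not detected\n", x$analyte))
  } else {
    cat(sprintf(
      "elution_peak '%s': center %.2f min, sigma %.3f min, area %.4g%s\n",
      x$analyte, x$center, x$sigma, x$area,
      if (!x$converged) " (fit did not converge; window-sum area)" else ""))
  }
  invisible(x)
}

#' Fit a Gaussian to an elution peak
#'
#' Nonlinear least squares of `height * exp(-(t - center)^2 / (2 sigma^2))
#' + offset` to the curve inside the window (Levenberg-Marquardt).  The
#' constant offset absorbs residual baseline.  The peak area is the
#' closed-form `height * sigma * sqrt(2 pi)`.  If the fit does not
#' converge, the result is flagged and the trapezoidal window integral is
#' used as a fallback area.  An (essentially) all-zero curve returns a
#' not-detected peak.
#'
#' @param time,intensity the elution curve.
#' @param window `c(t_start, t_end)` in min; must contain >= 5 points.
#' @param analyte name carried into the result.
#' @return an `elution_peak`.
#' @export
fit_gaussian_peak <- function(time, intensity, window, analyte = "") {
  stopifnot(length(time) == length(intensity))
  idx <- which(time >= window[1] & time <= window[2])
  if (length(idx) < 5L)
    stop("window must contain at least 5 points", call. = FALSE)
  t <- time[idx]; y <- intensity[idx]
  if (max(abs(y)) == 0 ||
      (max(y) - min(y)) < 1e-12 * max(1e-300, max(abs(y))))
    return(new_elution_peak(analyte, NA_real_, NA_real_, 0, 0, window,
                            converged = FALSE, detected = FALSE))
  start <- list(center = t[which.max(y)],
                sigma = diff(range(t)) / 6,
                height = max(y) - min(y),
                offset = min(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ height * exp(-(t - center)^2 / (2 * sigma^2)) + offset,
      start = start,
      lower = c(center = window[1], sigma = 1e-6, height = 0,
                offset = -Inf),
      upper = c(center = window[2], sigma = Inf, height = Inf,
                offset = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    area <- pracma::trapz(t, y)
    return(new_elution_peak(analyte, t[which.max(y)], NA_real_, max(y),
                            area, window, converged = FALSE))
  }
  cf <- stats::coef(fit)
  sigma <- abs(cf[["sigma"]])
  new_elution_peak(analyte, cf[["center"]], sigma, cf[["height"]],
                   cf[["height"]] * sigma * sqrt(2 * pi), window)
}

#' Trapezoidal integral of an elution curve over a window
#'
#' Integrates the curve over the points falling inside the closed window.
#' With `baseline = "linear"` a straight baseline drawn between the window
#' edges (each estimated as the mean of the three outermost in-window
#' points) is subtracted first; this is the usual chromatographic practice
#' and removes constant or slowly drifting offsets that are not part of
#' the peak.
#'
#' @param time,intensity the elution curve.
#' @param window `c(t_start, t_end)` in min.
#' @param baseline `"none"` (plain trapezoid) or `"linear"`.
#' @return the area in intensity * min.
#' @export
integrate_window <- function(time, intensity, window,
                             baseline = c("none", "linear")) {
  baseline <- match.arg(baseline)
  stopifnot(length(time) == length(intensity))
  if (window[2] < window[1]) window <- rev(window)
  idx <- which(time >= window[1] & time <= window[2])
  if (length(idx) < 2L)
    stop("integration window contains fewer than 2 points", call. = FALSE)
  t <- time[idx]; y <- intensity[idx]
  if (baseline == "linear") {
    ne <- min(3L, length(idx) %/% 2L)
    lo <- utils::head(seq_along(idx), ne)
    hi <- utils::tail(seq_along(idx), ne)
    t0 <- mean(t[lo]); y0 <- mean(y[lo])
    t1 <- mean(t[hi]); y1 <- mean(y[hi])
    y <- y - (y0 + (y1 - y0) * (t - t0) / max(t1 - t0, 1e-12))
  }
  pracma::trapz(t, y)
}

#' Measure a peak by window integration
#'
#' Convenience wrapper producing an `elution_peak` whose area is the
#' trapezoidal window integral (the same convention is applied to samples
#' and standards, so quantification uses area ratios of identically
#' truncated peaks).  The centre is the time of the curve maximum inside
#' the window.
#'
#' By default (`baseline = "median"`) the median intensity of the whole
#' curve is subtracted before integrating.  A resolved elution peak
#' occupies a small fraction of the chromatogram, so the median estimates
#' the flat offset that imperfect unmixing leaks into an elution curve —
#' essential for analytes near or below the detection limit, whose
#' windowed offset would otherwise masquerade as eluted amount.  The
#' median is preferred over a baseline drawn across the window edges
#' because the shipped windows may clip a peak before it returns to
#' baseline.
#'
#' The peak is flagged `detected` only when its area exceeds three times
#' the area uncertainty implied by the curve's own out-of-window noise
#' (robust MAD estimate): an elution curve resolved for an analyte that is
#' absent from the mixture is fitted noise, and its windowed wiggle must
#' not be mistaken for a peak.
#'
#' @inheritParams fit_gaussian_peak
#' @param baseline `"median"` (default), `"none"`, or `"linear"` (passed
#'   to [integrate_window()]).
#' @return an `elution_peak` (sigma NA; `converged` TRUE) with an attribute
#'   `"area_sd"` carrying the noise-based area uncertainty.
#' @export
window_peak <- function(time, intensity, window, analyte = "",
                        baseline = c("median", "none", "linear")) {
  baseline <- match.arg(baseline)
  if (baseline == "median") {
    intensity <- intensity - stats::median(intensity)
    baseline <- "none"
  }
  area <- integrate_window(time, intensity, window, baseline = baseline)
  idx <- which(time >= window[1] & time <= window[2])
  i0 <- idx[which.max(intensity[idx])]
  out_noise <- stats::mad(intensity[-idx])
  dt <- stats::median(diff(time))
  area_sd <- out_noise * dt * sqrt(length(idx))
  pk <- new_elution_peak(analyte, time[i0], NA_real_, intensity[i0], area,
                         window, detected = area > 3 * area_sd)
  attr(pk, "area_sd") <- area_sd
  pk
}

#' Linear calibration with LOD and LOQ
#'
#' Ordinary least squares of response on concentration.  The limits of
#' detection and quantification follow the residual-standard-error
#' convention LOD = 3 * se_resid / slope and LOQ = 10 * se_resid / slope,
#' so LOQ/LOD = 10/3 by construction.  Both mass (ug/mL) and molar (mM)
#' limits are reported when a molecular weight is given; molar = mass / MW.
#'
#' @param concentration,response calibration points (>= 3 points, >= 2
#'   distinct concentrations).
#' @param origin_forced force the regression through the origin.
#' @param mw molecular weight, g/mol (NA to skip unit conversion).
#' @param conc_unit unit of `concentration`: `"mM"` or `"ug_mL"`.
#' @return an object of class `calibration_result`: slope, intercept,
#'   se_resid, r2, lod_mass, loq_mass (ug/mL), lod_molar, loq_molar (mM),
#'   mw.
#' @export
linear_calibration <- function(concentration, response,
                               origin_forced = FALSE, mw = NA,
                               conc_unit = c("mM", "ug_mL")) {
  conc_unit <- match.arg(conc_unit)
  stopifnot(length(concentration) == length(response))
  if (length(concentration) < 3L)
    stop("calibration needs at least 3 points", call. = FALSE)
  if (length(unique(concentration)) < 2L ||
      stats::var(concentration) == 0)
    stop("calibration concentrations have zero variance", call. = FALSE)
  d <- data.frame(conc = concentration, resp = response)
  fm <- if (origin_forced) resp ~ conc + 0 else resp ~ conc
  fit <- stats::lm(fm, data = d)
  sm <- suppressWarnings(summary(fit)) # exact fits warn harmlessly
  slope <- stats::coef(fit)[["conc"]]
  intercept <- if (origin_forced) 0 else stats::coef(fit)[["(Intercept)"]]
  se_resid <- sm$sigma
  if (slope == 0) stop("calibration slope is zero", call. = FALSE)
  lod <- 3 * se_resid / abs(slope)
  loq <- 10 * se_resid / abs(slope)
  if (conc_unit == "mM") {
    lod_molar <- lod; loq_molar <- loq
    lod_mass <- if (is.na(mw)) NA_real_ else lod * mw
    loq_mass <- if (is.na(mw)) NA_real_ else loq * mw
  } else {
    lod_mass <- lod; loq_mass <- loq
    lod_molar <- if (is.na(mw)) NA_real_ else lod / mw
    loq_molar <- if (is.na(mw)) NA_real_ else loq / mw
  }
  structure(list(slope = slope, intercept = intercept,
                 se_resid = se_resid, r2 = sm$r.squared,
                 lod_mass = lod_mass, loq_mass = loq_mass,
                 lod_molar = lod_molar, loq_molar = loq_molar, mw = mw),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration: slope %.4g, intercept %.4g, R2 %.4f\n",
              x$slope, x$intercept, x$r2))
  cat(sprintf("  LOD %.4g ug/mL (%.4g mM), LOQ %.4g ug/mL (%.4g mM)\n",
              x$lod_mass, x$lod_molar, x$loq_mass, x$loq_molar))
  invisible(x)
}

#' Convert a mass concentration to molar
#'
#' @param value concentration in ug/mL.
#' @param mw molecular weight, g/mol; must be positive.
#' @return concentration in mM (`value / mw`).
#' @examples
#' convert_concentration(74, 342.3) # ~0.216 mM
#' @export
convert_concentration <- function(value, mw) {
  if (any(mw <= 0)) stop("molecular weight must be positive", call. = FALSE)
  value / mw
}

#' Quantify an analyte in a diluted sample against a single standard
#'
#' The injected amount of the analyte in the sample run is obtained from
#' the area ratio to a standard of known injected amount:
#' `mmol_sample = mmol_standard * area_sample / area_standard`, with
#' `mmol_standard = conc_mM * injected_mL / 1000`.  The analyte mass
#' (mg) is `mmol * MW`, and the weight-percent refers it to the mass of
#' original sample actually injected:
#' `mg_sample_injected = mass_g * 1000 * injected_mL / volume_mL`.
#'
#' When a detection limit is supplied, sample areas at or below the
#' LOD-equivalent area (`area_standard * lod_mmol / mmol_standard`) are
#' flagged not-detected rather than reported as a concentration.
#'
#' @param sample_peak,standard_peak `elution_peak`s of the same analyte;
#'   the standard's area must be positive.
#' @param standard list with `conc_mM` and `injected_mL` of the standard
#'   run.
#' @param dilution list with `mass_g` (sample dissolved), `volume_mL`
#'   (dissolution volume) and `injected_mL`.
#' @param mw molecular weight, g/mol.
#' @param lod_mM optional detection limit in the injected solution, mM.
#' @return an object of class `sample_quantification`: `analyte`,
#'   `injected_mmol`, `wt_percent`, `detected`, `dilution`.
#' @export
quantify_wt_percent <- function(sample_peak, standard_peak, standard,
                                dilution, mw, lod_mM = NULL) {
  stopifnot(inherits(sample_peak, "elution_peak"),
            inherits(standard_peak, "elution_peak"))
  if (!identical(sample_peak$analyte, standard_peak$analyte))
    stop("sample and standard peaks are for different analytes: ",
         sample_peak$analyte, " vs ", standard_peak$analyte, call. = FALSE)
  if (!is.finite(standard_peak$area) || standard_peak$area <= 0)
    stop("standard peak area must be positive", call. = FALSE)
  std_mmol <- standard$conc_mM * standard$injected_mL / 1000
  area <- if (isTRUE(sample_peak$detected)) sample_peak$area else 0
  detected <- area > 0
  if (!is.null(lod_mM)) {
    lod_mmol <- lod_mM * dilution$injected_mL / 1000
    area_thresh <- standard_peak$area * lod_mmol / std_mmol
    detected <- detected && area > area_thresh
  }
  inj_mmol <- std_mmol * area / standard_peak$area
  mg <- inj_mmol * mw
  sample_mg <- dilution$mass_g * 1000 * dilution$injected_mL /
    dilution$volume_mL
  wt <- 100 * mg / sample_mg
  if (!detected) {
    inj_mmol <- NA_real_
    wt <- NA_real_
  } else if (wt < 0 || wt > 100) {
    stop("weight-percent outside [0, 100]; inconsistent inputs",
         call. = FALSE)
  }
  structure(list(analyte = sample_peak$analyte,
                 injected_mmol = inj_mmol, wt_percent = wt,
                 detected = detected, dilution = dilution),
            class = "sample_quantification")
}

#' @export
print.sample_quantification <- function(x, ...) {
  if (!x$detected) {
    cat(sprintf("%s: not detected\n", x$analyte))
  } else {
    cat(sprintf("%s: %.4g mmol injected, %.3g wt%%\n",
                x$analyte, x$injected_mmol, x$wt_percent))
  }
  invisible(x)
}
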