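#' Specify a spectral channel mask
#'
#' The spatial line-rejection mask blocks narrow wavenumber intervals
#' (typically the sharp solvent bands) before detection; computationally
#' those channels are simply never observed.  Intervals are normalized:
#' sorted, and overlapping or touching intervals merged.
#'
#' @param intervals list of length-2 numeric vectors `c(lo, hi)` in cm^-1,
#'   or a 2-column matrix with one interval per row.  May be empty.
#' @return an object of class `mask_spec` (a list of normalized intervals).
#' @export
mask_spec <- function(intervals = list()) {
  if (is.matrix(intervals))
    intervals <- lapply(seq_len(nrow(intervals)), function(i) intervals[i, ])
  intervals <- lapply(intervals, function(iv) {
    iv <- as.numeric(iv)
    if (length(iv) != 2L || anyNA(iv))
      stop("each mask interval must be c(lo, hi)", call. = FALSE)
    sort(iv)
  })
  if (length(intervals) > 1L) {
    o <- order(vapply(intervals, `[`, numeric(1), 1L))
    intervals <- intervals[o]
    merged <- list(intervals[[1L]])
    for (iv in intervals[-1L]) {
      last <- merged[[length(merged)]]
      if (iv[1] <= last[2]) {
        merged[[length(merged)]] <- c(last[1], max(last[2], iv[2]))
      } else {
        merged <- c(merged, list(iv))
      }
    }
    intervals <- merged
  }
  structure(intervals, class = "mask_spec")
}

#' Default mask covering the sharp acetonitrile bands
#'
#' Blocks narrow windows around the three acetonitrile bands of
#' [reference_bands()] ("ACN": 380, 918, 1375 cm^-1), leaving the band
#' wings observable.
#'
#' @return a `mask_spec`.
#' @export
default_mask <- function() {
  mask_spec(list(c(374, 386), c(910, 926), c(1367, 1383)))
}

#' Flag masked wavenumber channels as unobserved
#'
#' Channels whose wavenumber falls inside a closed mask interval are set to
#' NA for all time points and flagged unobserved; observed values are
#' unchanged.  Intervals that do not overlap the axis have no effect.
#'
#' @param sc a [spectro_chromatogram()].
#' @param mask a [mask_spec()].
#' @return the masked `spectro_chromatogram`.
#' @export
apply_mask <- function(sc, mask) {
  stopifnot(inherits(sc, "spectro_chromatogram"))
  if (!inherits(mask, "mask_spec")) mask <- mask_spec(mask)
  obs <- sc$observed
  for (iv in mask) {
    obs[sc$wavenumber >= iv[1] & sc$wavenumber <= iv[2]] <- FALSE
  }
  if (!any(obs))
    stop("mask covers the entire wavenumber axis; nothing observable",
         call. = FALSE)
  sc$M[!obs, ] <- NA_real_
  sc$observed <- obs
  sc
}

#' Synthesize a spectro-chromatogram from components
#'
#' Builds the bilinear mixture `M = sum_k outer(spectrum_k, temporal_k)` and
#' adds Gaussian detector noise.  Optionally, signal-proportional (shot)
#' noise can be added on top of the homoscedastic floor.
#'
#' @param components list of components, each a list with elements
#'   `spectrum` (a [component_spectrum()]) and `temporal` (numeric series on
#'   the time axis).
#' @param time the elution-time axis (min); must satisfy
#'   `length(time) <= length(wavenumber axis)` (economy factorization).
#' @param noise_sigma standard deviation of additive Gaussian noise, counts.
#' @param seed integer seed making the noise reproducible; `NULL` uses the
#'   current RNG state.
#' @param shot_noise_scale if positive, each entry additionally receives
#'   noise of standard deviation `shot_noise_scale * sqrt(|signal|)`.
#' @return a `spectro_chromatogram` with attribute `"components"` holding
#'   the generating spectra/series.
#' @export
synthesize_matrix <- function(components, time, noise_sigma = 0,
                              seed = NULL, shot_noise_scale = 0) {
  if (length(components) == 0L)
    stop("no components to synthesize", call. = FALSE)
  time <- time_axis(time)
  wav <- components[[1L]]$spectrum$wavenumber
  m <- length(wav)
  n <- length(time)
  if (n > m)
    stop("time axis longer than wavenumber axis (need n <= m)",
         call. = FALSE)
  M <- matrix(0, m, n)
  for (k in seq_along(components)) {
    cs <- components[[k]]$spectrum
    v <- as.numeric(components[[k]]$temporal)
    if (!inherits(cs, "component_spectrum"))
      stop("component ", k, " has no component_spectrum", call. = FALSE)
    if (length(cs$profile) != m || !isTRUE(all.equal(cs$wavenumber, wav)))
      stop("component ", k, " is on a different wavenumber axis",
           call. = FALSE)
    if (length(v) != n)
      stop("component ", k, " temporal series length mismatch",
           call. = FALSE)
    M <- M + outer(cs$profile, v)
  }
  if (noise_sigma > 0 || shot_noise_scale > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    sd_mat <- sqrt(noise_sigma^2 + shot_noise_scale^2 * abs(M))
    M <- M + matrix(stats::rnorm(m * n, sd = sd_mat), m, n)
  }
  sc <- spectro_chromatogram(M, wav, time)
  attr(sc, "components") <- components
  sc
}

#' Residence time of the eluate in a sampling volume
#'
#' Time (ms) for liquid flowing at `flow_rate` (mL/min) to pass through
#' `volume` (mm^3): `volume / flow_rate` with the flow rate expressed in
#' mm^3/ms (1 mL/min = 1000/60000 mm^3/ms).
#'
#' @param volume sampled volume, mm^3; must be positive.
#' @param flow_rate flow rate, mL/min; must be positive.
#' @return residence time in ms.
#' @examples
#' residence_time(0.17, 3) # 3.4 ms
#' @export
residence_time <- function(volume, flow_rate) {
  if (volume <= 0 || flow_rate <= 0)
    stop("volume and flow_rate must be positive", call. = FALSE)
  volume / (flow_rate * 1000 / 60000)
}

# stationary AR(1) series with marginal standard deviation sd
ar1_series <- function(n, sd, phi = 0.9) {
  if (sd <= 0) return(numeric(n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, sd = sd)
  eps <- stats::rnorm(n - 1, sd = sd * sqrt(1 - phi^2))
  for (i in seq_len(n - 1L)) x[i + 1L] <- phi * x[i] + eps[i]
  x
}

#' Simulate a full HILIC-Raman run with ground truth
#'
#' Generates a synthetic 2D spectro-chromatogram with the structural
#' features of a sugar HILIC run with Raman detection:
#' \itemize{
#'   \item one tailing elution peak per analyte (EMG), amplitude
#'     proportional to concentration via `sensitivity` (counts per mM at
#'     the band maximum);
#'   \item constant acetonitrile and water levels, each modulated by an
#'     independent zero-mean AR(1) fluctuation (flow instability of the
#'     liquid-core waveguide);
#'   \item a constant baseline that dips while analytes elute (the dip is a
#'     widened negative copy of the summed elution profiles, scaled by
#'     `dip_factor`);
#'   \item a derivative-shaped artifact from a fluctuating shift of the
#'     acetonitrile bands;
#'   \item for single-analyte runs, a slow linear baseline drift component;
#'   \item homoscedastic Gaussian detector noise.
#' }
#'
#' @param concentrations named numeric vector of analyte concentrations in
#'   mM, names from `c("Fru","Glu","Suc","Mal","Tre")`.  Order gives the
#'   component order.
#' @param seed integer seed; the whole run is bit-reproducible from it.
#' @param noise_sigma detector noise sd, counts.  The default (5) is 1% of
#'   the band-maximum signal of a 25 mM analyte at the default sensitivity.
#' @param centers,widths,tails per-analyte elution parameters (min); the
#'   defaults place the five sugars at their characteristic HILIC elution
#'   times (Fru 36.4, Glu 39.3, Suc 42.7, Mal 46.4, Tre 47.9).
#' @param sensitivity counts per mM at an analyte's strongest band.
#' @param acn_level,h2o_level,baseline_level solvent and background levels
#'   in counts.
#' @param solvent_fluct relative sd of the AR(1) solvent fluctuation.
#' @param shift_sd sd of the acetonitrile band-shift series, cm^-1.
#' @param dip_factor fraction of the summed analyte profiles subtracted
#'   from the baseline series.
#' @param drift include the slow linear drift component? Default: only for
#'   single-analyte runs (where the observed component count is six:
#'   analyte, ACN, H2O, baseline, band shift, drift).
#' @param mask a [mask_spec()] applied to the result; `NULL` for none.
#' @param wavenumber,time axes; defaults [default_wavenumber_axis()] and
#'   [default_time_axis()].
#' @return list with elements `data` (masked `spectro_chromatogram`),
#'   `unmasked` (same before masking) and `truth` (list: `peaks` data.frame
#'   of per-analyte center/width/tail/amplitude/concentration, `components`
#'   the generating spectra and temporal series, `noise_sigma`, `seed`,
#'   `sensitivity`).
#' @export
simulate_hilic_run <- function(concentrations = c(Fru = 25, Glu = 25,
                                                  Suc = 25, Mal = 25,
                                                  Tre = 25),
                               seed = 1L,
                               noise_sigma = 5,
                               centers = c(Fru = 36.4, Glu = 39.3,
                                           Suc = 42.7, Mal = 46.4,
                                           Tre = 47.9),
                               widths = 0.5,
                               tails = 0.2,
                               sensitivity = 20,
                               acn_level = 30000,
                               h2o_level = 5000,
                               baseline_level = 500,
                               solvent_fluct = 0.01,
                               shift_sd = 0.1,
                               dip_factor = 0.05,
                               drift = length(concentrations) == 1L,
                               mask = default_mask(),
                               wavenumber = default_wavenumber_axis(),
                               time = default_time_axis()) {
  analytes <- names(concentrations)
  if (is.null(analytes) || any(!nzchar(analytes)))
    stop("concentrations must be a named vector of analytes", call. = FALSE)
  wavenumber <- wavenumber_axis(wavenumber)
  time <- time_axis(time)
  n <- length(time)
  widths <- rep_len(widths, length(analytes))
  tails <- rep_len(tails, length(analytes))
  specs <- model_spectra(wavenumber, analytes = analytes)

  set.seed(as.integer(seed))

  peaks <- data.frame(analyte = analytes,
                      center = as.numeric(centers[analytes]),
                      width = widths, tail = tails,
                      concentration = as.numeric(concentrations),
                      amplitude = as.numeric(concentrations) * sensitivity,
                      stringsAsFactors = FALSE)
  comp <- list()
  dip <- numeric(n)
  for (i in seq_len(nrow(peaks))) {
    ps <- elution_profile_spec(peaks$center[i], peaks$width[i],
                               peaks$tail[i], peaks$amplitude[i])
    comp[[peaks$analyte[i]]] <- list(spectrum = specs[[peaks$analyte[i]]],
                                     temporal = make_elution_profile(ps, time))
    # the refractive-index dip is broader than the peak itself
    wide <- elution_profile_spec(peaks$center[i], peaks$width[i] * 1.25,
                                 peaks$tail[i], peaks$amplitude[i])
    dip <- dip + make_elution_profile(wide, time)
  }
  acn_series <- acn_level * (1 + ar1_series(n, solvent_fluct))
  h2o_series <- h2o_level * (1 + ar1_series(n, solvent_fluct))
  baseline_series <- baseline_level - dip_factor * dip
  shift_series <- acn_level * ar1_series(n, shift_sd)
  comp$ACN <- list(spectrum = specs$ACN, temporal = acn_series)
  comp$H2O <- list(spectrum = specs$H2O, temporal = h2o_series)
  comp$baseline <- list(spectrum = specs$baseline,
                        temporal = baseline_series)
  comp[["ACN-shift"]] <- list(spectrum = specs[["ACN-shift"]],
                              temporal = shift_series)
  if (drift) {
    drift_spec <- make_component_spectra(
      data.frame(center = 1000, width = 600, height = 1),
      wavenumber, kind = "baseline", name = "drift")
    comp$drift <- list(
      spectrum = drift_spec,
      temporal = 0.1 * baseline_level * seq(-1, 1, length.out = n))
  }

  noise_seed <- sample.int(.Machine$integer.max, 1L)
  sc <- synthesize_matrix(comp, time, noise_sigma = noise_sigma,
                          seed = noise_seed)
  masked <- if (is.null(mask)) sc else apply_mask(sc, mask)
  truth <- list(peaks = peaks, components = comp,
                noise_sigma = noise_sigma, seed = seed,
                sensitivity = sensitivity)
  list(data = masked, unmasked = sc, truth = truth)
}
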