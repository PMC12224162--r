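test_that("Gaussian peak fitting recovers noiseless parameters exactly", {
  t <- seq(40, 46, by = 0.05)
  y <- 1 * exp(-(t - 42.7)^2 / (2 * 0.4^2))
  pk <- fit_gaussian_peak(t, y, c(41, 45), analyte = "Suc")
  expect_true(pk$converged)
  expect_equal(pk$center, 42.7, tolerance = 1e-6)
  expect_equal(pk$sigma, 0.4, tolerance = 1e-6)
  expect_equal(pk$height, 1, tolerance = 1e-6)
  expect_equal(pk$area, 0.4 * sqrt(2 * pi), tolerance = 1e-6)
})

test_that("an all-zero curve is reported as not detected", {
  t <- seq(40, 46, by = 0.1)
  pk <- fit_gaussian_peak(t, rep(0, length(t)), c(41, 45))
  expect_false(pk$detected)
  expect_equal(pk$area, 0)
})

test_that("Gaussian fits of tailing peaks are biased late, bounded by the tail", {
  tau <- 0.5
  t <- seq(38, 50, by = 0.02)
  y <- make_elution_profile(
    elution_profile_spec(42.7, 0.4, tail = tau, amplitude = 1), t)
  # dense numeric mode of the tailing profile
  td <- seq(40, 46, length.out = 1e5)
  yd <- make_elution_profile(
    elution_profile_spec(42.7, 0.4, tail = tau, amplitude = 1), td)
  mode <- td[which.max(yd)]
  pk <- fit_gaussian_peak(t, y, c(40.5, 46))
  expect_gt(pk$center, mode)          # symmetric fit chases the tail
  expect_lt(pk$center - 42.7, tau + 0.1)
})

test_that("window integration matches closed forms", {
  t <- seq(30, 55, by = 0.1)
  box <- as.numeric(t >= 35.3 & t <= 38.0)
  expect_equal(integrate_window(t, box, c(35.3, 38.0)), 2.7)

  expect_error(integrate_window(t, box, c(60, 65)), "fewer than 2")

  g <- exp(-(t - 42)^2 / (2 * 0.4^2))
  a <- integrate_window(t, g, c(42 - 1.6, 42 + 1.6)) # +/- 4 sigma
  expect_equal(a, 0.4 * sqrt(2 * pi), tolerance = 1e-3)

  pk <- window_peak(t, g, c(40, 44), analyte = "x")
  expect_equal(pk$center, 42)
  expect_equal(pk$area, a, tolerance = 1e-3) # wider window, same mass
})

test_that("calibration reports exact fits and the 3/10 detection convention", {
  conc <- c(5, 10, 15, 20, 25)
  cal <- linear_calibration(conc, 2 * conc, mw = 342.3)
  expect_equal(cal$r2, 1)
  expect_equal(cal$se_resid, 0)
  expect_equal(cal$lod_molar, 0)

  set.seed(99)
  cal2 <- linear_calibration(conc, 2 * conc + rnorm(5, 0, 0.5),
                             mw = 342.3)
  expect_equal(cal2$loq_molar / cal2$lod_molar, 10 / 3)
  expect_equal(cal2$loq_mass / cal2$lod_mass, 10 / 3)
  expect_equal(cal2$lod_mass, cal2$lod_molar * 342.3)

  expect_error(linear_calibration(c(1, 2), c(1, 2)), "3 points")
  expect_error(linear_calibration(c(2, 2, 2), c(1, 2, 3)),
               "zero variance")
})

test_that("Monte-Carlo detection limits track the injected noise level", {
  conc <- c(5, 10, 15, 20, 25)
  slope_true <- 2; sigma_true <- 0.8
  set.seed(7)
  lods <- replicate(100, {
    resp <- slope_true * conc + rnorm(5, 0, sigma_true)
    linear_calibration(conc, resp)$lod_molar
  })
  nominal <- 3 * sigma_true / slope_true
  expect_lt(abs(median(lods) / nominal - 1), 1)  # within a factor of 2
  expect_gt(median(lods), nominal / 2)
})

test_that("mass to molar conversion reproduces printed table values", {
  expect_equal(round(convert_concentration(74, 342.3), 2), 0.22)
  expect_equal(round(convert_concentration(61, 180.16), 2), 0.34)
  expect_equal(convert_concentration(0, 180.16), 0)
  expect_error(convert_concentration(10, 0), "positive")
})

test_that("weight-percent bookkeeping against a single standard", {
  win <- c(35.3, 38.0)
  std <- hilicraman:::new_elution_peak("Fru", 36.4, 0.5, 1, 100, win)
  smp <- hilicraman:::new_elution_peak("Fru", 36.4, 0.5, 1, 100, win)
  q <- quantify_wt_percent(
    smp, std, standard = list(conc_mM = 200, injected_mL = 1),
    dilution = list(mass_g = 1, volume_mL = 20, injected_mL = 1),
    mw = 180.16)
  # 0.2 mmol in the 50 mg of honey injected -> 36.03 mg / 50 mg
  expect_equal(q$injected_mmol, 0.2)
  expect_equal(round(q$wt_percent, 1), 72.1)

  zero <- hilicraman:::new_elution_peak("Fru", NA, NA, 0, 0, win)
  q0 <- quantify_wt_percent(
    zero, std, standard = list(conc_mM = 200, injected_mL = 1),
    dilution = list(mass_g = 1, volume_mL = 20, injected_mL = 1),
    mw = 180.16)
  expect_false(q0$detected)
  expect_true(is.na(q0$wt_percent))

  # areas under the LOD-equivalent area are flagged not-detected
  tiny <- hilicraman:::new_elution_peak("Fru", 36.4, 0.5, 1, 0.05, win)
  qt <- quantify_wt_percent(
    tiny, std, standard = list(conc_mM = 200, injected_mL = 1),
    dilution = list(mass_g = 1, volume_mL = 20, injected_mL = 1),
    mw = 180.16, lod_mM = 0.34)
  expect_false(qt$detected)

  glu <- hilicraman:::new_elution_peak("Glu", 39.3, 0.5, 1, 100, win)
  expect_error(quantify_wt_percent(
    smp, glu, standard = list(conc_mM = 160, injected_mL = 1),
    dilution = list(mass_g = 1, volume_mL = 20, injected_mL = 1),
    mw = 180.16), "different analytes")
})

test_that("quantified amounts are invariant to a global intensity rescale", {
  run <- small_run("Suc", 100, seed = 12, noise_sigma = 0)
  fac <- svd_factor(run$data)
  specs <- model_spectra(run$data$wavenumber, analytes = "Suc")
  lib <- component_library(specs[c("Suc", "ACN", "H2O", "baseline",
                                   "ACN-shift")], n_free = 1L)
  area_of <- function(sc) {
    D <- target_rotation(svd_factor(sc), 6L, lib)
    cur <- elution_curve(D, "Suc")
    integrate_window(cur$time, cur$intensity, c(40.7, 43.3))
  }
  a1 <- area_of(run$data)
  sc2 <- run$data
  sc2$M <- sc2$M * 7.5
  a2 <- area_of(sc2)
  # areas scale together, so any amount computed as a ratio is unchanged
  expect_equal(a2 / a1, 7.5, tolerance = 1e-9)
})

test_that("normalized replicate calibrations collapse onto the unit line", {
  conc <- c(5, 10, 15, 20, 25)
  slopes <- vapply(1:3, function(rep) {
    areas <- vapply(seq_along(conc), function(i) {
      run <- small_run("Suc", conc[i], seed = 1000 * rep + i,
                       noise_sigma = 5)
      fac <- svd_factor(run$data)
      specs <- model_spectra(run$data$wavenumber, analytes = "Suc")
      lib <- component_library(specs[c("Suc", "ACN", "H2O", "baseline",
                                       "ACN-shift")], n_free = 1L)
      D <- target_rotation(fac, 6L, lib)
      cur <- elution_curve(D, "Suc")
      integrate_window(cur$time, cur$intensity, c(40.7, 43.3))
    }, numeric(1))
    norm_resp <- areas / areas[length(areas)]
    norm_conc <- conc / conc[length(conc)]
    coef(lm(norm_resp ~ norm_conc))[["norm_conc"]]
  }, numeric(1))
  expect_lt(median(abs(slopes - 1)), 0.02)
})
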