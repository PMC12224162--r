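test_that("band synthesis places peaks correctly and validates input", {
  ax <- small_wav()
  cs <- make_component_spectra(
    data.frame(center = 1130, width = 12, height = 1), ax, name = "Glu")
  expect_equal(ax[which.max(cs$profile)], ax[which.min(abs(ax - 1130))])
  expect_equal(max(cs$profile), 1, tolerance = 1e-3)

  expect_error(make_component_spectra(data.frame(), ax), "empty")
  expect_error(make_component_spectra(
    data.frame(center = 5000, width = 10, height = 1), ax), "range")
  expect_error(make_component_spectra(
    data.frame(center = 1000, width = -1, height = 1), ax), "positive")

  lor <- make_component_spectra(
    data.frame(center = 900, width = 8, height = 2), ax,
    shape = "lorentzian", name = "L")
  expect_gt(max(lor$profile), 1.9) # grid may straddle the band centre
  # Lorentzian tails decay much slower than Gaussian
  far <- which.min(abs(ax - 1300))
  gau <- make_component_spectra(
    data.frame(center = 900, width = 8, height = 2), ax, name = "G")
  expect_gt(lor$profile[far], 100 * gau$profile[far])
})

test_that("derivative-artifact spectra integrate to zero", {
  ax <- small_wav(512)
  d <- make_component_spectra(
    data.frame(center = c(918, 1375), width = c(5, 6),
               height = c(1, 0.5)),
    ax, kind = "derivative-artifact", name = "shift")
  l1 <- pracma::trapz(ax, abs(d$profile))
  expect_lt(abs(pracma::trapz(ax, d$profile)), 1e-6 * l1)
})

test_that("elution profiles: Gaussian mode, clipping, zero amplitude", {
  tax <- time_axis(seq(30, 55, by = 0.1))
  p <- make_elution_profile(
    elution_profile_spec(36.4, 0.5, tail = 0, amplitude = 2), tax)
  expect_equal(tax[which.max(p)], 36.4)
  expect_equal(max(p), 2)

  expect_equal(make_elution_profile(
    elution_profile_spec(36.4, 0.5, amplitude = 0), tax),
    numeric(length(tax)))

  expect_warning(make_elution_profile(
    elution_profile_spec(20, 0.5, amplitude = 1), tax), "clipped")
})

test_that("tailing peaks match an independent Gaussian*exponential convolution", {
  # oracle: numeric convolution of a Gaussian with an exponential decay
  center <- 36.4; sigma <- 0.5; tau <- 1.0
  dt <- 1e-3
  g_grid <- seq(-8, 8, by = dt)
  e_grid <- seq(0, 15, by = dt)
  conv <- convolve(dnorm(g_grid, 0, sigma), rev(dexp(e_grid, 1 / tau)),
                   type = "open") * dt
  t_conv <- center + (seq_along(conv) - 1) * dt + g_grid[1] + e_grid[1]

  tax <- time_axis(seq(30, 55, length.out = 2501))
  spec <- elution_profile_spec(center, sigma, tail = tau, amplitude = 1)
  p <- make_elution_profile(spec, tax)

  # EMG mode lies later than the Gaussian centre
  mode_oracle <- t_conv[which.max(conv)]
  expect_gt(mode_oracle, center)
  expect_lt(abs(tax[which.max(p)] - mode_oracle), 0.02)

  # shape agrees with the convolution oracle after area normalization
  p_dens <- p / pracma::trapz(tax, p)
  oracle_at <- approx(t_conv, conv, xout = tax)$y
  keep <- !is.na(oracle_at) & tax > 31 & tax < 50
  expect_lt(max(abs(p_dens[keep] - oracle_at[keep])), 1e-3)

  # tailing conserves the eluted amount (area of the untailed Gaussian)
  expect_equal(pracma::trapz(tax, p), sigma * sqrt(2 * pi),
               tolerance = 1e-4)
})

test_that("noiseless synthesis has exact numerical rank k", {
  tim <- small_time()
  for (k in c(1L, 3L, 5L)) {
    comp <- random_components(k, tim = tim, seed = 100 + k)
    sc <- synthesize_matrix(comp, tim, noise_sigma = 0)
    W <- svd(sc$M)$d
    expect_lt(W[k + 1] / W[1], 1e-10)
    expect_gt(W[k] / W[1], 1e-10)
  }
})

test_that("synthesis is linear in amplitude and deterministic under seed", {
  tim <- small_time()
  mk <- function(amp, noise = 0, seed = NULL) {
    comp <- random_components(2, tim = tim, seed = 5)
    comp[[1]]$temporal <- amp * comp[[1]]$temporal
    synthesize_matrix(comp, tim, noise_sigma = noise, seed = seed)
  }
  M0 <- mk(0)$M; M1 <- mk(1)$M; M2 <- mk(2)$M
  expect_lt(max(abs(M2 - 2 * M1 + M0)), 1e-9 * max(abs(M1)))

  a <- mk(1, noise = 3, seed = 11)$M
  b <- mk(1, noise = 3, seed = 11)$M
  expect_identical(a, b)

  full <- simulate_hilic_run(seed = 3, wavenumber = small_wav(),
                             time = small_time())
  again <- simulate_hilic_run(seed = 3, wavenumber = small_wav(),
                              time = small_time())
  expect_identical(full$data$M, again$data$M)
})

test_that("masking flags exactly the covered channels and nothing else", {
  run <- small_run(noise_sigma = 2, mask = NULL)
  sc <- run$unmasked

  expect_identical(apply_mask(sc, mask_spec(list()))$M, sc$M)
  expect_identical(apply_mask(sc, mask_spec(list(c(2200, 2300))))$M, sc$M)

  iv <- c(900, 940)
  masked <- apply_mask(sc, mask_spec(list(iv)))
  inside <- sc$wavenumber >= iv[1] & sc$wavenumber <= iv[2]
  expect_identical(!masked$observed, inside)
  expect_equal(sum(!masked$observed), sum(inside))
  expect_identical(masked$M[masked$observed, ], sc$M[masked$observed, ])
  expect_true(all(is.na(masked$M[!masked$observed, ])))

  expect_error(apply_mask(sc, mask_spec(list(c(0, 5000)))), "entire")

  # overlapping intervals are merged on normalization
  m <- mask_spec(list(c(900, 950), c(940, 980), c(300, 310)))
  expect_length(m, 2L)
  expect_equal(m[[2]], c(900, 980))
})

test_that("residence time follows volume / flow-rate in mm^3 per ms", {
  expect_equal(residence_time(0.17, 3), 3.4)
  expect_equal(residence_time(1, 60), 1.0)
  expect_equal(residence_time(0.0424, 3), 0.848)
  expect_error(residence_time(0, 3), "positive")
  expect_error(residence_time(1, -2), "positive")
})
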