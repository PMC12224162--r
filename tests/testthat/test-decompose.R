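test_that("svd_factor agrees with a brute-force eigendecomposition oracle", {
  set.seed(13)
  M <- matrix(rnorm(200), 20, 10)
  sc <- spectro_chromatogram(M, wavenumber_axis(seq(200, 1800,
                                                    length.out = 20)),
                             time_axis(1:10))
  fac <- svd_factor(sc)

  # oracle: singular values from eigen(M^T M)
  ev <- eigen(crossprod(M), symmetric = TRUE)$values
  expect_equal(fac$W, sqrt(pmax(ev, 0)), tolerance = 1e-8)

  recon <- fac$U %*% (fac$W * t(fac$V))
  expect_lt(max(abs(recon - M)), 1e-10 * max(abs(M)))

  # orthonormality of both factor sets
  expect_lt(max(abs(crossprod(fac$U) - diag(10))), 1e-8)
  expect_lt(max(abs(crossprod(fac$V) - diag(10))), 1e-8)
})

test_that("rank-1 data yields a single dominant singular value", {
  tim <- small_time()
  sc <- synthesize_matrix(random_components(1, tim = tim, seed = 2), tim)
  fac <- svd_factor(sc)
  expect_lt(fac$W[2] / fac$W[1], 1e-10)
})

test_that("svd_factor refuses non-finite observed entries", {
  wav <- small_wav(4)
  M <- matrix(1, 4, 3); M[2, 2] <- Inf
  sc <- spectro_chromatogram(M, wav, time_axis(1:3))
  expect_error(svd_factor(sc), "finite")
})

test_that("rank selection: scree gap, forced override, bounds", {
  expect_equal(select_rank(c(100, 50, 1e-8, 1e-9)), 2L)
  expect_equal(select_rank(rep(1, 20), k = 11), 11L)
  expect_error(select_rank(c(3, 2, 1), k = 5), "outside")

  run <- small_run("Fru", 200, seed = 4, noise_sigma = 0)
  fac <- svd_factor(run$data)
  expect_equal(select_rank(fac$W), 6L)
})

test_that("targets equal to the singular vectors give the identity rotation", {
  tim <- small_time()
  wav <- small_wav()
  sc <- synthesize_matrix(random_components(4, tim = tim, seed = 21), tim)
  fac <- svd_factor(sc)
  m1 <- 4L
  targets <- lapply(seq_len(m1), function(j)
    component_spectrum(paste0("u", j), fac$U[, j], wav, kind = "baseline"))
  D <- target_rotation(fac, m1, component_library(targets),
                       normalize_targets = FALSE)
  expect_equal(D$K, diag(m1), tolerance = 1e-8, ignore_attr = TRUE)
  VW <- sweep(fac$V[, 1:m1], 2, fac$W[1:m1], "*")
  expect_equal(unname(D$Vprime), VW, tolerance = 1e-6)
  expect_true(all(D$fit_residual < 1e-10))
})

test_that("rotation preserves the truncated reconstruction for any K", {
  for (seed in c(1, 2)) {
    run <- small_run("Suc", 100, seed = seed, noise_sigma = 3)
    fac <- svd_factor(run$data)
    specs <- model_spectra(run$data$wavenumber, analytes = "Suc")
    lib <- component_library(specs[c("Suc", "ACN", "H2O", "baseline",
                                     "ACN-shift")])
    D <- target_rotation(fac, 6L, lib)
    obs <- D$observed
    m1 <- D$rank
    trunc <- fac$U[, 1:m1] %*% (fac$W[1:m1] * t(fac$V[, 1:m1]))
    rot <- D$Uprime[obs, ] %*% t(D$Vprime)
    relerr <- norm(rot - trunc, "F") / norm(trunc, "F")
    expect_lt(relerr, 1e-8)
  }
})

test_that("noiseless single-sugar run recovers the elution peak exactly", {
  run <- small_run("Fru", 200, seed = 9, noise_sigma = 0)
  fac <- svd_factor(run$data)
  specs <- model_spectra(run$data$wavenumber, analytes = "Fru")
  lib <- component_library(specs[c("Fru", "ACN", "H2O", "baseline",
                                   "ACN-shift")], n_free = 1L)
  D <- target_rotation(fac, 6L, lib)
  expect_lt(D$fit_residual[["Fru"]], 1e-6)

  # dense evaluation of the true (tailing) profile locates its mode
  pk <- run$truth$peaks
  dense_t <- seq(30, 55, length.out = 1e5)
  dense <- make_elution_profile(
    elution_profile_spec(pk$center, pk$width, pk$tail, pk$amplitude),
    dense_t)
  true_mode <- dense_t[which.max(dense)]
  cur <- elution_curve(D, "Fru")
  step <- diff(cur$time[1:2])
  expect_lt(abs(cur$time[which.max(cur$intensity)] - true_mode), step)
})

test_that("five-sugar noiseless decomposition resolves all analytes in order", {
  run <- simulate_hilic_run(seed = 5, noise_sigma = 0,
                            wavenumber = small_wav(512),
                            time = small_time(250))
  fac <- svd_factor(run$data)
  expect_equal(sum(fac$W > 1e-10 * fac$W[1]), 9L)
  specs <- model_spectra(run$data$wavenumber)
  nm <- c("Fru", "Glu", "Suc", "Mal", "Tre", "ACN", "H2O", "baseline",
          "ACN-shift")
  D <- target_rotation(fac, 9L, component_library(specs[nm]))
  expect_true(all(D$fit_residual[1:5] < 1e-6))
  centers <- vapply(c("Fru", "Glu", "Suc", "Mal", "Tre"), function(a) {
    cur <- elution_curve(D, a)
    cur$time[which.max(cur$intensity)]
  }, numeric(1))
  expect_true(all(diff(centers) > 0)) # Fru < Glu < Suc < Mal < Tre
})

test_that("permuting the targets permutes the components identically", {
  run <- small_run("Glu", 160, seed = 6, noise_sigma = 2)
  fac <- svd_factor(run$data)
  specs <- model_spectra(run$data$wavenumber, analytes = "Glu")
  nm <- c("Glu", "ACN", "H2O", "baseline", "ACN-shift")
  D1 <- target_rotation(fac, 6L, component_library(specs[nm]))
  perm <- c(3, 1, 5, 2, 4)
  D2 <- target_rotation(fac, 6L, component_library(specs[nm[perm]]))
  expect_equal(D2$Vprime[, nm], D1$Vprime[, nm], tolerance = 1e-10)
  expect_equal(D2$Uprime[, nm], D1$Uprime[, nm], tolerance = 1e-10)
  expect_equal(D2$fit_residual[nm], D1$fit_residual[nm],
               tolerance = 1e-12)
})

test_that("rotation rejects invalid ranks and collinear targets", {
  run <- small_run("Fru", 100, seed = 8, noise_sigma = 1)
  fac <- svd_factor(run$data)
  specs <- model_spectra(run$data$wavenumber, analytes = "Fru")
  nm <- c("Fru", "ACN", "H2O", "baseline", "ACN-shift")
  expect_error(target_rotation(fac, 3L, component_library(specs[nm])),
               "at least the number of targets")
  dup <- specs[c("Fru", "Fru", "ACN")]
  dup[[2]]$name <- "Fru2"
  expect_error(target_rotation(fac, 6L, component_library(dup)),
               "collinear.*Fru", ignore.case = TRUE)
})

test_that("unit-temporal normalization conserves the bilinear product", {
  run <- small_run("Suc", 50, seed = 10, noise_sigma = 2)
  fac <- svd_factor(run$data)
  specs <- model_spectra(run$data$wavenumber, analytes = "Suc")
  D <- target_rotation(fac, 6L, component_library(
    specs[c("Suc", "ACN", "H2O", "baseline", "ACN-shift")], n_free = 1L))
  N <- normalize_components(D)
  obs <- D$observed
  before <- D$Uprime[obs, ] %*% t(D$Vprime)
  after <- N$Uprime[obs, ] %*% t(N$Vprime)
  expect_lt(max(abs(after - before)), 1e-12 * max(abs(before)))
  expect_equal(unname(apply(abs(N$Vprime), 2, max)),
               rep(1, ncol(N$Vprime)))

  jmax <- which.max(abs(D$Vprime[, "Suc"]))
  expect_equal(N$Uprime[obs, "Suc"],
               D$Uprime[obs, "Suc"] * abs(D$Vprime[jmax, "Suc"]),
               tolerance = 1e-12)

  Z <- D
  Z$Vprime[, "free1"] <- 0
  expect_warning(normalize_components(Z), "all zero")
})
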