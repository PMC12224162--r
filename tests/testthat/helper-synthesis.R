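# compact axes for fast unit tests; acceptance tests use the full defaults
small_wav <- function(n = 512) wavenumber_axis(seq(200, 1800, length.out = n))
small_time <- function(n = 125) time_axis(seq(30, 55, length.out = n))

# k linearly independent synthetic components on the small axes
random_components <- function(k, wav = small_wav(), tim = small_time(),
                              seed = 42) {
  set.seed(seed)
  lapply(seq_len(k), function(i) {
    bands <- data.frame(center = runif(3, 300, 1700),
                        width = runif(3, 8, 25),
                        height = runif(3, 0.3, 1))
    list(spectrum = make_component_spectra(bands, wav,
                                           name = paste0("c", i)),
         temporal = make_elution_profile(
           elution_profile_spec(runif(1, 32, 52), runif(1, 0.4, 1.5),
                                amplitude = runif(1, 50, 500)), tim))
  })
}

# scaled-down single-analyte run for unit tests
small_run <- function(analyte = "Fru", conc = 200, seed = 7,
                      noise_sigma = 0, ...) {
  simulate_hilic_run(concentrations = stats::setNames(conc, analyte),
                     seed = seed, noise_sigma = noise_sigma,
                     wavenumber = small_wav(), time = small_time(), ...)
}
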