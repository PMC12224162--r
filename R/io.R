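#' Write a spectro-chromatogram as delimited text
#'
#' Tab-delimited dialect: first row is the time axis (min) with an empty
#' corner cell, first column the wavenumber axis (cm^-1), the body the
#' intensities in counts.  Unobserved cells are written as `NA`.  Values
#' are written with 17 significant digits so the round trip through
#' [read_matrix()] is exact.
#'
#' @param sc a [spectro_chromatogram()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(sc, path) {
  stopifnot(inherits(sc, "spectro_chromatogram"))
  fmt <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
  }
  header <- paste(c("", fmt(sc$time)), collapse = "\t")
  body <- vapply(seq_len(nrow(sc$M)), function(i) {
    paste(c(fmt(sc$wavenumber[i]), fmt(sc$M[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a spectro-chromatogram from delimited text
#'
#' Reads the dialect written by [write_matrix()].  Rows that are entirely
#' `NA` are reconstructed as unobserved (masked) channels.  Ragged rows
#' and non-monotonic axes raise errors naming the offending line.
#'
#' @param path input file.
#' @return a [spectro_chromatogram()].
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("matrix file too short: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(fields[[1L]])
  time <- suppressWarnings(as.numeric(fields[[1L]][-1L]))
  if (anyNA(time))
    stop("line 1: time axis header is not numeric", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("line 1: time axis is not strictly increasing", call. = FALSE)
  m <- length(lines) - 1L
  wav <- numeric(m)
  M <- matrix(NA_real_, m, length(time))
  for (i in seq_len(m)) {
    f <- fields[[i + 1L]]
    if (length(f) != ncols)
      stop(sprintf("line %d: expected %d fields, found %d", i + 1L,
                   ncols, length(f)), call. = FALSE)
    row <- suppressWarnings(
      ifelse(f == "NA", NA_real_, as.numeric(f)))
    if (is.na(row[1L]))
      stop(sprintf("line %d: wavenumber is not numeric", i + 1L),
           call. = FALSE)
    wav[i] <- row[1L]
    M[i, ] <- row[-1L]
  }
  bad <- which(diff(wav) <= 0)
  if (length(bad) > 0L)
    stop(sprintf("line %d: wavenumber axis is not strictly increasing",
                 bad[1L] + 2L), call. = FALSE)
  spectro_chromatogram(M, wav, time)
}

#' Write / read a component spectrum as two-column text
#'
#' Tab-delimited, header `wavenumber_cm1  intensity`, full precision.
#'
#' @param cs a [component_spectrum()].
#' @param path file path.
#' @return `write_spectrum`: `path` invisibly; `read_spectrum`: a
#'   `component_spectrum`.
#' @export
write_spectrum <- function(cs, path) {
  stopifnot(inherits(cs, "component_spectrum"))
  lines <- c("wavenumber_cm1\tintensity",
             sprintf("%.17g\t%.17g", cs$wavenumber, cs$profile))
  writeLines(lines, path)
  invisible(path)
}

#' @param name,kind identity given to the spectrum read back.
#' @rdname write_spectrum
#' @export
read_spectrum <- function(path, name = "spectrum", kind = "solvent") {
  d <- utils::read.delim(path, header = TRUE)
  component_spectrum(name, d[[2L]], d[[1L]], kind = kind)
}

#' Write simulation ground truth as a flat YAML config
#'
#' Scalars and the per-analyte peak table only; the stochastic series are
#' regenerable from the recorded seed.
#'
#' @param truth the `truth` element of [simulate_hilic_run()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  flat <- list(seed = truth$seed, noise_sigma = truth$noise_sigma,
               sensitivity = truth$sensitivity,
               analytes = truth$peaks$analyte,
               center_min = truth$peaks$center,
               width_min = truth$peaks$width,
               tail_min = truth$peaks$tail,
               concentration_mM = truth$peaks$concentration,
               amplitude = truth$peaks$amplitude)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  yaml::read_yaml(path)
}
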