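#' Construct a spectro-chromatogram
#'
#' The central container: an m x n intensity matrix with wavenumber rows
#' (cm^-1) and elution-time columns (min), plus a per-channel logical
#' `observed` flag.  Channels blocked by the spatial line-rejection mask are
#' unobserved at every time point (the mask is spectral, not temporal);
#' their rows are carried as NA and never imputed.
#'
#' @param M numeric m x n matrix of intensities (counts).
#' @param wavenumber spectral axis, length m (see [wavenumber_axis()]).
#' @param time temporal axis, length n (see [time_axis()]).
#' @param observed logical vector of length m; `FALSE` rows are masked.
#'   Defaults to all observed, except rows that are entirely NA.
#' @return an object of class `spectro_chromatogram`: a list with elements
#'   `M`, `wavenumber`, `time`, `observed`.
#' @export
spectro_chromatogram <- function(M, wavenumber, time, observed = NULL) {
  M <- as.matrix(M)
  wavenumber <- wavenumber_axis(wavenumber)
  time <- time_axis(time)
  if (nrow(M) != length(wavenumber))
    stop("nrow(M) must match the wavenumber axis length", call. = FALSE)
  if (ncol(M) != length(time))
    stop("ncol(M) must match the time axis length", call. = FALSE)
  if (is.null(observed)) {
    observed <- !apply(M, 1L, function(r) all(is.na(r)))
  }
  observed <- as.logical(observed)
  if (length(observed) != nrow(M))
    stop("observed flags must have one entry per wavenumber channel",
         call. = FALSE)
  # enforce the spectral-mask semantics: an unobserved channel is NA always
  M[!observed, ] <- NA_real_
  if (anyNA(M[observed, , drop = FALSE]))
    stop("observed channels must not contain NA", call. = FALSE)
  structure(list(M = M, wavenumber = wavenumber, time = time,
                 observed = observed),
            class = "spectro_chromatogram")
}

#' @export
print.spectro_chromatogram <- function(x, ...) {
  cat(sprintf(
    "spectro_chromatogram: %d wavenumber channels (%.1f-%.1f cm^-1), %d time points (%.2f-%.2f min)\n",
    nrow(x$M), min(x$wavenumber), max(x$wavenumber),
    ncol(x$M), min(x$time), max(x$time)))
  n_mask <- sum(!x$observed)
  if (n_mask > 0)
    cat(sprintf("  %d channels masked (unobserved)\n", n_mask))
  invisible(x)
}

#' @export
dim.spectro_chromatogram <- function(x) dim(x$M)
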