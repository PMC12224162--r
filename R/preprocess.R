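#' Block-average spectra along the time axis
#'
#' Averages consecutive groups of `block` columns (e.g. ten raw 0.4 s
#' exposures per stored spectrum).  Each output column is the arithmetic
#' mean of its block and is stamped with the mean of the block's times.
#' If the column count is not divisible by `block`, the trailing partial
#' block is dropped with a warning.
#'
#' @param sc a [spectro_chromatogram()].
#' @param block number of columns per block, >= 1 and <= ncol.
#' @return the block-averaged `spectro_chromatogram`.
#' @export
block_average <- function(sc, block) {
  stopifnot(inherits(sc, "spectro_chromatogram"))
  block <- as.integer(block)
  n <- ncol(sc$M)
  if (block < 1L) stop("block must be >= 1", call. = FALSE)
  if (block > n) stop("block exceeds the number of columns", call. = FALSE)
  if (block == 1L) return(sc)
  nb <- n %/% block
  if (n %% block != 0L)
    warning(sprintf("dropping %d trailing columns (partial block)",
                    n %% block), call. = FALSE)
  idx <- seq_len(nb * block)
  grp <- rep(seq_len(nb), each = block)
  # group means via matrix product with the averaging operator
  A <- matrix(0, nb * block, nb)
  A[cbind(idx, grp)] <- 1 / block
  M2 <- sc$M[, idx, drop = FALSE] %*% A
  t2 <- as.numeric(tapply(sc$time[idx], grp, mean))
  if (nb == 1L) {
    # degenerate single-column result: bypass the >= 2 time point validation
    sc$M <- M2
    sc$time <- t2
    return(sc)
  }
  spectro_chromatogram(M2, sc$wavenumber, t2, observed = sc$observed)
}

#' Crop a spectro-chromatogram to a time window
#'
#' Retains columns with `t0 <= t <= t1`, inclusive at both ends.
#'
#' @param sc a [spectro_chromatogram()].
#' @param t0,t1 window limits, min.
#' @return the cropped `spectro_chromatogram`.
#' @export
crop_window <- function(sc, t0, t1) {
  stopifnot(inherits(sc, "spectro_chromatogram"))
  eps <- 1e-9 * max(1, abs(t0), abs(t1))
  keep <- sc$time >= t0 - eps & sc$time <= t1 + eps
  if (sum(keep) == 0L)
    stop("no columns inside the requested time window", call. = FALSE)
  if (sum(keep) == 1L) {
    # degenerate single-column crop: bypass the >= 2 time point validation
    out <- sc
    out$M <- sc$M[, keep, drop = FALSE]
    out$time <- sc$time[keep]
    return(out)
  }
  spectro_chromatogram(sc$M[, keep, drop = FALSE], sc$wavenumber,
                       sc$time[keep], observed = sc$observed)
}

#' Define a solvent reference for subtraction
#'
#' @param profile a [component_spectrum()] of the running solvent (it may be
#'   a composite, e.g. acetonitrile plus water at their mixing ratio).
#' @param scale_channels list of wavenumber intervals used to estimate the
#'   per-column subtraction scale; defaults to the neighbourhood
#'   (+/- `halfwidth` cm^-1) of the strongest band of `profile`.  The
#'   intervals must contain at least 3 observed channels at use time.
#' @param halfwidth half-width (cm^-1) of the default scale neighbourhood.
#' @return an object of class `solvent_reference`.
#' @export
solvent_reference <- function(profile, scale_channels = NULL,
                              halfwidth = 20) {
  stopifnot(inherits(profile, "component_spectrum"))
  structure(list(profile = profile, scale_channels = scale_channels,
                 halfwidth = halfwidth),
            class = "solvent_reference")
}

# resolve scale channel indices for a reference on a chromatogram
scale_channel_index <- function(sc, ref) {
  if (is.null(ref$scale_channels)) {
    p <- abs(ref$profile$profile)
    p[!sc$observed] <- -Inf
    i0 <- which.max(p)
    w0 <- sc$wavenumber[i0]
    ivs <- list(c(w0 - ref$halfwidth, w0 + ref$halfwidth))
  } else {
    ivs <- ref$scale_channels
  }
  idx <- logical(length(sc$wavenumber))
  for (iv in ivs) {
    idx <- idx | (sc$wavenumber >= iv[1] & sc$wavenumber <= iv[2])
  }
  which(idx & sc$observed)
}

#' Subtract the solvent spectrum column by column
#'
#' For every time column j a scale s_j is fitted by least squares of the
#' column against the solvent reference profile restricted to the scale
#' channels, and `s_j * profile` is subtracted from the observed channels.
#' The per-column scale absorbs the temporal fluctuation of the solvent
#' intensity.  Unobserved channels are untouched (still NA).
#'
#' The operation is idempotent up to numerical noise: re-running it on its
#' own output yields scales that are ~0.
#'
#' @param sc a [spectro_chromatogram()].
#' @param ref a [solvent_reference()].
#' @return list with `data` (solvent-subtracted `spectro_chromatogram`) and
#'   `scales` (numeric per-column scale series).
#' @export
subtract_solvent <- function(sc, ref) {
  stopifnot(inherits(sc, "spectro_chromatogram"),
            inherits(ref, "solvent_reference"))
  if (length(ref$profile$profile) != length(sc$wavenumber))
    stop("solvent reference is on a different wavenumber axis",
         call. = FALSE)
  idx <- scale_channel_index(sc, ref)
  if (length(idx) < 3L)
    stop("scale channels must contain at least 3 observed channels",
         call. = FALSE)
  r <- ref$profile$profile[idx]
  denom <- sum(r^2)
  if (denom <= (1e-12 * max(abs(ref$profile$profile)))^2 * length(r) ||
      denom == 0)
    stop("degenerate fit: solvent reference ~ 0 on the scale channels",
         call. = FALSE)
  scales <- as.numeric(crossprod(sc$M[idx, , drop = FALSE], r)) / denom
  obs <- sc$observed
  sc$M[obs, ] <- sc$M[obs, , drop = FALSE] -
    outer(ref$profile$profile[obs], scales)
  list(data = sc, scales = scales)
}

#' Widen the spectral mask
#'
#' Extends every unobserved wavenumber run by `margin` cm^-1 on each side.
#' This is the explicit counterpart of erasing data points adjacent to
#' subtraction artifacts: instead of deleting outliers heuristically, the
#' mask is enlarged by a stated amount.
#'
#' @param sc a [spectro_chromatogram()].
#' @param margin widening margin in cm^-1.
#' @return the `spectro_chromatogram` with the enlarged mask.
#' @export
widen_mask <- function(sc, margin) {
  stopifnot(inherits(sc, "spectro_chromatogram"))
  if (margin <= 0) return(sc)
  bad <- which(!sc$observed)
  if (length(bad) == 0L) return(sc)
  obs <- sc$observed
  for (i in bad) {
    w0 <- sc$wavenumber[i]
    obs[sc$wavenumber >= w0 - margin & sc$wavenumber <= w0 + margin] <- FALSE
  }
  if (!any(obs))
    stop("widened mask covers the entire axis", call. = FALSE)
  sc$M[!obs, ] <- NA_real_
  sc$observed <- obs
  sc
}
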