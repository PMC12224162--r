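#' Singular value decomposition of a spectro-chromatogram
#'
#' Factorizes the observed part of the data matrix as
#' `M = U W V^T` (economy SVD): `U` holds column-orthonormal spectral
#' factors on the observed channels, `W` the non-increasing singular
#' values, `V` column-orthonormal temporal factors.  Masked channels are
#' excluded from the factorization, never zero-filled (zero-filling would
#' manufacture spurious components at mask edges).
#'
#' @param sc a [spectro_chromatogram()]; all observed entries must be
#'   finite.
#' @return an object of class `svd_factors`: list with `U` (m_obs x r),
#'   `W` (length r), `V` (n x r), `observed`, `wavenumber`, `time`, where
#'   `r = min(m_obs, n)`.
#' @export
svd_factor <- function(sc) {
  stopifnot(inherits(sc, "spectro_chromatogram"))
  Mo <- sc$M[sc$observed, , drop = FALSE]
  if (!all(is.finite(Mo)))
    stop("observed entries must all be finite", call. = FALSE)
  r <- min(dim(Mo))
  s <- svd(Mo, nu = r, nv = r)
  structure(list(U = s$u, W = s$d[seq_len(r)], V = s$v,
                 observed = sc$observed, wavenumber = sc$wavenumber,
                 time = sc$time),
            class = "svd_factors")
}

#' @export
print.svd_factors <- function(x, ...) {
  cat(sprintf("svd_factors: %d x %d observed matrix, %d singular values\n",
              nrow(x$U), length(x$time), length(x$W)))
  cat("  leading SVs:",
      paste(signif(utils::head(x$W, 6), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Choose the number of significant components
#'
#' Rank selection from the singular value plot.  With `k` supplied the
#' user's choice is returned unchanged (e.g. feeding more vectors than the
#' visual count suggests, to hunt for minor components).  Otherwise the
#' rank maximizing the log-gap `log(w_i / w_{i+1})` over
#' `search = lo:hi` is returned — the scree-gap criterion.
#'
#' @param W numeric vector of singular values, non-increasing.
#' @param k optional forced rank.
#' @param search integer range of candidate ranks for the automatic gap
#'   search; defaults to `1:min(15, length(W) - 1)`.
#' @return the selected rank `m1`.
#' @export
select_rank <- function(W, k = NULL, search = NULL) {
  W <- as.numeric(W)
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 1L || k > length(W))
      stop("forced rank k outside 1..length(W)", call. = FALSE)
    return(k)
  }
  if (is.null(search)) search <- seq_len(min(15L, length(W) - 1L))
  search <- search[search >= 1L & search < length(W)]
  if (length(search) == 0L)
    stop("empty rank search range", call. = FALSE)
  Ws <- pmax(W, .Machine$double.xmin)
  gaps <- log(Ws[search]) - log(Ws[search + 1L])
  search[which.max(gaps)]
}

# restrict and (optionally) peak-normalize library targets to the
# observed channels
prepare_targets <- function(lib, observed, normalize = TRUE) {
  Tn <- vapply(lib$targets, function(cs) cs$profile[observed],
               numeric(sum(observed)))
  Tn <- as.matrix(Tn)
  scl <- apply(abs(Tn), 2L, max)
  if (any(scl == 0))
    stop("target spectrum identically zero on observed channels",
         call. = FALSE)
  if (!normalize) return(list(Tn = Tn, scale = rep(1, ncol(Tn))))
  list(Tn = sweep(Tn, 2L, scl, "/"), scale = scl)
}

#' Assemble a library of rotation targets
#'
#' @param targets list of [component_spectrum()] objects to be matched, in
#'   the component order wanted in the result.
#' @param n_free number of additional unconstrained components expected
#'   beyond the targets (baseline/residual structure).
#' @return an object of class `component_library`.
#' @export
component_library <- function(targets, n_free = 0L) {
  if (length(targets) == 0L)
    stop("target list is empty", call. = FALSE)
  ok <- vapply(targets, inherits, logical(1), "component_spectrum")
  if (!all(ok))
    stop("all targets must be component_spectrum objects", call. = FALSE)
  nm <- vapply(targets, `[[`, character(1), "name")
  names(targets) <- nm
  structure(list(targets = targets, n_free = as.integer(n_free)),
            class = "component_library")
}

collinear_pair <- function(Tn, names) {
  C <- abs(stats::cor(Tn))
  diag(C) <- 0
  ij <- which(C == max(C), arr.ind = TRUE)[1L, ]
  paste(names[ij], collapse = " / ")
}

#' Rotate SVD factors onto model spectra
#'
#' Truncates the factorization to its `m1` leading components and rotates
#' them by a regular `m1 x m1` matrix K so that the rotated spectral
#' vectors match the library targets:
#' `M ~ U_m1 W_m1 V_m1^T = (U_m1 K)(K^-1 W_m1 V_m1^T) = U' V'^T`.
#'
#' Because the truncated spectral factors are column-orthonormal, the
#' least-squares problem `min || U_m1 k_j - target_j ||^2` for each target
#' has the closed-form solution `k_j = U_m1^T target_j`; the remaining
#' `m1 - p` free columns of K are an orthonormal basis of the complement
#' of the fitted columns within the truncated subspace, ordered by the
#' variance their temporal vectors explain.  The temporal factors
#' transform by the inverse, `V' = V_m1 W_m1 K^-T`, so the truncated
#' reconstruction `U' V'^T` is preserved exactly.
#'
#' Targets are peak-normalized (max |value| = 1) on the observed channels
#' before fitting; the applied scale is reported in `target_scale`.
#' Each targeted component's sign is fixed by a positive inner product
#' with its target; each free component's largest-magnitude temporal
#' element is made positive.
#'
#' @param F an [svd_factor()] result.
#' @param m1 truncation rank; must be >= the number of targets.
#' @param lib a [component_library()].
#' @param normalize_targets peak-normalize targets before fitting
#'   (default).  With `FALSE` the targets are used at their native scale,
#'   so targets equal to the leading left singular vectors give exactly
#'   the identity rotation.
#' @return an object of class `decomposition`: list with `rank`, `K`,
#'   `K_condition`, `Uprime` (full-axis spectra, NA on masked channels),
#'   `Vprime` (n x m1 temporal vectors), `fit_residual` (per-target
#'   relative L2 mismatch), `target_names`, `target_scale`, `wavenumber`,
#'   `time`, `observed`.
#' @export
target_rotation <- function(F, m1, lib, normalize_targets = TRUE) {
  stopifnot(inherits(F, "svd_factors"), inherits(lib, "component_library"))
  m1 <- as.integer(m1)
  p <- length(lib$targets)
  if (m1 > length(F$W))
    stop("m1 exceeds the number of singular values", call. = FALSE)
  if (m1 < p)
    stop("m1 must be at least the number of targets", call. = FALSE)
  nm <- names(lib$targets)
  for (cs in lib$targets) {
    if (length(cs$profile) != length(F$wavenumber))
      stop("target '", cs$name, "' is on a different wavenumber axis",
           call. = FALSE)
  }
  pt <- prepare_targets(lib, F$observed, normalize = normalize_targets)
  Tn <- pt$Tn
  scl <- pt$scale
  # mutual linear independence of the targets on the observed channels
  if (p > 1L) {
    g <- svd(Tn, nu = 0, nv = 0)$d
    if ((g[1] / g[p])^2 >= 1e8)
      stop("targets nearly collinear on observed channels: ",
           collinear_pair(Tn, nm), call. = FALSE)
  }

  U1 <- F$U[, seq_len(m1), drop = FALSE]
  Kt <- crossprod(U1, Tn)                    # m1 x p, closed-form LS
  fitted <- U1 %*% Kt
  fit_residual <- sqrt(colSums((fitted - Tn)^2) / colSums(Tn^2))
  names(fit_residual) <- nm

  if (m1 > p) {
    Q <- qr.Q(qr(Kt), complete = TRUE)
    Kf <- Q[, (p + 1L):m1, drop = FALSE]
    K <- cbind(Kt, Kf)
  } else {
    K <- Kt
  }
  sv_K <- svd(K, nu = 0, nv = 0)$d
  K_condition <- sv_K[1] / sv_K[length(sv_K)]
  if (!is.finite(K_condition) || K_condition > 1e12)
    stop("rotation matrix K is singular; collinear targets: ",
         collinear_pair(Tn, nm), call. = FALSE)

  Vw <- sweep(F$V[, seq_len(m1), drop = FALSE], 2L, F$W[seq_len(m1)], "*")
  Vprime <- Vw %*% t(solve(K))
  Uprime_obs <- U1 %*% K

  if (m1 > p) {
    free <- (p + 1L):m1
    # sign: largest-magnitude temporal element positive
    for (j in free) {
      i0 <- which.max(abs(Vprime[, j]))
      if (Vprime[i0, j] < 0) {
        Vprime[, j] <- -Vprime[, j]
        Uprime_obs[, j] <- -Uprime_obs[, j]
        K[, j] <- -K[, j]
      }
    }
    # order free components by explained temporal variance
    o <- free[order(colSums(Vprime[, free, drop = FALSE]^2),
                    decreasing = TRUE)]
    perm <- c(seq_len(p), o)
    Vprime <- Vprime[, perm, drop = FALSE]
    Uprime_obs <- Uprime_obs[, perm, drop = FALSE]
    K <- K[, perm, drop = FALSE]
  }

  Uprime <- matrix(NA_real_, length(F$wavenumber), m1)
  Uprime[F$observed, ] <- Uprime_obs
  cn <- c(nm, if (m1 > p) paste0("free", seq_len(m1 - p)))
  colnames(Uprime) <- colnames(Vprime) <- colnames(K) <- cn

  structure(list(rank = m1, K = K, K_condition = K_condition,
                 Uprime = Uprime, Vprime = Vprime,
                 fit_residual = fit_residual, target_names = nm,
                 target_scale = stats::setNames(scl, nm),
                 wavenumber = F$wavenumber, time = F$time,
                 observed = F$observed),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("decomposition: rank %d, %d targets, cond(K) = %.3g\n",
              x$rank, length(x$target_names), x$K_condition))
  cat("  target fit residuals:\n")
  print(signif(x$fit_residual, 3))
  invisible(x)
}

#' Normalize rotated components
#'
#' Mode `"unit-temporal"`: each temporal vector is scaled to
#' max |value| = 1 and the inverse scale applied to its spectral vector,
#' so the magnitude of the spectral vector reports the contribution of
#' the component while the product `U' V'^T` is unchanged.  All-zero
#' components are left unscaled with a warning.
#'
#' @param D a [target_rotation()] result.
#' @param mode normalization mode; only `"unit-temporal"` is defined.
#' @return the rescaled `decomposition`.
#' @export
normalize_components <- function(D, mode = "unit-temporal") {
  stopifnot(inherits(D, "decomposition"))
  mode <- match.arg(mode, "unit-temporal")
  for (j in seq_len(ncol(D$Vprime))) {
    s <- max(abs(D$Vprime[, j]))
    if (s == 0) {
      warning("component ", colnames(D$Vprime)[j],
              " is all zero; left unscaled", call. = FALSE)
      next
    }
    D$Vprime[, j] <- D$Vprime[, j] / s
    D$Uprime[, j] <- D$Uprime[, j] * s
  }
  D
}

#' Screen rotation targets by their transformation residual
#'
#' Target testing: a model spectrum that cannot be reproduced within the
#' truncated subspace (relative least-squares residual above
#' `max_residual`) is judged absent from the mixture.  Fitting such a
#' target anyway makes its K column chase noise directions, which both
#' yields a meaningless elution curve and can make K nearly singular when
#' two absent targets collide in the same noise subspace.  The screened
#' library (absent targets removed) should be re-rotated.
#'
#' @param F an [svd_factor()] result.
#' @param m1 truncation rank used for the screening fit.
#' @param lib a [component_library()].
#' @param max_residual largest relative residual accepted as "present";
#'   present targets typically fit to a few percent, absent ones leave
#'   most of their norm unexplained.
#' @return list with `present` (named logical) and `residual` (named
#'   numeric).
#' @export
screen_targets <- function(F, m1, lib, max_residual = 0.5) {
  stopifnot(inherits(F, "svd_factors"), inherits(lib, "component_library"))
  m1 <- as.integer(m1)
  if (m1 > length(F$W))
    stop("m1 exceeds the number of singular values", call. = FALSE)
  Tn <- prepare_targets(lib, F$observed)$Tn
  U1 <- F$U[, seq_len(m1), drop = FALSE]
  K <- crossprod(U1, Tn)
  resid <- sqrt(colSums((U1 %*% K - Tn)^2) / colSums(Tn^2))
  names(resid) <- names(lib$targets)
  list(present = resid <= max_residual, residual = resid)
}

#' Extract one resolved elution curve
#'
#' @param D a [target_rotation()] result.
#' @param component column name or index.
#' @return data.frame with columns `time` (min) and `intensity`.
#' @export
elution_curve <- function(D, component) {
  stopifnot(inherits(D, "decomposition"))
  data.frame(time = D$time, intensity = D$Vprime[, component])
}
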