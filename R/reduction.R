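#' Orthonormal DCT-II basis matrix
#'
#' Returns the `n x n` orthonormal type-II discrete cosine transform
#' matrix `D`, so `D %*% x` are the DCT coefficients of `x` and
#' `t(D) %*% z` the inverse transform.
#'
#' @param n number of samples.
#' @export
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  D <- sqrt(2 / n) * cos(pi * outer(k, (2 * k + 1) / (2 * n)))
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

#' Spatial mode projector from the leadfield Gram matrix
#'
#' Eigenvectors of `L L^T` whose eigenvalues are at least
#' `rel_eigen_tol` times the mean eigenvalue, ordered by descending
#' eigenvalue and arranged as rows.  These dominant spatial modes span
#' the sensor-space directions the forward model can actually produce.
#'
#' @param L a `leadfield` or a gain matrix (`n_sensors x v`).
#' @param rel_eigen_tol relative eigenvalue cutoff (default `exp(-16)`).
#' @return a `u x n_sensors` matrix with orthonormal rows.
#' @export
spatial_projector <- function(L, rel_eigen_tol = exp(-16)) {
  gain <- if (inherits(L, "leadfield")) L$gain else L
  if (!all(is.finite(gain))) stop_param("leadfield contains non-finite values")
  if (nrow(gain) < 2) stop_param("need at least 2 sensors")
  if (all(gain == 0)) stop_param("all-zero leadfield")
  gram <- tcrossprod(gain)
  e <- eigen(sym(gram), symmetric = TRUE)
  keep <- e$values >= rel_eigen_tol * mean(e$values)
  U <- t(e$vectors[, keep, drop = FALSE])
  U
}

#' Temporal mode projector from spatially reduced epochs
#'
#' The spatially reduced data are DCT-transformed along time, an optional
#' frequency band mask is applied, and an SVD of the pooled coefficient
#' cross-product identifies the dominant temporal modes, which are
#' back-transformed into orthonormal time-domain columns.
#'
#' Two retention rules are available.  The default, `"noise_floor"`,
#' keeps the eigenmodes that rise significantly above the flat
#' eigenvalue floor of white noise (floor estimated by the median
#' eigenvalue, significance margin from the Marchenko-Pastur spread of
#' the pooled cross-product); because the simulated signal repeats over
#' trials while the noise does not, these are the signal-dominated
#' modes, so the reduction actively removes noise -- one or two modes
#' survive at high SNR, while at very low SNR no mode clears the floor
#' and the rule falls back to the `"variance"` rule over all modes.
#' `"variance"` keeps the smallest mode count whose eigenvalue sum
#' reaches `variance_fraction` of the total.
#'
#' @param y_spatial epochs after spatial reduction: a `u x s x n_trials`
#'   array, a list of `u x s` matrices, or a single matrix.
#' @param variance_fraction cumulative eigenvalue fraction for the
#'   `"variance"` rule and the low-SNR fallback (default 0.999).
#' @param fs_hz sampling rate, required when `band` is given.
#' @param band optional `c(lo, hi)` frequency window in Hz applied in the
#'   DCT domain.
#' @param mode_rule `"noise_floor"` (default) or `"variance"`.
#' @param floor_margin significance multiplier on the Marchenko-Pastur
#'   half-width for the noise-floor rule.
#' @return an `s x nu` matrix `T` with orthonormal columns.
#' @export
temporal_projector <- function(y_spatial, variance_fraction = 0.999,
                               fs_hz = NULL, band = NULL,
                               mode_rule = c("noise_floor", "variance"),
                               floor_margin = 4) {
  mode_rule <- match.arg(mode_rule)
  trials <- as_trial_list(y_spatial)
  s <- ncol(trials[[1]])
  if (s < 2) stop_param("need at least 2 time samples")
  D <- dct_matrix(s)
  keep <- rep(TRUE, s)
  if (!is.null(band)) {
    if (is.null(fs_hz)) stop_param("band requires fs_hz")
    freqs <- (0:(s - 1)) * fs_hz / (2 * s)  # DCT bin center frequencies
    keep <- freqs >= band[1] & freqs <= band[2]
    if (!any(keep)) stop_param("empty frequency band")
  }
  cc <- matrix(0, s, s)
  n_obs <- 0
  for (y in trials) {
    z <- y %*% t(D)          # DCT along time
    z[, !keep] <- 0
    cc <- cc + crossprod(z)  # s x s coefficient cross-product
    n_obs <- n_obs + nrow(y)
  }
  e <- eigen(sym(cc), symmetric = TRUE)
  ev <- pmax(e$values, 0)
  nu_var <- {
    cum <- cumsum(ev) / sum(ev)
    n0 <- which(cum >= min(variance_fraction, 1))[1]
    if (is.na(n0)) sum(keep) else min(n0, sum(keep))
  }
  nu <- nu_var
  if (mode_rule == "noise_floor") {
    floor_est <- median(ev[ev > 1e-12 * max(ev)])
    thresh <- floor_est * (1 + floor_margin * sqrt(s / n_obs))
    n_above <- sum(ev > thresh & ev > 1e-12 * max(ev))
    if (n_above >= 1) nu <- n_above
  }
  Tm <- t(D) %*% e$vectors[, seq_len(nu), drop = FALSE]  # inverse DCT
  qr.Q(qr(Tm))[, seq_len(nu), drop = FALSE]
}

as_trial_list <- function(y) {
  if (is.list(y)) return(y)
  if (is.matrix(y)) return(list(y))
  if (is.array(y) && length(dim(y)) == 3) {
    return(lapply(seq_len(dim(y)[3]), function(t) y[, , t]))
  }
  stop_param("epochs must be a matrix, list of matrices, or 3-d array")
}

#' Project data and leadfields into the reduced model
#'
#' Applies the spatial projector `U` and temporal projector `T` to every
#' epoch and to the leadfield, and forms the trial-averaged reduced data
#' covariance `mean_t( Y_t Y_t^T ) / nu`.
#'
#' @param B sensor epochs: `n_sensors x s x n_trials` array (or list or
#'   single matrix).
#' @param U spatial projector (`u x n_sensors`).
#' @param Tm temporal projector (`s x nu`).
#' @param L a `leadfield` or gain matrix.
#' @return a `reduced_model` with `U`, `T`, `L_reduced`, `Y_reduced`
#'   (`u x nu x n_trials`), `u`, `nu`, `n_trials` and `sample_cov`.
#' @export
reduce_model <- function(B, U, Tm, L) {
  gain <- if (inherits(L, "leadfield")) L$gain else L
  trials <- as_trial_list(B)
  if (ncol(U) != nrow(trials[[1]])) stop_param("U and epochs disagree on sensor count")
  if (nrow(Tm) != ncol(trials[[1]])) stop_param("T and epochs disagree on sample count")
  if (ncol(U) != nrow(gain)) stop_param("U and leadfield disagree on sensor count")
  u <- nrow(U)
  nu <- ncol(Tm)
  nt <- length(trials)
  Y <- array(0, c(u, nu, nt))
  cov <- matrix(0, u, u)
  for (t in seq_len(nt)) {
    yt <- U %*% trials[[t]] %*% Tm
    Y[, , t] <- yt
    cov <- cov + tcrossprod(yt)
  }
  cov <- cov / (nt * nu)
  structure(list(
    U = U, T = Tm,
    L_reduced = U %*% gain,
    Y_reduced = Y,
    u = u, nu = nu, n_trials = nt,
    sample_cov = sym(cov)
  ), class = "reduced_model")
}

#' @export
print.reduced_model <- function(x, ...) {
  cat(sprintf("reduced_model: u = %d spatial modes, nu = %d temporal modes, %d trials\n",
              x$u, x$nu, x$n_trials))
  invisible(x)
}

#' One-call reduction of raw epochs
#'
#' Convenience wrapper chaining [spatial_projector()],
#' [temporal_projector()] and [reduce_model()].
#'
#' By default the temporal projector is estimated from the trial-averaged
#' (evoked) data: for epoched studies whose signal repeats over trials,
#' averaging attenuates the noise before the signal subspace is
#' identified, so the retained temporal modes stay signal-dominated far
#' into the noise.  Set `temporal_from = "trials"` to pool the
#' per-trial cross-products instead (appropriate for induced,
#' non-phase-locked activity).
#'
#' @inheritParams reduce_model
#' @inheritParams temporal_projector
#' @param rel_eigen_tol spatial eigenvalue cutoff.
#' @param temporal_from estimate the temporal modes from the `"evoked"`
#'   average (default) or from the pooled `"trials"`.
#' @export
reduce_epochs <- function(B, L, rel_eigen_tol = exp(-16),
                          variance_fraction = 0.999, fs_hz = NULL, band = NULL,
                          mode_rule = c("noise_floor", "variance"),
                          floor_margin = 4,
                          temporal_from = c("evoked", "trials")) {
  temporal_from <- match.arg(temporal_from)
  gain <- if (inherits(L, "leadfield")) L$gain else L
  U <- spatial_projector(gain, rel_eigen_tol)
  trials <- as_trial_list(B)
  yspat <- lapply(trials, function(b) U %*% b)
  tin <- if (temporal_from == "evoked" && length(yspat) > 1) {
    list(Reduce(`+`, yspat) / length(yspat))
  } else yspat
  Tm <- temporal_projector(tin, variance_fraction, fs_hz, band,
                           mode_rule = mode_rule, floor_margin = floor_margin)
  reduce_model(trials, U, Tm, gain)
}
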