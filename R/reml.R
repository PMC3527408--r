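#' Hyperpriors on log-scale hyperparameters
#'
#' Gaussian prior on each log-scale hyperparameter `lambda_i` with mean
#' `eta` and precision `pi`.  The defaults (`eta = -32`,
#' `pi = 1/256`) are weakly informative: scale parameters
#' `exp(lambda)` start around zero and are allowed to vary over many
#' orders of magnitude.
#'
#' @param eta prior mean of each log-scale hyperparameter.
#' @param pi prior precision of each (must be > 0).
#' @export
hyperprior <- function(eta = -32, pi = 1 / 256) {
  if (any(pi <= 0)) stop_param("hyperprior precision pi must be positive")
  structure(list(eta = eta, pi = pi), class = "hyperprior")
}

LAMBDA_CLIP <- 64  # |lambda| cap: exp(lambda) in [exp(-64), exp(64)]

# Internal: dense u x u projections/factors for a component list.
# Returns list(Fall, fmap, dense, dmap, u) where Fall concatenates the
# rank factors (P = F F^T) and dense holds full matrices.
split_components <- function(components, u) {
  Fall <- NULL
  fmap <- list()
  dense <- list()
  dmap <- integer(0)
  fcols <- list()
  for (i in seq_along(components)) {
    cm <- components[[i]]
    if (!is.null(cm$sensor_factor)) {
      fcols[[length(fcols) + 1]] <- list(i = i, f = cm$sensor_factor)
    } else {
      P <- if (!is.null(cm$sensor_projection)) cm$sensor_projection
      else if (cm$kind == "sensor_noise") diag(u)
      else stop_param("component '%s' has no sensor-level form; call attach_sensor_projections()",
                      cm$label)
      dense[[length(dense) + 1]] <- P
      dmap <- c(dmap, i)
    }
  }
  if (length(fcols)) {
    Fall <- do.call(cbind, lapply(fcols, `[[`, "f"))
    at <- 0L
    for (k in seq_along(fcols)) {
      nc <- ncol(fcols[[k]]$f)
      fmap[[k]] <- list(i = fcols[[k]]$i, cols = at + seq_len(nc))
      at <- at + nc
    }
  }
  list(Fall = Fall, fmap = fmap, dense = dense, dmap = dmap, u = u)
}

# Compose C = sum_i exp(lambda_i) P_i from the split representation.
compose_from_split <- function(sp, lambda) {
  u <- sp$u
  C <- matrix(0, u, u)
  if (!is.null(sp$Fall)) {
    w <- rep(0, ncol(sp$Fall))
    for (fm in sp$fmap) w[fm$cols] <- exp(lambda[fm$i])
    C <- C + sp$Fall %*% (w * t(sp$Fall))
  }
  for (k in seq_along(sp$dense)) {
    C <- C + exp(lambda[sp$dmap[k]]) * sp$dense[[k]]
  }
  sym(C)
}

#' Compose the model covariance from components
#'
#' `C = sum_i exp(lambda_i) P_i`, where `P_i` are the sensor-level
#' projections of the components (the sensor-noise component contributes
#' `exp(lambda_0) I`).
#'
#' @param components list of components (sensor-level forms attached) or
#'   a `prior_library`.
#' @param lambda numeric vector of log-scale hyperparameters, one per
#'   component.
#' @param u reduced sensor dimension (needed only when it cannot be
#'   inferred from the components).
#' @return a symmetric positive semi-definite `u x u` matrix.
#' @export
compose_covariance <- function(components, lambda, u = NULL) {
  comps <- if (inherits(components, "prior_library")) components$components else components
  if (length(comps) != length(lambda)) stop_param("lambda length must match component count")
  if (any(lambda > 700)) {
    warning("lambda > 700 clipped to avoid exp overflow")
    lambda <- pmin(lambda, 700)
  }
  if (is.null(u)) u <- infer_u(comps)
  compose_from_split(split_components(comps, u), lambda)
}

infer_u <- function(comps) {
  for (cm in comps) {
    if (!is.null(cm$sensor_factor)) return(nrow(cm$sensor_factor))
    if (!is.null(cm$sensor_projection)) return(nrow(cm$sensor_projection))
  }
  stop_param("cannot infer sensor dimension; attach sensor projections first")
}

# Robust inverse via Cholesky with escalating jitter.
chol_inv <- function(C) {
  u <- nrow(C)
  jit <- 0
  base <- mean(diag(C))
  if (!is.finite(base) || base <= 0) base <- 1
  for (k in 0:6) {
    R <- tryCatch(chol(C + diag(jit, u)), error = function(e) NULL)
    if (!is.null(R)) {
      return(list(inv = chol2inv(R), logdet = 2 * sum(log(diag(R))) ))
    }
    jit <- if (jit == 0) base * 1e-12 else jit * 100
  }
  stop_param("covariance matrix is numerically singular")
}

#' Laplace free energy of a covariance-component model
#'
#' The variational lower bound on the log evidence of the reduced data
#' under the composed covariance: an accuracy term
#' `-nu/2 tr(C^-1 S)`, an amplitude term `-nu/2 log|C|`, the
#' normalization constant `-u nu/2 log(2 pi)`, and two complexity terms
#' comparing the hyperparameter posterior `(lambda, Sigma_lambda)` with
#' its Gaussian hyperprior.
#'
#' @param sample_cov reduced data covariance `S` (`u x u`).
#' @param nu effective number of (reduced) samples.
#' @param u reduced sensor dimension.
#' @param components component list (sensor forms attached) or
#'   `prior_library`.
#' @param lambda hyperparameter vector.
#' @param lambda_cov posterior covariance `Sigma_lambda` of the
#'   hyperparameters.
#' @param hp a [hyperprior()].
#' @return scalar free energy `F`.
#' @export
free_energy <- function(sample_cov, nu, u, components, lambda, lambda_cov,
                        hp = hyperprior()) {
  comps <- if (inherits(components, "prior_library")) components$components else components
  sp <- split_components(comps, u)
  C <- compose_from_split(sp, lambda)
  ci <- chol_inv(C)
  free_energy_terms(sample_cov, nu, u, ci, lambda, lambda_cov, hp)$F
}

free_energy_terms <- function(S, nu, u, ci, lambda, lambda_cov, hp) {
  n <- length(lambda)
  eta <- rep(hp$eta, length.out = n)
  piv <- rep(hp$pi, length.out = n)
  accuracy <- -nu / 2 * sum(ci$inv * S)
  amplitude <- -nu / 2 * ci$logdet
  constant <- -u * nu / 2 * log(2 * pi)
  divergence <- -0.5 * sum(piv * (lambda - eta)^2)
  ld <- determinant(lambda_cov %*% diag(piv, n), logarithm = TRUE)
  laplace <- 0.5 * as.numeric(ld$modulus)
  F <- accuracy + amplitude + constant + divergence + laplace
  list(F = F, accuracy = accuracy, amplitude = amplitude,
       constant = constant, divergence = divergence, laplace = laplace)
}

# Gradient and expected information of the penalized log-likelihood.
reml_derivatives <- function(sp, S, nu, lambda, eta, piv, Cinv) {
  n <- length(lambda)
  E <- S - compose_from_split(sp, lambda)
  grad <- numeric(n)
  Tr <- matrix(0, n, n)  # tr(Cinv P_i Cinv P_j)
  Fc <- NULL
  if (!is.null(sp$Fall)) {
    Fc <- Cinv %*% sp$Fall
    # gradients for factored components
    W <- E %*% Fc
    gcol <- colSums(Fc * W)
    K <- crossprod(sp$Fall, Fc)       # F^T Cinv F
    K2 <- K^2
    nf <- length(sp$fmap)
    agg <- matrix(0, ncol(sp$Fall), nf)
    fidx <- integer(nf)
    for (k in seq_len(nf)) {
      agg[sp$fmap[[k]]$cols, k] <- 1
      fidx[k] <- sp$fmap[[k]]$i
      grad[sp$fmap[[k]]$i] <- sum(gcol[sp$fmap[[k]]$cols])
    }
    Tr[fidx, fidx] <- crossprod(agg, K2 %*% agg)
  }
  if (length(sp$dense)) {
    CE <- Cinv %*% E
    Alist <- lapply(sp$dense, function(P) Cinv %*% P)
    for (k in seq_along(sp$dense)) {
      i <- sp$dmap[k]
      grad[i] <- sum(Alist[[k]] * t(CE))
      for (l in seq_len(k)) {
        j <- sp$dmap[l]
        Tr[i, j] <- Tr[j, i] <- sum(Alist[[k]] * t(Alist[[l]]))
      }
      if (!is.null(Fc)) {
        vals <- colSums(Fc * (sp$dense[[k]] %*% Fc))
        for (fm in sp$fmap) {
          Tr[i, fm$i] <- Tr[fm$i, i] <- sum(vals[fm$cols])
        }
      }
    }
  }
  el <- exp(lambda)
  grad <- nu / 2 * el * grad - piv * (lambda - eta)
  H <- nu / 2 * outer(el, el) * Tr + diag(piv, n)
  list(grad = grad, H = H)
}

#' Restricted maximum likelihood over covariance components
#'
#' Estimates the log-scale hyperparameters of
#' `C = sum_i exp(lambda_i) P_i` from a reduced sample covariance by
#' Fisher-scoring ReML under Gaussian hyperpriors, with Levenberg-style
#' damping when the expected information is ill-conditioned.  The
#' objective is the Laplace free energy; its per-iteration trace is
#' returned and is non-decreasing up to the convergence tolerance.
#'
#' @param sample_cov reduced data covariance (`u x u`, PSD).
#' @param nu effective number of reduced samples (temporal modes times
#'   trials when the covariance is trial-averaged).
#' @param components list of components or `prior_library`, sensor-level
#'   forms attached; must contain exactly one `sensor_noise` component.
#' @param hp a [hyperprior()].
#' @param max_iter maximum Fisher-scoring iterations.
#' @param tol absolute free-energy increase below which iteration stops.
#' @param lambda_init optional starting hyperparameters (defaults to a
#'   trace-matching heuristic).
#' @return a `reml_result`: `lambda_mean`, `lambda_cov`, `F_trace`,
#'   `F` (final), `C_est`, `converged`, `n_iter`.
#' @export
reml <- function(sample_cov, nu, components, hp = hyperprior(),
                 max_iter = 512L, tol = 1e-2, lambda_init = NULL) {
  comps <- if (inherits(components, "prior_library")) components$components else components
  if (nu < 1) stop_param("nu must be >= 1")
  ev_min <- min(eigen(sym(sample_cov), symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * max(1, sum(diag(sample_cov)))) {
    stop_param("sample covariance is not positive semi-definite")
  }
  n_noise <- sum(vapply(comps, function(cm) cm$kind == "sensor_noise", logical(1)))
  if (n_noise != 1L) stop_param("components must include exactly one sensor_noise component")
  if (length(comps) < 2L) stop_param("need at least one signal component plus noise")
  u <- nrow(sample_cov)
  sp <- split_components(comps, u)
  n <- length(comps)
  eta <- rep(hp$eta, length.out = n)
  piv <- rep(hp$pi, length.out = n)

  lambda <- if (!is.null(lambda_init)) rep(lambda_init, length.out = n) else {
    trS <- sum(diag(sample_cov))
    vapply(seq_len(n), function(i) {
      trP <- component_trace(sp, i)
      if (trS > 0 && trP > 0) log(trS / (n * trP)) else eta[i]
    }, numeric(1))
  }
  lambda <- pmin(pmax(lambda, -LAMBDA_CLIP), LAMBDA_CLIP)

  eval_state <- function(lam) {
    C <- compose_from_split(sp, lam)
    ci <- chol_inv(C)
    d <- reml_derivatives(sp, sample_cov, nu, lam, eta, piv, ci$inv)
    Sig <- solve_psd(d$H)
    Fv <- free_energy_terms(sample_cov, nu, u, ci, lam, Sig, hp)$F
    list(lambda = lam, C = C, ci = ci, grad = d$grad, H = d$H, Sig = Sig, F = Fv)
  }

  st <- eval_state(lambda)
  F_trace <- st$F
  damping <- 1e-8
  converged <- FALSE
  n_iter <- 0L
  fails <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    accepted <- FALSE
    for (try in 1:12) {
      Hd <- st$H + diag(damping * pmax(diag(st$H), 1e-12), n)
      step <- tryCatch(solve(Hd, st$grad), error = function(e) NULL)
      if (is.null(step)) { damping <- damping * 10; next }
      # cap wild steps so exp() stays sane
      smax <- max(abs(step))
      if (smax > 8) step <- step * (8 / smax)
      cand <- pmin(pmax(st$lambda + step, -LAMBDA_CLIP), LAMBDA_CLIP)
      st_new <- tryCatch(eval_state(cand), error = function(e) NULL)
      if (!is.null(st_new) && is.finite(st_new$F) &&
          st_new$F >= st$F - 1e-6 * abs(st$F)) {
        dF <- st_new$F - st$F
        st <- st_new
        damping <- max(damping / 10, 1e-10)
        accepted <- TRUE
        break
      }
      damping <- damping * 10
    }
    if (!accepted) {
      fails <- fails + 1L
      if (fails >= 3L) break
      next
    }
    F_trace <- c(F_trace, st$F)
    if (length(F_trace) > 1 && abs(dF) < tol) { converged <- TRUE; break }
  }
  structure(list(
    lambda_mean = st$lambda,
    lambda_cov = st$Sig,
    F_trace = F_trace,
    F = st$F,
    C_est = st$C,
    converged = converged,
    n_iter = n_iter
  ), class = "reml_result")
}

component_trace <- function(sp, i) {
  for (fm in sp$fmap) {
    if (fm$i == i) return(sum(sp$Fall[, fm$cols]^2))
  }
  k <- match(i, sp$dmap)
  if (!is.na(k)) return(sum(diag(sp$dense[[k]])))
  0
}

solve_psd <- function(H) {
  out <- tryCatch(chol2inv(chol(sym(H))), error = function(e) NULL)
  if (is.null(out)) {
    e <- eigen(sym(H), symmetric = TRUE)
    vals <- pmax(e$values, max(e$values) * 1e-12)
    out <- e$vectors %*% (t(e$vectors) / vals)
  }
  sym(out)
}

#' @export
print.reml_result <- function(x, ...) {
  cat(sprintf("reml_result: %d hyperparameters, F = %.3f, %s in %d iterations\n",
              length(x$lambda_mean), x$F,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Write a ReML iteration trace as TSV
#'
#' @param result a `reml_result`.
#' @param path output path.
#' @export
write_reml_trace <- function(result, path) {
  df <- data.frame(iteration = seq_along(result$F_trace) - 1L,
                   F = result$F_trace)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- MAP extraction -------------------------------------------------------

#' Maximum a posteriori source extractor
#'
#' Builds the matrix `M` mapping reduced sensor data to posterior-mean
#' source estimates: `M = Q L^T (L Q L^T + exp(lambda_0) I)^-1`, where
#' `Q = sum exp(lambda_i) Q_i` is the composed source covariance of the
#' signal components (held in factored/diagonal form) and `lambda_0` is
#' the sensor-noise hyperparameter.
#'
#' @param components component list or `prior_library` (source-level
#'   forms present; must include the sensor-noise component).
#' @param lambda hyperparameter vector matching `components`.
#' @param L_reduced reduced leadfield (`u x v`).
#' @return a `map_extractor` with `M` (`v x u`) and the source
#'   covariance in factored form.
#' @export
map_extractor <- function(components, lambda, L_reduced) {
  comps <- if (inherits(components, "prior_library")) components$components else components
  if (length(comps) != length(lambda)) stop_param("lambda length must match component count")
  v <- ncol(L_reduced)
  u <- nrow(L_reduced)
  d <- rep(0, v)
  Wcols <- list()
  wts <- numeric(0)
  noise_var <- NA_real_
  for (i in seq_along(comps)) {
    cm <- comps[[i]]
    w <- exp(min(lambda[i], 700))
    if (cm$kind == "sensor_noise") {
      noise_var <- w
    } else if (!is.null(cm$source_diag)) {
      d <- d + w * cm$source_diag
    } else if (!is.null(cm$source_factor)) {
      Wcols[[length(Wcols) + 1]] <- cm$source_factor
      wts <- c(wts, rep(w, ncol(cm$source_factor)))
    }
  }
  if (is.na(noise_var)) stop_param("components must include the sensor_noise component")
  if (all(d == 0) && !length(Wcols)) stop_param("composed source covariance is zero")
  QLt <- d * t(L_reduced)                          # v x u
  W <- NULL
  if (length(Wcols)) {
    W <- do.call(cbind, Wcols)
    WtLt <- Matrix::crossprod(W, t(L_reduced))     # m x u
    QLt <- QLt + as.matrix(W %*% (wts * WtLt))
  }
  B <- L_reduced %*% QLt + diag(noise_var, u)
  M <- t(solve(sym(B), t(QLt)))
  if (!all(is.finite(M))) stop_param("MAP extractor is not finite")
  structure(list(M = M, source_diag = d, source_factor = W,
                 factor_weights = wts, noise_var = noise_var),
            class = "map_extractor")
}

#' @export
print.map_extractor <- function(x, ...) {
  cat(sprintf("map_extractor: %d sources x %d sensor modes\n", nrow(x$M), ncol(x$M)))
  invisible(x)
}

#' Extract source time courses
#'
#' @param extractor a `map_extractor`.
#' @param Y reduced data (`u x nu` matrix or `u x nu x trials` array).
#' @return source estimates with matching trailing dimensions.
#' @export
extract_sources <- function(extractor, Y) {
  if (is.matrix(Y)) return(extractor$M %*% Y)
  if (is.array(Y) && length(dim(Y)) == 3) {
    out <- array(0, c(nrow(extractor$M), dim(Y)[2], dim(Y)[3]))
    for (t in seq_len(dim(Y)[3])) out[, , t] <- extractor$M %*% Y[, , t]
    return(out)
  }
  stop_param("Y must be a matrix or 3-d array")
}
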