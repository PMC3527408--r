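#' Covariance-component priors
#'
#' Every inversion scheme is defined by the source-covariance components
#' it brings to the common ReML stage.  A component is a fixed symmetric
#' positive semi-definite source-level matrix `Q`, stored in factored or
#' diagonal form; its sensor-level projection `P = L Q L^T` is what ReML
#' actually weights.  Kinds: `global_identity` (minimum norm),
#' `global_ebb` (beamformer variance map), `patch` / `bilateral_patch`
#' (multiple sparse priors), and `sensor_noise` (identity at sensor
#' level).
#'
#' @name covariance-components
NULL

new_component <- function(kind, label, source_diag = NULL, source_factor = NULL) {
  structure(list(kind = kind, label = label,
                 source_diag = source_diag,
                 source_factor = source_factor,
                 sensor_factor = NULL, sensor_projection = NULL),
            class = "covariance_component")
}

#' @export
print.covariance_component <- function(x, ...) {
  cat(sprintf("covariance_component <%s> '%s'\n", x$kind, x$label))
  invisible(x)
}

#' Minimum-norm source prior
#'
#' The identity source covariance: all sources a priori equiprobable and
#' mutually uncorrelated.
#'
#' @param v number of source vertices.
#' @return a `global_identity` covariance component.
#' @export
mnm_prior <- function(v) {
  check_scalar(v, "v", lower = 1)
  new_component("global_identity", "mnm", source_diag = rep(1, v))
}

#' Sensor noise component
#'
#' White sensor noise projected through the (orthonormal) spatial modes:
#' the identity in reduced sensor space.
#' @export
sensor_noise_prior <- function() {
  new_component("sensor_noise", "noise")
}

#' Empirical Bayesian beamformer prior
#'
#' Per-vertex LCMV source-power estimates
#' `sigma^2(theta) = (l^T C^-1 l)^-1` computed from the reduced data
#' covariance `C` and reduced leadfield columns `l`, assembled into a
#' diagonal source covariance (no source correlations assumed).  The
#' covariance inverse is stabilized with a small ridge because the
#' reduced covariance built from few temporal modes can be rank
#' deficient.
#'
#' @param model a `reduced_model`.
#' @param ridge relative ridge loading on `C` (fraction of
#'   `trace(C)/u`, default `1e-8`).
#' @param normalize_leadfield if `TRUE`, unit-norm leadfield columns are
#'   used (depth-bias variant); default `FALSE`.
#' @return a `global_ebb` covariance component (sensor projection cached).
#' @export
ebb_prior <- function(model, ridge = 1e-8, normalize_leadfield = FALSE) {
  stopifnot(inherits(model, "reduced_model"))
  C <- model$sample_cov
  u <- nrow(C)
  load <- ridge * sum(diag(C)) / u
  Ci <- tryCatch(chol2inv(chol(C + diag(load, u))),
                 error = function(e) stop_param("reduced covariance is singular even after ridge loading"))
  L <- model$L_reduced
  if (normalize_leadfield) L <- sweep(L, 2, pmax(sqrt(colSums(L^2)), .Machine$double.eps), "/")
  denom <- colSums(L * (Ci %*% L))
  if (any(denom <= 0)) stop_param("non-positive beamformer denominator; covariance not PD")
  sig2 <- 1 / denom
  comp <- new_component("global_ebb", "ebb", source_diag = sig2)
  comp$sensor_projection <- sym(model$L_reduced %*% (sig2 * t(model$L_reduced)))
  comp
}

#' Multiple-sparse-priors patch library
#'
#' One `patch` component per patch center (its source profile is the
#' Green-smoother column at the center, so `Q_i = q_i q_i^T`), and
#' optionally one `bilateral_patch` component per left-hemisphere center
#' pairing it with its contralateral mirror partner
#' (`Q = (q + q_mirror)(q + q_mirror)^T`), accommodating correlated
#' symmetric sources.
#'
#' @param G a `green_smoother`.
#' @param centers a `patch_centers` object (both hemispheres).
#' @param include_bilateral add the `p` bilateral components?
#' @return a `prior_library` with `2p` components (`3p` when bilateral
#'   components are included).
#' @export
msp_library <- function(G, centers, include_bilateral = FALSE) {
  stopifnot(inherits(G, "green_smoother"), inherits(centers, "patch_centers"))
  if (!all(c("left", "right") %in% centers$hemisphere)) {
    stop_param("patch centers must cover both hemispheres")
  }
  comps <- lapply(seq_along(centers$vertices), function(i) {
    ctr <- centers$vertices[i]
    q <- G$G[, ctr, drop = FALSE]
    c0 <- new_component("patch", sprintf("patch_%d", ctr), source_factor = q)
    c0$center <- ctr
    c0$hemisphere <- centers$hemisphere[i]
    c0
  })
  if (include_bilateral) {
    if (is.null(centers$pair)) {
      stop_param("centers carry no contralateral pairing; cannot build bilateral priors")
    }
    bi <- lapply(seq_len(nrow(centers$pair)), function(i) {
      lft <- centers$pair[i, 1]
      rgt <- centers$pair[i, 2]
      if (is.na(rgt)) stop_param("no contralateral partner for center %d", lft)
      q <- G$G[, lft, drop = FALSE] + G$G[, rgt, drop = FALSE]
      c0 <- new_component("bilateral_patch", sprintf("bilateral_%d_%d", lft, rgt),
                          source_factor = q)
      c0$center <- c(lft, rgt)
      c0$hemisphere <- "both"
      c0
    })
    comps <- c(comps, bi)
  }
  structure(list(components = comps,
                 includes_bilateral = include_bilateral,
                 p_per_hemisphere = centers$p_per_hemisphere,
                 centers = centers),
            class = "prior_library")
}

#' @export
print.prior_library <- function(x, ...) {
  cat(sprintf("prior_library: %d components (p = %d per hemisphere%s)\n",
              length(x$components), x$p_per_hemisphere,
              if (x$includes_bilateral) ", with bilateral priors" else ""))
  invisible(x)
}

#' @export
length.prior_library <- function(x) length(x$components)

# ---- sensor-level projections --------------------------------------------

#' Sensor-level projection of a component
#'
#' Returns the dense `u x u` matrix `P = L Q L^T` for a component (the
#' identity for the sensor-noise component).  Projections are cached on
#' the component by [attach_sensor_projections()].
#'
#' @param comp a `covariance_component`.
#' @param L_reduced reduced leadfield (`u x v`); optional when a cached
#'   projection exists.
#' @export
sensor_projection <- function(comp, L_reduced = NULL) {
  if (!is.null(comp$sensor_projection)) return(comp$sensor_projection)
  if (!is.null(comp$sensor_factor)) return(sym(tcrossprod(comp$sensor_factor)))
  if (comp$kind == "sensor_noise") {
    if (is.null(L_reduced)) stop_param("need L_reduced (for u) to build the noise projection")
    return(diag(nrow(L_reduced)))
  }
  if (is.null(L_reduced)) stop_param("no cached projection; supply L_reduced")
  cm <- attach_sensor_projections(list(comp), L_reduced)[[1]]
  if (!is.null(cm$sensor_projection)) cm$sensor_projection else sym(tcrossprod(cm$sensor_factor))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cache sensor-level forms on a set of components
#'
#' Rank-limited components (patches) get a sensor factor `f = L q`;
#' global diagonal components get the dense projection
#' `L diag(d) L^T`; the noise component gets the identity.
#'
#' @param components a list of components or a `prior_library`.
#' @param L_reduced reduced leadfield (`u x v`).
#' @return the input with sensor-level forms attached.
#' @export
attach_sensor_projections <- function(components, L_reduced) {
  lib <- inherits(components, "prior_library")
  comps <- if (lib) components$components else components
  u <- nrow(L_reduced)
  out <- lapply(comps, function(cm) {
    if (!is.null(cm$sensor_factor) || !is.null(cm$sensor_projection)) {
      # already in sensor space
    } else if (!is.null(cm$source_factor)) {
      cm$sensor_factor <- as.matrix(L_reduced %*% cm$source_factor)
    } else if (cm$kind == "sensor_noise") {
      cm$sensor_projection <- diag(u)
    } else if (!is.null(cm$source_diag)) {
      if (is.null(cm$sensor_projection)) {
        cm$sensor_projection <- sym(L_reduced %*% (cm$source_diag * t(L_reduced)))
      }
    } else {
      stop_param("component '%s' has no source-level form", cm$label)
    }
    cm
  })
  if (lib) {
    components$components <- out
    components
  } else out
}
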