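#' Inversion schemes
#'
#' Four source-reconstruction schemes share one pipeline: build a prior
#' (or prior library), weight it by ReML against the free energy, and run
#' a common final two-hyperparameter inversion (synthesized source prior
#' + sensor noise) whose free energy is comparable across schemes.
#' `MNM` and `EBB` use a single global prior; `ARD` weights and prunes
#' every patch component; `GS` greedily evaluates shrinking sets of
#' patches.
#'
#' @name inversion-schemes
NULL

nu_effective <- function(model) model$nu * model$n_trials

# All hyperparameter estimation happens on data rescaled to unit mean
# power, so hyperparameters live in a sane range regardless of the
# user's field units; the MAP extractor is invariant to this scaling.
model_scale <- function(model) {
  sc <- sqrt(mean(diag(model$sample_cov)))
  if (!is.finite(sc) || sc <= 0) sc <- 1
  sc
}

#' Common final inversion
#'
#' A fresh two-hyperparameter ReML (synthesized source prior + sensor
#' noise) followed by MAP extraction.  This step is identical for every
#' scheme, so the resulting free energies are directly comparable; it is
#' also invariant to a positive rescaling of the synthesized prior
#' (absorbed by its hyperparameter).
#'
#' @param model a `reduced_model`.
#' @param synthesized_prior a source-level `covariance_component`.
#' @param hp hyperprior for the final ReML.
#' @param max_iter,tol ReML controls.
#' @return list with `extractor` (a `map_extractor`), `F` (comparable
#'   free energy), `reml` (the final `reml_result`) and `lambda`.
#' @export
final_inversion <- function(model, synthesized_prior, hp = hyperprior(),
                            max_iter = 512L, tol = 1e-2) {
  stopifnot(inherits(model, "reduced_model"))
  sc <- model_scale(model)
  S <- model$sample_cov / sc^2
  comps <- attach_sensor_projections(list(synthesized_prior, sensor_noise_prior()),
                                     model$L_reduced)
  # normalize the synthesized prior to noise trace: any positive rescaling
  # of the prior is removed here, so the final free energy is invariant
  comps[[1]] <- normalize_component_trace(comps[[1]], nrow(S))
  fit <- reml(S, nu_effective(model), comps, hp = hp,
              max_iter = max_iter, tol = tol)
  ex <- map_extractor(comps, fit$lambda_mean, model$L_reduced)
  list(extractor = ex, F = fit$F, reml = fit, lambda = fit$lambda_mean)
}

build_inversion_result <- function(scheme, model, fin, active, diagnostics) {
  M <- fin$extractor$M
  nt <- model$n_trials
  v <- nrow(M)
  image_trials <- matrix(0, v, nt)
  for (t in seq_len(nt)) {
    st <- M %*% model$Y_reduced[, , t]
    image_trials[, t] <- rowSums(st^2) / model$nu
  }
  Ymean <- apply(model$Y_reduced, c(1, 2), mean)
  structure(list(
    scheme = scheme,
    image = rowMeans(image_trials),
    image_trials = image_trials,
    timecourses = M %*% Ymean,
    F_final = fin$F,
    active_components = active,
    extractor = fin$extractor,
    lambda_final = fin$lambda,
    diagnostics = diagnostics
  ), class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf("inversion_result <%s>: %d vertices, F = %.2f, %d active components\n",
              x$scheme, length(x$image), x$F_final, length(x$active_components)))
  invisible(x)
}

#' Single-global-prior inversion (MNM, EBB)
#'
#' For the minimum-norm and beamformer schemes the prior-weighting stage
#' and the common final stage coincide: one ReML with two hyperparameters
#' (global source prior + noise).
#'
#' @param model a `reduced_model`.
#' @param prior a `global_identity` or `global_ebb` component.
#' @param hp,max_iter,tol ReML controls.
#' @return an `inversion_result`.
#' @export
invert_single_prior <- function(model, prior, hp = hyperprior(),
                                max_iter = 512L, tol = 1e-2) {
  if (!prior$kind %in% c("global_identity", "global_ebb")) {
    stop_param("single-prior inversion requires a global prior, got '%s'", prior$kind)
  }
  scheme <- if (prior$kind == "global_identity") "MNM" else "EBB"
  fin <- final_inversion(model, prior, hp, max_iter, tol)
  build_inversion_result(scheme, model, fin, active = prior$label,
                         diagnostics = list(n_iter = fin$reml$n_iter,
                                            F_trace = fin$reml$F_trace,
                                            n_hyperparameters = length(fin$lambda)))
}

#' Automatic relevance determination over a patch library
#'
#' One ReML run with a hyperparameter per patch component; components
#' whose scale parameter collapses towards the prior expectation
#' (`lambda < eta + prune_offset`) are pruned, and the surviving weighted
#' mixture forms the synthesized prior for the common final inversion.
#'
#' @param model a `reduced_model`.
#' @param library a `prior_library`.
#' @param hp hyperprior.
#' @param prune_offset pruning threshold above the prior mean `eta`
#'   (default 2: prune when `exp(lambda) < exp(eta + 2)`).
#' @param max_iter,tol ReML controls.
#' @return an `inversion_result`.
#' @export
invert_ard <- function(model, library, hp = hyperprior(), prune_offset = 2,
                       max_iter = 512L, tol = 1e-2) {
  stopifnot(inherits(library, "prior_library"))
  if (!length(library$components)) stop_param("empty prior library")
  sc <- model_scale(model)
  S <- model$sample_cov / sc^2
  lib <- attach_sensor_projections(library, model$L_reduced)
  comps <- c(lib$components, list(sensor_noise_prior()))
  fit <- reml(S, nu_effective(model), comps, hp = hp,
              max_iter = max_iter, tol = tol)
  nsig <- length(lib$components)
  lam <- fit$lambda_mean[seq_len(nsig)]
  thresh <- rep(hp$eta, length.out = nsig) + prune_offset
  active <- which(lam >= thresh)
  if (!length(active)) active <- which.max(lam)  # never an empty active set
  syn <- synthesize_patch_prior(lib$components[active], lam[active])
  fin <- final_inversion(model, syn, hp, max_iter, tol)
  labels <- vapply(lib$components[active], `[[`, "", "label")
  build_inversion_result("ARD", model, fin, active = labels,
                         diagnostics = list(
                           n_iter = fit$n_iter,
                           F_trace = fit$F_trace,
                           converged = fit$converged,
                           n_pruned = nsig - length(active),
                           lambda_library = fit$lambda_mean,
                           n_hyperparameters = nsig + 1L))
}

# Rescale a component so its sensor projection has trace u (the noise
# component's trace), keeping source- and sensor-level forms consistent.
normalize_component_trace <- function(cm, u) {
  tr <- if (!is.null(cm$sensor_factor)) sum(cm$sensor_factor^2)
  else sum(diag(cm$sensor_projection))
  if (!is.finite(tr) || tr <= 0) stop_param("synthesized prior has zero sensor trace")
  f <- u / tr
  if (!is.null(cm$sensor_factor)) cm$sensor_factor <- cm$sensor_factor * sqrt(f)
  if (!is.null(cm$sensor_projection)) cm$sensor_projection <- cm$sensor_projection * f
  if (!is.null(cm$source_factor)) cm$source_factor <- cm$source_factor * sqrt(f)
  if (!is.null(cm$source_diag)) cm$source_diag <- cm$source_diag * f
  cm
}

# Weighted mixture of patch components as a single source-level prior:
# Q = sum_i w_i q_i q_i^T, stored as a factor with sqrt(w)-scaled columns.
synthesize_patch_prior <- function(components, lambda) {
  cols <- lapply(seq_along(components), function(k) {
    components[[k]]$source_factor * sqrt(exp(min(lambda[k], 700)))
  })
  W <- do.call(cbind, cols)
  cmp <- new_component("patch", "synthesized", source_factor = W)
  cmp
}

#' Greedy search over sets of patch priors
#'
#' Iteratively evaluates a small pool of candidate patch sets, each set a
#' single covariance component with one hyperparameter.  The pool starts
#' from the set of all patches; after each ReML pass an internal E-step
#' ranks the patches of the newest set by reconstructed source power and
#' its top half becomes a new candidate set.  Unsupported sets are
#' dropped (pool capped at `max_pool`), and the search stops when the
#' free energy stops increasing or the newest set has a single patch.
#'
#' @param model a `reduced_model`.
#' @param library a `prior_library`.
#' @param hp hyperprior.
#' @param prune_offset dropping threshold above `eta` for set
#'   hyperparameters.
#' @param max_pool maximum number of candidate sets kept (default 8).
#' @param max_outer maximum outer iterations.
#' @param max_iter,tol inner ReML controls; `tol` also defines the
#'   "F stopped increasing" rule (two consecutive outer gains below it).
#' @return an `inversion_result`.
#' @export
invert_gs <- function(model, library, hp = hyperprior(), prune_offset = 2,
                      max_pool = 8L, max_outer = 24L,
                      max_iter = 512L, tol = 1e-2) {
  stopifnot(inherits(library, "prior_library"))
  if (!length(library$components)) stop_param("empty prior library")
  sc <- model_scale(model)
  S <- model$sample_cov / sc^2
  lib <- attach_sensor_projections(library, model$L_reduced)
  patches <- lib$components
  np <- length(patches)
  supports <- lapply(patches, function(cm) which(Matrix::rowSums(cm$source_factor) > 0))

  set_component <- function(idx, label) {
    Wf <- do.call(cbind, lapply(patches[idx], `[[`, "source_factor"))
    cmp <- new_component("patch", label, source_factor = Wf)
    cmp$sensor_factor <- do.call(cbind, lapply(patches[idx], `[[`, "sensor_factor"))
    cmp$set <- idx
    cmp
  }

  pool <- list(seq_len(np))
  set_history <- lengths(pool)
  F_prev <- -Inf
  low_gain <- 0L
  fit <- NULL
  pool_comps <- NULL
  for (outer in seq_len(max_outer)) {
    pool_comps <- c(lapply(seq_along(pool), function(k) {
      set_component(pool[[k]], sprintf("set_%d", k))
    }), list(sensor_noise_prior()))
    fit <- reml(S, nu_effective(model), pool_comps, hp = hp,
                max_iter = max_iter, tol = tol)
    gain <- fit$F - F_prev
    F_prev <- max(F_prev, fit$F)
    # internal E-step: reconstructed source power per vertex
    ex <- map_extractor(pool_comps, fit$lambda_mean, model$L_reduced)
    power <- rowSums((ex$M %*% S) * ex$M)
    parent <- pool[[length(pool)]]
    if (outer > 1 && gain < tol) low_gain <- low_gain + 1L else low_gain <- 0L
    if (length(parent) == 1L || low_gain >= 2L) break
    mag <- vapply(parent, function(i) sum(power[supports[[i]]]), numeric(1))
    newset <- parent[order(mag, decreasing = TRUE)][seq_len(ceiling(length(parent) / 2))]
    newset <- sort(newset)
    if (any(vapply(pool, identical, logical(1), y = newset))) break
    # drop unsupported sets (never the newly appended one)
    lam_sets <- fit$lambda_mean[seq_along(pool)]
    keep <- lam_sets >= hp$eta + prune_offset
    if (!any(keep)) keep[which.max(lam_sets)] <- TRUE
    pool <- c(pool[keep], list(newset))
    while (length(pool) > max_pool) pool <- pool[-1]  # evict oldest
    set_history <- c(set_history, length(newset))
  }
  lam_sets <- fit$lambda_mean[seq_along(pool)]
  keep <- which(lam_sets >= hp$eta + prune_offset)
  if (!length(keep)) keep <- which.max(lam_sets)
  syn_cols <- lapply(keep, function(k) {
    w <- sqrt(exp(min(lam_sets[k], 700)))
    do.call(cbind, lapply(patches[pool[[k]]], `[[`, "source_factor")) * w
  })
  syn <- new_component("patch", "synthesized", source_factor = do.call(cbind, syn_cols))
  fin <- final_inversion(model, syn, hp, max_iter, tol)
  active <- sort(unique(unlist(pool[keep])))
  labels <- vapply(patches[active], `[[`, "", "label")
  build_inversion_result("GS", model, fin, active = labels,
                         diagnostics = list(
                           n_outer = outer,
                           set_history = set_history,
                           pool_sizes = length(pool),
                           F_trace = fit$F_trace,
                           converged = fit$converged,
                           n_hyperparameters = length(pool) + 1L))
}

#' Run a named inversion scheme
#'
#' Dispatcher over the four schemes.  `MNM` needs no library; `EBB`
#' derives its prior from the model; `ARD` and `GS` require a patch
#' library.
#'
#' @param model a `reduced_model`.
#' @param scheme one of `"MNM"`, `"EBB"`, `"ARD"`, `"GS"`.
#' @param library a `prior_library` (for ARD/GS).
#' @param ... passed to the scheme driver.
#' @return an `inversion_result`.
#' @export
invert_scheme <- function(model, scheme = c("MNM", "EBB", "ARD", "GS"),
                          library = NULL, ...) {
  scheme <- match.arg(toupper(scheme), c("MNM", "EBB", "ARD", "GS"))
  switch(scheme,
    MNM = invert_single_prior(model, mnm_prior(ncol(model$L_reduced)), ...),
    EBB = invert_single_prior(model, ebb_prior(model), ...),
    ARD = {
      if (is.null(library)) stop_param("ARD requires a prior library")
      invert_ard(model, library, ...)
    },
    GS = {
      if (is.null(library)) stop_param("GS requires a prior library")
      invert_gs(model, library, ...)
    })
}
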