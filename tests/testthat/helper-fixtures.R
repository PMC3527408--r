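# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small head for unit tests: 642 vertices, 60 sensors.
small_head <- function() cached("small_head", {
  build_synthetic_head(n_vertices = 642, n_sensors = 60, seed = 7)
})

small_leadfield <- function() cached("small_lf", {
  compute_leadfield(small_head()$mesh, small_head()$sensors)
})

small_smoother <- function(s = 0.6) cached(sprintf("small_G_%s", s), {
  green_smoother(small_head()$mesh, s)
})

small_centers <- function(p = 24) cached(sprintf("small_ctr_%d", p), {
  select_patch_centers(small_head()$mesh, p, seed = 7)
})

small_library <- function(bilateral = FALSE) cached(sprintf("small_lib_%s", bilateral), {
  msp_library(small_smoother(), small_centers(), include_bilateral = bilateral)
})

# Study-scale head shared by the acceptance tests: 2562 vertices,
# 120 sensors, 64 patches per hemisphere.
study_head <- function() cached("study_head", {
  build_synthetic_head(n_vertices = 2562, n_sensors = 120, seed = 11)
})

study_leadfield <- function() cached("study_lf", {
  compute_leadfield(study_head()$mesh, study_head()$sensors)
})

study_centers <- function() cached("study_ctr", {
  select_patch_centers(study_head()$mesh, 64, seed = 11)
})

study_library <- function(bilateral = FALSE) cached(sprintf("study_lib_%s", bilateral), {
  msp_library(green_smoother_study(), study_centers(), include_bilateral = bilateral)
})

green_smoother_study <- function() cached("study_G", {
  green_smoother(study_head()$mesh, 0.6)
})

# Simulate + reduce in one call (the common test pattern).
simulate_reduced <- function(spec, head = study_head(), lf = study_leadfield(),
                             centers = study_centers(), locations = NULL) {
  ds <- simulate_dataset(spec, lf, centers, locations = locations)
  list(ds = ds, model = reduce_epochs(ds$epochs, lf))
}

# Mean per-trial SAI at a fixed search size.
mean_trial_sai <- function(inv, ds, model, mesh, r_mm) {
  mean(vapply(seq_len(model$n_trials), function(t) {
    pk <- find_local_maxima(inv$image_trials[, t], mesh)
    sai_at(pk, ds$true_vertices, mesh, r_mm)
  }, numeric(1)))
}

# A tiny synthetic covariance-component pair (signal + noise) for ReML
# tests, with data generated at known scale.
toy_reml_problem <- function(u = 6, nu = 1000, seed = 42,
                             w_signal = 1, w_noise = 0.01) {
  set.seed(seed)
  P1 <- crossprod(matrix(rnorm(u * u), u))
  P1 <- P1 / mean(diag(P1))
  Ctrue <- w_signal * P1 + w_noise * diag(u)
  X <- t(chol(Ctrue)) %*% matrix(rnorm(u * nu), u)
  S <- tcrossprod(X) / nu
  comps <- attach_sensor_projections(list(
    structure(list(kind = "custom", label = "sig", sensor_projection = P1),
              class = "covariance_component"),
    sensor_noise_prior()), matrix(0, u, 2))
  list(S = S, nu = nu, comps = comps, P1 = P1, u = u)
}
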