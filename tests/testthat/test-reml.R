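test_that("free energy closed form: identity covariance at the prior mean", {
  u <- 5; nu <- 7
  comps <- attach_sensor_projections(list(sensor_noise_prior()), matrix(0, u, 1))
  hp <- hyperprior(eta = 0, pi = 1 / 4)
  Fv <- free_energy(diag(u), nu, u, comps, lambda = 0,
                    lambda_cov = matrix(4), hp = hp)
  expect_equal(Fv, -u * nu / 2 - u * nu / 2 * log(2 * pi), tolerance = 1e-10)
})

test_that("compose_covariance follows the component algebra", {
  u <- 4
  set.seed(1)
  P <- crossprod(matrix(rnorm(u * u), u))
  comps <- attach_sensor_projections(list(
    structure(list(kind = "custom", label = "a", sensor_projection = P),
              class = "covariance_component"),
    sensor_noise_prior()), matrix(0, u, 2))
  expect_equal(compose_covariance(comps[2], 0, u = u), diag(u))
  C0 <- compose_covariance(comps, c(-1e6, -1e6), u = u)
  expect_lt(max(abs(C0)), 1e-200)
  # additivity of the composition
  Ca <- compose_covariance(comps, c(0.3, -1e6), u = u)
  Cb <- compose_covariance(comps, c(-1e6, -0.2), u = u)
  Cab <- compose_covariance(comps, c(0.3, -0.2), u = u)
  expect_equal(Ca + Cb, Cab, tolerance = 1e-10)
  expect_warning(compose_covariance(comps, c(800, 0), u = u), "clipped")
})

test_that("reml recovers generating scales on self-generated data", {
  prob <- toy_reml_problem(u = 6, nu = 1000, w_signal = 1, w_noise = 0.01)
  fit <- reml(prob$S, prob$nu, prob$comps)
  expect_true(fit$converged)
  scale <- exp(fit$lambda_mean[1])
  expect_gt(scale, 0.8)
  expect_lt(scale, 1.25)
  # free energy trace is non-decreasing up to relative tolerance
  expect_true(all(diff(fit$F_trace) >= -1e-6 * abs(fit$F_trace[-1])))
  expect_true(isSymmetric(fit$C_est))
  expect_gte(min(eigen(fit$C_est, only.values = TRUE)$values), 0)
})

test_that("reml matches a dense grid search of the free energy", {
  set.seed(7)
  u <- 4; nu <- 200
  P1 <- crossprod(matrix(rnorm(u * u), u)); P1 <- P1 / mean(diag(P1))
  Ctrue <- exp(0.7) * P1 + exp(-1.3) * diag(u)
  X <- t(chol(Ctrue)) %*% matrix(rnorm(u * nu), u)
  S <- tcrossprod(X) / nu
  comps <- attach_sensor_projections(list(
    structure(list(kind = "custom", label = "sig", sensor_projection = P1),
              class = "covariance_component"),
    sensor_noise_prior()), matrix(0, u, 2))
  fit <- reml(S, nu, comps)
  hp <- hyperprior()
  sp <- bayesmeg:::split_components(comps, u)
  grid <- seq(-8, 8, by = 0.05)
  eta <- rep(hp$eta, 2); piv <- rep(hp$pi, 2)
  best <- c(NA, NA); bestF <- -Inf
  for (l1 in grid) {
    C1 <- exp(l1) * P1
    for (l2 in grid) {
      lam <- c(l1, l2)
      ci <- tryCatch(bayesmeg:::chol_inv(C1 + exp(l2) * diag(u)),
                     error = function(e) NULL)
      if (is.null(ci)) next
      d <- bayesmeg:::reml_derivatives(sp, S, nu, lam, eta, piv, ci$inv)
      Fv <- bayesmeg:::free_energy_terms(S, nu, u, ci, lam,
                                         bayesmeg:::solve_psd(d$H), hp)$F
      if (is.finite(Fv) && Fv > bestF) { bestF <- Fv; best <- lam }
    }
  }
  expect_lt(max(abs(best - fit$lambda_mean)), 0.05 + 1e-9)
})

test_that("free energy is locally maximal at the reml optimum", {
  prob <- toy_reml_problem(u = 5, nu = 400, seed = 11)
  fit <- reml(prob$S, prob$nu, prob$comps, tol = 1e-6)
  hp <- hyperprior()
  probe <- function(lam) {
    sp <- bayesmeg:::split_components(prob$comps, prob$u)
    ci <- bayesmeg:::chol_inv(bayesmeg:::compose_from_split(sp, lam))
    d <- bayesmeg:::reml_derivatives(sp, prob$S, prob$nu, lam,
                                     rep(hp$eta, 2), rep(hp$pi, 2), ci$inv)
    bayesmeg:::free_energy_terms(prob$S, prob$nu, prob$u, ci, lam,
                                 bayesmeg:::solve_psd(d$H), hp)$F
  }
  F0 <- probe(fit$lambda_mean)
  for (i in 1:2) for (dd in c(-0.2, 0.2)) {
    lam <- fit$lambda_mean
    lam[i] <- lam[i] + dd
    expect_lt(probe(lam), F0 + 1e-8)
  }
})

test_that("a redundant duplicate component does not raise the optimized free energy", {
  prob <- toy_reml_problem(u = 5, nu = 300, seed = 13)
  fit1 <- reml(prob$S, prob$nu, prob$comps, tol = 1e-4)
  dup <- prob$comps[[1]]
  dup$label <- "sig_dup"
  fit2 <- reml(prob$S, prob$nu, c(list(dup), prob$comps), tol = 1e-4)
  expect_lte(fit2$F, fit1$F + 1e-3 * abs(fit1$F) + 1)
})

test_that("pure-noise data leave the noise component dominant", {
  set.seed(17)
  u <- 8; nu <- 500
  X <- matrix(rnorm(u * nu), u)
  S <- tcrossprod(X) / nu
  P <- crossprod(matrix(rnorm(u * u), u)); P <- P / mean(diag(P))
  comps <- attach_sensor_projections(list(
    structure(list(kind = "custom", label = "sig", sensor_projection = P),
              class = "covariance_component"),
    sensor_noise_prior()), matrix(0, u, 2))
  fit <- reml(S, nu, comps)
  hp <- hyperprior()
  expect_lt(fit$lambda_mean[1], hp$eta + 3 * sqrt(1 / hp$pi))
  noise_tr <- exp(fit$lambda_mean[2]) * u
  sig_tr <- exp(fit$lambda_mean[1]) * sum(diag(P))
  expect_gt(noise_tr, 10 * sig_tr)
})

test_that("data rescaling rescales every optimal scale parameter by c^2", {
  prob <- toy_reml_problem(u = 6, nu = 800, seed = 19)
  f1 <- reml(prob$S, prob$nu, prob$comps, tol = 1e-4)
  f2 <- reml(prob$S * 9, prob$nu, prob$comps, tol = 1e-4)
  ratio <- exp(f2$lambda_mean - f1$lambda_mean)
  expect_equal(ratio, c(9, 9), tolerance = 0.01)
})

test_that("reml input validation", {
  u <- 3
  comps <- attach_sensor_projections(list(mnm_prior(5), sensor_noise_prior()),
                                     matrix(rnorm(u * 5), u))
  expect_error(reml(-diag(u), 10, comps), "positive semi-definite")
  expect_error(reml(diag(u), 0, comps), "nu")
  expect_error(reml(diag(u), 10, comps[1]), "sensor_noise")
})

test_that("MAP extractor: identity prior equals the Tikhonov minimum-norm inverse", {
  set.seed(23)
  u <- 6; v <- 40
  L <- matrix(rnorm(u * v), u, v)
  comps <- attach_sensor_projections(list(mnm_prior(v), sensor_noise_prior()), L)
  lam <- c(0.4, -1.1)
  ex <- map_extractor(comps, lam, L)
  Mt <- exp(lam[1]) * t(L) %*% solve(exp(lam[1]) * tcrossprod(L) +
                                       exp(lam[2]) * diag(u))
  expect_lt(max(abs(ex$M - Mt)), 1e-10)
  # zero data give zero sources
  expect_true(all(extract_sources(ex, matrix(0, u, 3)) == 0))
  expect_error(map_extractor(comps, lam, L * 0), NA)
})

test_that("MAP extractor reproduces a noiseless source in the small-noise limit", {
  lf <- study_leadfield()
  ctr <- study_centers()
  spec <- simulation_spec(1, "single", snr_db = Inf, n_trials = 3, seed = 31)
  ds <- simulate_dataset(spec, lf, ctr)
  # full temporal basis so the reconstructed time course has length > 1
  U <- spatial_projector(lf)
  trials <- lapply(seq_len(dim(ds$epochs)[3]), function(t) ds$epochs[, , t])
  model <- reduce_model(trials, U, diag(dim(ds$epochs)[2]), lf$gain)
  v <- ncol(model$L_reduced)
  comps <- attach_sensor_projections(list(mnm_prior(v), sensor_noise_prior()),
                                     model$L_reduced)
  ex <- map_extractor(comps, c(0, -25), model$L_reduced)  # noise -> 0 limit
  shat <- ex$M %*% model$Y_reduced[, , 1]
  truth <- ds$true_timecourses %*% model$T
  cc <- abs(cor(as.numeric(shat[ds$true_vertices, ]), as.numeric(truth)))
  expect_gte(cc, 0.999)
})

test_that("reml trace file round-trips", {
  prob <- toy_reml_problem()
  fit <- reml(prob$S, prob$nu, prob$comps)
  p <- tempfile(fileext = ".tsv")
  write_reml_trace(fit, p)
  tr <- read.table(p, header = TRUE, sep = "\t")
  expect_equal(tr$F, fit$F_trace, tolerance = 1e-12)
})
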