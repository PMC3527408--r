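#' Simulation specification
#'
#' Declares one simulated dataset: dipole count and placement, time-course
#' correlation regime, SNR, epoch structure and seed.  Defaults follow
#' the benchmark conditions: 100 epochs of 0.8 s at 200 Hz, instantaneous
#' frequencies drawn from N(10, 2^2) Hz, SNR swept from -30 to +10 dB.
#'
#' @param n_dipoles 1, 2 or 3 simulated dipoles.
#' @param placement `"single"`, `"symmetric_pair"`, `"asymmetric_pair"`
#'   or `"random_triple"`.
#' @param correlation_regime `"high"` (all pairwise |r| > 0.8), `"low"`
#'   (< 0.3) or `"none"` (unconstrained).
#' @param snr_db signal-to-noise ratio in dB (RMS amplitude ratio);
#'   `Inf` disables noise.
#' @param n_trials number of epochs.
#' @param duration_s epoch length in seconds.
#' @param fs_hz sampling rate in Hz.
#' @param freq_mean_hz,freq_sd_hz instantaneous-frequency distribution.
#' @param amplitude_nam dipole moment in nAm (all dipoles equal).
#' @param snr_convention `"amplitude"` (20 log10 RMS ratio, default) or
#'   `"power"` (10 log10).
#' @param seed integer seed.
#' @export
simulation_spec <- function(n_dipoles = 1L,
                            placement = c("single", "symmetric_pair",
                                          "asymmetric_pair", "random_triple"),
                            correlation_regime = c("none", "low", "high"),
                            snr_db = 0,
                            n_trials = 100L,
                            duration_s = 0.8,
                            fs_hz = 200,
                            freq_mean_hz = 10,
                            freq_sd_hz = 2,
                            amplitude_nam = 1,
                            snr_convention = c("amplitude", "power"),
                            seed = 1L) {
  placement <- match.arg(placement)
  correlation_regime <- match.arg(correlation_regime)
  snr_convention <- match.arg(snr_convention)
  if (!n_dipoles %in% 1:3) stop_param("n_dipoles must be 1, 2 or 3")
  if (placement == "single" && n_dipoles != 1) stop_param("'single' placement needs n_dipoles = 1")
  if (placement %in% c("symmetric_pair", "asymmetric_pair") && n_dipoles != 2) {
    stop_param("pair placements need n_dipoles = 2")
  }
  if (placement == "random_triple" && n_dipoles != 3) stop_param("'random_triple' needs n_dipoles = 3")
  n_samples <- duration_s * fs_hz
  if (abs(n_samples - round(n_samples)) > 1e-9 || n_samples < 2) {
    stop_param("duration_s * fs_hz must be an integer >= 2")
  }
  if (freq_sd_hz < 0) stop_param("freq_sd_hz must be >= 0")
  structure(list(n_dipoles = as.integer(n_dipoles), placement = placement,
                 correlation_regime = correlation_regime, snr_db = snr_db,
                 n_trials = as.integer(n_trials), duration_s = duration_s,
                 fs_hz = fs_hz, freq_mean_hz = freq_mean_hz,
                 freq_sd_hz = freq_sd_hz, amplitude_nam = amplitude_nam,
                 snr_convention = snr_convention, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Select dipole locations with minimally correlated leadfields
#'
#' Draws `n_candidate_sets` random sets of `n_locations` patch centers
#' and keeps the set whose maximum absolute pairwise leadfield-column
#' correlation is smallest, giving well-separated simulation sites
#' spread across the source space.
#'
#' @param L a `leadfield` or gain matrix.
#' @param centers a `patch_centers` object or integer vertex vector.
#' @param n_locations number of sites to select (default 50).
#' @param n_candidate_sets number of random sets scored (default 10000).
#' @param seed integer seed.
#' @return integer vector of selected vertex indices, with the winning
#'   maximum |correlation| as attribute `"max_cor"`.
#' @export
select_dipole_locations <- function(L, centers, n_locations = 50L,
                                    n_candidate_sets = 10000L, seed = 1L) {
  gain <- if (inherits(L, "leadfield")) L$gain else L
  verts <- if (inherits(centers, "patch_centers")) centers$vertices else centers
  n <- length(verts)
  if (n_locations > n) stop_param("n_locations exceeds the number of centers (%d)", n)
  if (n_locations < 2) {
    sel <- with_local_seed(seed, sample(verts, n_locations))
    attr(sel, "max_cor") <- 0
    return(sel)
  }
  cm <- abs(stats::cor(gain[, verts, drop = FALSE]))
  diag(cm) <- 0
  with_local_seed(seed, {
    best <- NULL
    best_score <- Inf
    for (k in seq_len(n_candidate_sets)) {
      idx <- sample.int(n, n_locations)
      score <- max(cm[idx, idx])
      if (score < best_score) {
        best_score <- score
        best <- idx
      }
    }
    sel <- verts[best]
    attr(sel, "max_cor") <- best_score
    sel
  })
}

#' Generate a frequency-integrated sinusoid time course
#'
#' Per-sample instantaneous frequencies are drawn from
#' `N(freq_mean_hz, freq_sd_hz^2)`; the output is the sine of the
#' cumulative phase (2 pi cumsum(f)/fs) plus a random starting phase.
#'
#' @param n_samples number of samples (>= 2).
#' @param fs_hz sampling rate.
#' @param freq_mean_hz,freq_sd_hz frequency distribution parameters.
#' @param seed optional seed.
#' @export
generate_timecourse <- function(n_samples, fs_hz, freq_mean_hz = 10,
                                freq_sd_hz = 2, seed = NULL) {
  if (n_samples < 2) stop_param("n_samples must be >= 2")
  with_local_seed(seed, {
    f <- rnorm(n_samples, freq_mean_hz, freq_sd_hz)
    phase0 <- runif(1, 0, 2 * pi)
    sin(phase0 + 2 * pi * cumsum(f) / fs_hz)
  })
}

#' Generate dipole time courses under a correlation regime
#'
#' Rejection-samples tuples of time courses until every pairwise Pearson
#' correlation satisfies the regime: all `|r| > 0.8` for `"high"`, all
#' `|r| < 0.3` for `"low"`, unconstrained for `"none"`.
#'
#' @param n_dipoles number of time courses.
#' @param regime `"high"`, `"low"` or `"none"`.
#' @param n_samples,fs_hz,freq_mean_hz,freq_sd_hz as in
#'   [generate_timecourse()].
#' @param max_attempts rejection-sampling cap.
#' @param seed integer seed.
#' @return `n_dipoles x n_samples` matrix with attributes `"attempts"`
#'   and `"correlations"`.
#' @export
generate_source_set <- function(n_dipoles, regime = c("none", "low", "high"),
                                n_samples = 160L, fs_hz = 200,
                                freq_mean_hz = 10, freq_sd_hz = 2,
                                max_attempts = 10000L, seed = 1L) {
  regime <- match.arg(regime)
  ok <- function(r) {
    off <- r[upper.tri(r)]
    switch(regime,
           none = TRUE,
           low = all(abs(off) < 0.3),
           high = all(abs(off) > 0.8))
  }
  with_local_seed(seed, {
    draw <- function() {
      t(vapply(seq_len(n_dipoles), function(i) {
        f <- rnorm(n_samples, freq_mean_hz, freq_sd_hz)
        sin(runif(1, 0, 2 * pi) + 2 * pi * cumsum(f) / fs_hz)
      }, numeric(n_samples)))
    }
    if (n_dipoles == 1L) {
      s <- draw()
      attr(s, "attempts") <- 1L
      attr(s, "correlations") <- matrix(1, 1, 1)
      return(s)
    }
    for (att in seq_len(max_attempts)) {
      s <- draw()
      r <- stats::cor(t(s))
      if (ok(r)) {
        attr(s, "attempts") <- att
        attr(s, "correlations") <- r
        return(s)
      }
    }
    stop_param("no %s-correlation time-course set found in %d attempts; relax the regime",
               regime, max_attempts)
  })
}

#' Add white sensor noise at a target SNR
#'
#' Gaussian noise, independent across trials, sensors and samples, with
#' standard deviation `signal_rms / 10^(snr_db / 20)` (amplitude
#' convention) where `signal_rms` is the RMS of the noiseless sensor
#' data over all trials, sensors and samples.
#'
#' @param clean_epochs `n_sensors x s x trials` array (or matrix/list).
#' @param snr_db target SNR in dB; `Inf` returns the input unchanged.
#' @param seed integer seed.
#' @param convention `"amplitude"` (20 log10) or `"power"` (10 log10).
#' @return array of noisy epochs with attributes `"achieved_snr_db"` and
#'   `"noise_sd"`.
#' @export
add_sensor_noise <- function(clean_epochs, snr_db, seed = 1L,
                             convention = c("amplitude", "power")) {
  convention <- match.arg(convention)
  trials <- as_trial_list(clean_epochs)
  arr <- simplify2array(trials)
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1)
  if (!all(is.finite(arr))) stop_param("clean epochs must be finite")
  if (is.infinite(snr_db)) {
    attr(arr, "achieved_snr_db") <- Inf
    attr(arr, "noise_sd") <- 0
    return(arr)
  }
  signal_rms <- sqrt(mean(arr^2))
  expo <- if (convention == "amplitude") 20 else 10
  sdn <- signal_rms / 10^(snr_db / expo)
  noise <- with_local_seed(seed, array(rnorm(length(arr), 0, sdn), dim(arr)))
  out <- arr + noise
  attr(out, "achieved_snr_db") <- expo * log10(signal_rms / sqrt(mean(noise^2)))
  attr(out, "noise_sd") <- sdn
  out
}

#' Simulate an epoched MEG dataset
#'
#' Places dipoles at patch centers according to the placement rule,
#' generates time courses under the requested correlation regime,
#' replicates the clean sensor signal over trials, and adds white sensor
#' noise calibrated to the requested SNR (the noise differs from trial
#' to trial; the clean component does not).
#'
#' @param spec a [simulation_spec()].
#' @param L a `leadfield` or gain matrix.
#' @param centers a `patch_centers` object.
#' @param locations optional pre-selected site vector (e.g. from
#'   [select_dipole_locations()]); defaults to all patch centers.
#' @return a `simulated_dataset`: `epochs` (sensors x samples x trials),
#'   `true_vertices`, `true_timecourses`, `achieved_snr_db`,
#'   `achieved_correlations`, `spec`.
#' @export
simulate_dataset <- function(spec, L, centers, locations = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  gain <- if (inherits(L, "leadfield")) L$gain else L
  n_samples <- as.integer(round(spec$duration_s * spec$fs_hz))
  pool <- if (!is.null(locations)) as.integer(locations) else {
    if (inherits(centers, "patch_centers")) centers$vertices else as.integer(centers)
  }
  verts <- with_local_seed(child_seed(spec$seed, 1L), {
    switch(spec$placement,
      single = sample(pool, 1L),
      symmetric_pair = {
        if (!inherits(centers, "patch_centers") || is.null(centers$pair)) {
          stop_param("symmetric placement needs patch centers with contralateral pairing")
        }
        lefts <- intersect(pool, centers$pair[, 1])
        if (!length(lefts)) lefts <- centers$pair[, 1]
        v1 <- sample(lefts, 1L)
        c(v1, centers$pair[match(v1, centers$pair[, 1]), 2])
      },
      asymmetric_pair = sample(pool, 2L),
      random_triple = sample(pool, 3L))
  })
  verts <- unname(verts)
  S <- generate_source_set(spec$n_dipoles, spec$correlation_regime,
                           n_samples = n_samples, fs_hz = spec$fs_hz,
                           freq_mean_hz = spec$freq_mean_hz,
                           freq_sd_hz = spec$freq_sd_hz,
                           seed = child_seed(spec$seed, 2L))
  clean <- gain[, verts, drop = FALSE] %*% (spec$amplitude_nam * S)  # n x s
  clean_arr <- array(rep(clean, spec$n_trials),
                     c(nrow(clean), n_samples, spec$n_trials))
  epochs <- add_sensor_noise(clean_arr, spec$snr_db,
                             seed = child_seed(spec$seed, 3L),
                             convention = spec$snr_convention)
  structure(list(
    epochs = epochs,
    true_vertices = verts,
    true_timecourses = S,
    achieved_snr_db = attr(epochs, "achieved_snr_db"),
    achieved_correlations = attr(S, "correlations"),
    noise_sd = attr(epochs, "noise_sd"),
    spec = spec
  ), class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: %d dipole(s) at [%s], %d trials, SNR %.1f dB (achieved %.2f)\n",
              length(x$true_vertices), paste(x$true_vertices, collapse = ", "),
              dim(x$epochs)[3], x$spec$snr_db, x$achieved_snr_db))
  invisible(x)
}
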