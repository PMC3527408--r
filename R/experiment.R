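#' Experiment configuration
#'
#' A single structured description of a simulation study: head geometry,
#' patch library, the simulation grid (placements x correlation regimes
#' x SNRs x repetitions), the schemes to run and the metric parameters.
#' Any field can be overridden; everything else keeps the benchmark
#' defaults.  Configurations round-trip through YAML.
#'
#' @param ... named overrides of the default fields (nested lists are
#'   merged field-wise).
#' @return an `experiment_config`.
#' @export
experiment_config <- function(...) {
  base <- list(
    head = list(n_vertices = 2562, cortex_radius_mm = 71,
                conductor_radius_mm = 95, n_sensors = 120, seed = 11),
    library = list(p_per_hemisphere = 64, s = 0.6, bilateral = FALSE),
    simulation = list(placements = "single", regimes = "none",
                      snr_db = c(0), n_simulations = 2, n_trials = 20,
                      duration_s = 0.8, fs_hz = 200,
                      freq_mean_hz = 10, freq_sd_hz = 2),
    schemes = c("EBB"),
    metrics = list(sai_at_mm = 14, tai_at_mm = 10),
    seed = 1,
    out_dir = NULL
  )
  over <- list(...)
  cfg <- modifyList(base, over)
  if (is.null(cfg$out_dir)) cfg["out_dir"] <- list(NULL)
  bad <- setdiff(toupper(cfg$schemes), c("MNM", "EBB", "ARD", "GS"))
  if (length(bad)) stop_param("unknown scheme(s): %s", paste(bad, collapse = ", "))
  if (!length(cfg$simulation$snr_db)) stop_param("SNR list must be non-empty")
  structure(cfg, class = "experiment_config")
}

#' @rdname experiment_config
#' @param path YAML file path.
#' @export
read_experiment_config <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}

#' @rdname experiment_config
#' @param config an `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

placement_dipoles <- function(placement) {
  switch(placement, single = 1L, symmetric_pair = 2L, asymmetric_pair = 2L,
         random_triple = 3L, stop_param("unknown placement '%s'", placement))
}

#' Run a full simulation experiment
#'
#' Builds the synthetic head and prior library once, then for every grid
#' cell (scheme x placement x correlation regime x SNR) simulates
#' `n_simulations` datasets, inverts them and scores SAI/TAI.  Each
#' completed cell is written to `out_dir/cells/` as TSV and skipped on
#' re-run, so interrupted experiments resume; a merged summary and a
#' JSON manifest (seeds, config, versions) are written at the end.
#'
#' @param config an `experiment_config`.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @param quiet suppress progress messages.
#' @return invisibly, the summary data frame (also written to
#'   `summary.tsv`).
#' @export
run_experiment <- function(config, out_dir = config$out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(out_dir)) stop_param("an output directory is required")
  dir.create(file.path(out_dir, "cells"), recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  hd <- config$head
  head <- build_synthetic_head(hd$n_vertices, hd$cortex_radius_mm,
                               hd$conductor_radius_mm, hd$n_sensors, hd$seed)
  lf <- compute_leadfield(head$mesh, head$sensors)
  G <- green_smoother(head$mesh, config$library$s)
  centers <- select_patch_centers(head$mesh, config$library$p_per_hemisphere,
                                  seed = hd$seed)
  lib <- msp_library(G, centers, include_bilateral = isTRUE(config$library$bilateral))

  grid <- expand.grid(scheme = toupper(config$schemes),
                      placement = config$simulation$placements,
                      regime = config$simulation$regimes,
                      snr_db = config$simulation$snr_db,
                      stringsAsFactors = FALSE)
  rows <- list()
  for (gi in seq_len(nrow(grid))) {
    cell <- grid[gi, ]
    cell_id <- sprintf("%s_%s_%s_%+05.1fdB", cell$scheme, cell$placement,
                       cell$regime, cell$snr_db)
    cell_path <- file.path(out_dir, "cells", paste0(cell_id, ".tsv"))
    if (file.exists(cell_path)) {
      say("cell %s: cached", cell_id)
      rows[[gi]] <- read.table(cell_path, header = TRUE, sep = "\t")
      next
    }
    res <- tryCatch({
      out <- lapply(seq_len(config$simulation$n_simulations), function(si) {
        sim_seed <- child_seed(config$seed, gi * 1000L + si)
        spec <- simulation_spec(
          n_dipoles = placement_dipoles(cell$placement),
          placement = cell$placement, correlation_regime = cell$regime,
          snr_db = cell$snr_db, n_trials = config$simulation$n_trials,
          duration_s = config$simulation$duration_s,
          fs_hz = config$simulation$fs_hz,
          freq_mean_hz = config$simulation$freq_mean_hz,
          freq_sd_hz = config$simulation$freq_sd_hz, seed = sim_seed)
        ds <- simulate_dataset(spec, lf, centers)
        model <- reduce_epochs(ds$epochs, lf)
        inv <- invert_scheme(model, cell$scheme, library = lib)
        sai <- mean(vapply(seq_len(model$n_trials), function(t) {
          pk <- find_local_maxima(inv$image_trials[, t], head$mesh)
          sai_at(pk, ds$true_vertices, head$mesh, config$metrics$sai_at_mm)
        }, numeric(1)))
        tai <- compute_tai(inv, model, ds$true_vertices, head$mesh,
                           search_sizes = config$metrics$tai_at_mm)
        data.frame(cell = cell_id, scheme = cell$scheme,
                   condition = paste(cell$placement, cell$regime, sep = "/"),
                   placement = cell$placement, regime = cell$regime,
                   snr_db = cell$snr_db, simulation = si, seed = sim_seed,
                   sai = sai, tai = tai$tai_at_size[1],
                   F_final = inv$F_final,
                   achieved_snr_db = ds$achieved_snr_db)
      })
      do.call(rbind, out)
    }, error = function(e) {
      say("cell %s FAILED: %s", cell_id, conditionMessage(e))
      writeLines(conditionMessage(e), file.path(out_dir, "cells",
                                                paste0(cell_id, ".error.log")))
      NULL
    })
    if (is.null(res)) next
    write.table(res, cell_path, sep = "\t", row.names = FALSE, quote = FALSE)
    rows[[gi]] <- res
    say("cell %s: done (%d simulations)", cell_id, nrow(res))
  }
  summary <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  write_report(list(summary = summary, config = config), out_dir)
  invisible(summary)
}

#' Write experiment reports
#'
#' Writes the merged summary table as TSV, a JSON manifest recording the
#' configuration (including every seed and every defaulted parameter)
#' and, when ggplot2 is available, an accuracy-versus-SNR figure with
#' standard-error bars; tables are still written when plotting is not
#' possible.
#'
#' @param results list with elements `summary` (data frame) and
#'   `config`.
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
write_report <- function(results, out_dir) {
  if (is.null(results$summary) || !nrow(results$summary)) {
    stop_param("no completed cells to report")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  sp <- file.path(out_dir, "summary.tsv")
  write.table(results$summary, sp, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, sp)
  manifest <- list(
    package = "bayesmeg",
    version = as.character(utils::packageVersion("bayesmeg")),
    r_version = R.version.string,
    created = format(Sys.time(), tz = "UTC"),
    config = unclass(results$config),
    config_hash = fnv1a(paste(deparse(unclass(results$config)), collapse = "")),
    seeds = sort(unique(results$summary$seed))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, mp)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    agg <- stats::aggregate(sai ~ scheme + snr_db, results$summary, mean)
    agg$se <- stats::aggregate(sai ~ scheme + snr_db, results$summary,
                               function(x) sd(x) / sqrt(length(x)))$sai
    p <- ggplot2::ggplot(agg, ggplot2::aes(x = snr_db, y = sai, color = scheme)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = sai - se, ymax = sai + se),
                             width = 0.5) +
      ggplot2::labs(x = "SNR (dB)", y = "SAI", color = "scheme") +
      ggplot2::theme_minimal()
    pp <- file.path(out_dir, "accuracy_vs_snr.svg")
    ok <- tryCatch({ ggplot2::ggsave(pp, p, width = 6, height = 4); TRUE },
                   error = function(e) FALSE)
    if (ok) paths <- c(paths, pp)
  } else {
    warning("ggplot2 not available; tables written, plot skipped")
  }
  invisible(paths)
}

#' Export epochs as per-trial TSV files
#'
#' One `trial_<k>.tsv` per epoch (sensors x samples) plus a JSON sidecar
#' with the sampling rate and units.
#'
#' @param epochs `n_sensors x s x trials` array.
#' @param dir output directory.
#' @param fs_hz sampling rate recorded in the sidecar.
#' @param units field units recorded in the sidecar.
#' @export
write_epochs_tsv <- function(epochs, dir, fs_hz = 200, units = "fT") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nt <- dim(epochs)[3]
  for (t in seq_len(nt)) {
    write.table(epochs[, , t], file.path(dir, sprintf("trial_%03d.tsv", t)),
                sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(list(n_trials = nt, n_sensors = dim(epochs)[1],
                            n_samples = dim(epochs)[2], fs_hz = fs_hz,
                            units = units),
                       file.path(dir, "epochs.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_epochs_tsv
#' @export
read_epochs_tsv <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "epochs.json"))
  out <- array(0, c(meta$n_sensors, meta$n_samples, meta$n_trials))
  for (t in seq_len(meta$n_trials)) {
    out[, , t] <- as.matrix(read.table(file.path(dir, sprintf("trial_%03d.tsv", t)),
                                       sep = "\t"))
  }
  attr(out, "fs_hz") <- meta$fs_hz
  attr(out, "units") <- meta$units
  out
}
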