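#' Default log-spaced search sizes
#'
#' Ten search radii from 3 to 30 mm on a logarithmic scale, the grid on
#' which the spatial and temporal accuracy indices are reported.
#' @param n number of sizes.
#' @param range_mm range endpoints in mm.
#' @export
default_search_sizes <- function(n = 10L, range_mm = c(3, 30)) {
  exp(seq(log(range_mm[1]), log(range_mm[2]), length.out = n))
}

#' Local maxima of a source-power image
#'
#' A vertex is a peak if its value exceeds all first-order mesh
#' neighbors' values (ties broken towards the lower vertex index); peaks
#' below `rel_threshold` of the strongest peak are discarded.  Peaks are
#' returned sorted by descending value.
#'
#' @param image per-vertex nonnegative values (length `v`).
#' @param mesh a `source_mesh`.
#' @param rel_threshold relative floor (default 0.05 of the top peak).
#' @return a `peak_set`: `peak_vertices`, `peak_values`,
#'   `rel_threshold`.
#' @export
find_local_maxima <- function(image, mesh, rel_threshold = 0.05) {
  stopifnot(inherits(mesh, "source_mesh"))
  v <- nrow(mesh$vertices)
  if (length(image) != v) stop_param("image length must equal vertex count")
  if (all(image == 0)) {
    return(structure(list(peak_vertices = integer(0), peak_values = numeric(0),
                          rel_threshold = rel_threshold), class = "peak_set"))
  }
  A <- mesh$adjacency
  # vectorized neighbor maximum per vertex (columns of A list the
  # neighbors of each vertex), and the smallest neighbor index tied at it
  ci <- col_index(A)
  nb <- A@i + 1L
  nbval <- image[nb]
  nbmax <- as.numeric(tapply(nbval, ci, max))
  tie_min <- as.integer(tapply(ifelse(nbval == nbmax[ci], nb, NA_integer_),
                               ci, min, na.rm = TRUE))
  own <- seq_len(v)
  is_peak <- image > nbmax | (image == nbmax & own < tie_min)
  pk <- which(is_peak)
  if (!length(pk)) {
    return(structure(list(peak_vertices = integer(0), peak_values = numeric(0),
                          rel_threshold = rel_threshold), class = "peak_set"))
  }
  vals <- image[pk]
  keep <- vals >= rel_threshold * max(vals)
  pk <- pk[keep]; vals <- vals[keep]
  ord <- order(vals, decreasing = TRUE)
  structure(list(peak_vertices = pk[ord], peak_values = vals[ord],
                 rel_threshold = rel_threshold), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d peaks (threshold %.0f%% of max)\n",
              length(x$peak_vertices), 100 * x$rel_threshold))
  invisible(x)
}

#' Spatial Accuracy Index (SAI)
#'
#' FROC-inspired localization score.  For each search size `r`, peaks
#' within `r` mm (Euclidean) of the nearest true dipole are true
#' positives; walking the peaks in descending magnitude, the curve
#' `Y = TP_acc / (TP_acc + FP_acc)` of accumulated magnitudes is traced
#' over the fraction of peaks considered, and its trapezoidal area is
#' the SAI: 1 when no false positive outranks the true peaks, 0 when no
#' peak lands near a source.
#'
#' @param peaks a `peak_set` (or a source-power image if `mesh` can
#'   locate its maxima).
#' @param true_vertices true dipole vertex indices.
#' @param mesh a `source_mesh`.
#' @param search_sizes radii in mm (default [default_search_sizes()]).
#' @param distance `"euclidean"` (default) or `"geodesic"`.
#' @return a `sai_report`: `search_sizes_mm`, `sai` (AUC per size) and
#'   `ppv_curves` (list of per-size step curves).
#' @export
compute_sai <- function(peaks, true_vertices, mesh,
                        search_sizes = default_search_sizes(),
                        distance = c("euclidean", "geodesic")) {
  distance <- match.arg(distance)
  if (!inherits(peaks, "peak_set")) peaks <- find_local_maxima(peaks, mesh)
  if (!length(true_vertices)) stop_param("need at least one true vertex")
  ord <- order(peaks$peak_values, decreasing = TRUE)  # descending-magnitude walk
  peaks$peak_vertices <- peaks$peak_vertices[ord]
  peaks$peak_values <- peaks$peak_values[ord]
  k <- length(peaks$peak_vertices)
  if (k == 0) {
    return(structure(list(search_sizes_mm = search_sizes,
                          sai = rep(0, length(search_sizes)),
                          ppv_curves = replicate(length(search_sizes),
                                                 list(fraction = numeric(0), Y = numeric(0)),
                                                 simplify = FALSE)),
                     class = "sai_report"))
  }
  dmat <- if (distance == "euclidean") {
    pv <- mesh$vertices[peaks$peak_vertices, , drop = FALSE]
    tv <- mesh$vertices[true_vertices, , drop = FALSE]
    outer_dist(pv, tv)
  } else {
    t(mesh_geodesics(mesh, true_vertices))[peaks$peak_vertices, , drop = FALSE]
  }
  dnear <- apply(dmat, 1, min)
  frac <- seq_len(k) / k
  res <- lapply(search_sizes, function(r) {
    tp <- dnear <= r
    tp_acc <- cumsum(peaks$peak_values * tp)
    fp_acc <- cumsum(peaks$peak_values * !tp)
    Y <- tp_acc / (tp_acc + fp_acc)
    # trapezoid over the fraction axis, extended flat to fraction 0
    auc <- sum(diff(c(0, frac)) * (c(Y[1], utils::head(Y, -1)) + Y) / 2)
    list(curve = list(fraction = frac, Y = Y), auc = auc)
  })
  structure(list(search_sizes_mm = search_sizes,
                 sai = vapply(res, `[[`, numeric(1), "auc"),
                 ppv_curves = lapply(res, `[[`, "curve")),
            class = "sai_report")
}

outer_dist <- function(a, b) {
  m <- matrix(0, nrow(a), nrow(b))
  for (j in seq_len(nrow(b))) {
    m[, j] <- sqrt(colSums((t(a) - b[j, ])^2))
  }
  m
}

#' @export
print.sai_report <- function(x, ...) {
  cat("sai_report:\n")
  print(data.frame(search_mm = round(x$search_sizes_mm, 1), sai = round(x$sai, 3)))
  invisible(x)
}

#' SAI at a given search size
#'
#' Convenience: the SAI evaluated at exactly `r_mm` (computed, not
#' interpolated).
#' @inheritParams compute_sai
#' @param r_mm search radius in mm.
#' @export
sai_at <- function(peaks, true_vertices, mesh, r_mm) {
  compute_sai(peaks, true_vertices, mesh, search_sizes = r_mm)$sai[1]
}

#' Temporal Accuracy Index (TAI)
#'
#' For each search size `r`, the sources within `r` mm of any true
#' dipole count as true positives, and `R^2 = 1 - SS_res / SS_tot`
#' measures the fraction of reduced-data variance those sources explain.
#' Each selected source contributes the rank-one sensor pattern
#' `l_v %*% t(shat_v)` formed from its reduced leadfield column and its
#' reconstructed time course; the data are regressed on the selected
#' patterns by least squares.  Because the pattern sets are nested in
#' `r`, the `R^2` curve is non-decreasing in the search size by
#' construction.  The TAI summary is the trapezoidal area of that curve
#' over the log-spaced sizes, normalized to `[0, 1]`; per-size values
#' are also reported.  `R^2` is undefined (returned as `NA`) when a
#' single temporal mode survives reduction.
#'
#' @param result an `inversion_result` (its extractor supplies the
#'   reconstructed sources; time-course signatures come from the
#'   trial-mean response).
#' @param model the `reduced_model` the inversion used.
#' @param true_vertices true dipole vertex indices.
#' @param mesh a `source_mesh`.
#' @param search_sizes radii in mm.
#' @param per_trial score trials individually and average (default); if
#'   `FALSE`, score the trial-mean reduced data.
#' @return a `tai_report`: `search_sizes_mm`, `tai_at_size` (R^2 per
#'   size), `tai_auc`.
#' @export
compute_tai <- function(result, model, true_vertices, mesh,
                        search_sizes = default_search_sizes(),
                        per_trial = TRUE) {
  stopifnot(inherits(result, "inversion_result"), inherits(model, "reduced_model"))
  if (model$nu < 2) {
    return(structure(list(search_sizes_mm = search_sizes,
                          tai_at_size = rep(NA_real_, length(search_sizes)),
                          tai_auc = NA_real_),
                     class = "tai_report"))
  }
  tv <- mesh$vertices[true_vertices, , drop = FALSE]
  dnear <- apply(outer_dist(mesh$vertices, tv), 1, min)
  sel_max <- which(dnear <= max(search_sizes))
  M <- result$extractor$M
  Ymean <- apply(model$Y_reduced, c(1, 2), mean)
  Shat <- M[sel_max, , drop = FALSE] %*% Ymean     # temporal signatures
  L_sel <- model$L_reduced[, sel_max, drop = FALSE]
  gram_full <- crossprod(L_sel) * tcrossprod(Shat) # (l_i.l_j)(s_i.s_j)
  Ys <- if (per_trial) {
    lapply(seq_len(model$n_trials), function(t) model$Y_reduced[, , t])
  } else list(Ymean)
  r2_mat <- matrix(0, length(search_sizes), length(Ys))
  for (si in seq_along(search_sizes)) {
    sub <- which(dnear[sel_max] <= search_sizes[si])
    if (!length(sub)) {
      r2_mat[si, ] <- 0
      next
    }
    eg <- eigen(sym(gram_full[sub, sub, drop = FALSE]), symmetric = TRUE)
    keep <- eg$values > max(eg$values, 0) * 1e-10
    if (!any(keep)) {
      r2_mat[si, ] <- 0
      next
    }
    Vk <- eg$vectors[, keep, drop = FALSE]
    wk <- eg$values[keep]
    for (ti in seq_along(Ys)) {
      Y <- Ys[[ti]]
      ss_tot <- sum(Y^2)
      if (ss_tot == 0) stop_param("zero total sum of squares in reduced data")
      # b_i = l_i' Y shat_i ; explained SS = b' G^+ b (LS projection)
      b <- rowSums((t(L_sel[, sub, drop = FALSE]) %*% Y) *
                     Shat[sub, , drop = FALSE])
      z <- crossprod(Vk, b)
      r2_mat[si, ti] <- sum(z^2 / wk) / ss_tot
    }
  }
  r2 <- rowMeans(r2_mat)
  xs <- (log(search_sizes) - log(min(search_sizes))) /
    max(log(max(search_sizes)) - log(min(search_sizes)), .Machine$double.eps)
  auc <- if (length(search_sizes) > 1) {
    sum(diff(xs) * (utils::head(r2, -1) + r2[-1]) / 2)
  } else r2[1]
  structure(list(search_sizes_mm = search_sizes, tai_at_size = r2,
                 tai_auc = auc), class = "tai_report")
}

#' @export
print.tai_report <- function(x, ...) {
  cat(sprintf("tai_report: AUC = %.3f\n", x$tai_auc))
  invisible(x)
}

#' Compare scheme accuracies with corrected t-tests
#'
#' Two-sample t-tests between every pair of schemes, separately per
#' condition and SNR, Bonferroni-corrected across the number of
#' conditions times the number of SNR levels; cell means and standard
#' errors are reported alongside.
#'
#' @param scores data frame with columns `scheme`, `condition`, `snr_db`,
#'   `score` (one row per simulation).
#' @param alpha significance level after correction.
#' @return list with `cells` (mean +/- SE per scheme x condition x SNR)
#'   and `tests` (pairwise comparisons with raw and corrected p-values).
#' @export
compare_accuracy <- function(scores, alpha = 0.05) {
  need <- c("scheme", "condition", "snr_db", "score")
  if (!all(need %in% names(scores))) {
    stop_param("scores must have columns %s", paste(need, collapse = ", "))
  }
  conditions <- unique(scores$condition)
  snrs <- unique(scores$snr_db)
  bonf <- length(conditions) * length(snrs)
  cells <- do.call(rbind, lapply(split(scores, scores[c("scheme", "condition", "snr_db")],
                                       drop = TRUE), function(d) {
    data.frame(scheme = d$scheme[1], condition = d$condition[1],
               snr_db = d$snr_db[1], n = nrow(d), mean = mean(d$score),
               se = stats::sd(d$score) / sqrt(nrow(d)))
  }))
  rownames(cells) <- NULL
  tests <- list()
  for (cond in conditions) {
    for (s in snrs) {
      d <- scores[scores$condition == cond & scores$snr_db == s, ]
      schemes <- unique(d$scheme)
      if (length(schemes) < 2) next
      prs <- utils::combn(schemes, 2, simplify = FALSE)
      for (pr in prs) {
        x <- d$score[d$scheme == pr[1]]
        y <- d$score[d$scheme == pr[2]]
        if (length(x) < 2 || length(y) < 2) next
        degenerate <- stats::sd(x) == 0 && stats::sd(y) == 0
        if (degenerate && isTRUE(all.equal(mean(x), mean(y)))) {
          p <- 1; tstat <- 0
        } else if (degenerate) {
          p <- 0; tstat <- Inf
        } else {
          tt <- t.test(x, y)
          p <- tt$p.value; tstat <- unname(tt$statistic)
        }
        tests[[length(tests) + 1]] <- data.frame(
          condition = cond, snr_db = s, scheme_a = pr[1], scheme_b = pr[2],
          mean_diff = mean(x) - mean(y), t = tstat, p = p,
          p_bonferroni = min(1, p * bonf),
          significant = min(1, p * bonf) < alpha,
          degenerate = degenerate)
      }
    }
  }
  list(cells = cells,
       tests = if (length(tests)) do.call(rbind, tests) else NULL,
       bonferroni_factor = bonf)
}

#' Pairwise fixed-effects free-energy comparison
#'
#' For each pair of schemes, the mean free-energy difference over
#' simulations of the same data, the sign counts and the fraction of
#' simulations favoring each scheme.
#'
#' @param F_table data frame or matrix: one row per simulation, one
#'   column per scheme, entries the comparable final free energies.
#' @return data frame of pairwise summaries.
#' @export
compare_free_energy <- function(F_table) {
  ft <- as.data.frame(F_table)
  dropped <- !stats::complete.cases(ft)
  if (any(dropped)) {
    message(sprintf("compare_free_energy: dropping %d incomplete row(s)", sum(dropped)))
    ft <- ft[!dropped, , drop = FALSE]
  }
  schemes <- colnames(ft)
  prs <- utils::combn(schemes, 2, simplify = FALSE)
  out <- lapply(prs, function(pr) {
    d <- ft[[pr[1]]] - ft[[pr[2]]]
    data.frame(scheme_a = pr[1], scheme_b = pr[2],
               mean_diff = mean(d),
               n_favor_a = sum(d > 0), n_favor_b = sum(d < 0), n_tie = sum(d == 0),
               fraction_favor_a = (sum(d > 0) + 0.5 * sum(d == 0)) / length(d))
  })
  do.call(rbind, out)
}
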