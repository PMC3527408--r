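# Independent brute-force SAI oracle: explicit step-by-step accumulation.
sai_oracle <- function(values, is_tp) {
  ord <- order(values, decreasing = TRUE)
  tp_acc <- 0; fp_acc <- 0
  Y <- numeric(length(ord))
  for (k in seq_along(ord)) {
    if (is_tp[ord[k]]) tp_acc <- tp_acc + values[ord[k]]
    else fp_acc <- fp_acc + values[ord[k]]
    Y[k] <- tp_acc / (tp_acc + fp_acc)
  }
  frac <- seq_along(ord) / length(ord)
  xs <- c(0, frac)
  ys <- c(Y[1], Y)
  sum(diff(xs) * (utils::head(ys, -1) + ys[-1]) / 2)
}

peakset <- function(vertices, values) {
  structure(list(peak_vertices = vertices, peak_values = values,
                 rel_threshold = 0.05), class = "peak_set")
}

test_that("local maxima agree with a brute-force neighbor scan", {
  m <- small_head()$mesh
  v <- nrow(m$vertices)
  A <- m$adjacency
  set.seed(1)
  for (k in 1:100) {
    img <- abs(rnorm(v))
    if (k %% 7 == 0) img <- round(img, 1)  # force ties sometimes
    pk <- find_local_maxima(img, m)
    # oracle: direct scan
    is_peak <- vapply(seq_len(v), function(i) {
      nb <- which(A[i, ] > 0)
      mx <- max(img[nb])
      img[i] > mx || (img[i] == mx && all(nb[img[nb] == mx] > i))
    }, logical(1))
    keep <- which(is_peak)
    keep <- keep[img[keep] >= 0.05 * max(img[keep])]
    expect_setequal(pk$peak_vertices, keep)
    expect_true(all(diff(pk$peak_values) <= 0))
  }
})

test_that("local maxima handle degenerate images", {
  m <- small_head()$mesh
  v <- nrow(m$vertices)
  expect_length(find_local_maxima(rep(0, v), m)$peak_vertices, 0)
  img <- rep(0, v); img[100] <- 3
  pk <- find_local_maxima(img, m)
  expect_equal(pk$peak_vertices, 100L)
  # sub-threshold secondary peaks are removed (4 < 5% of 100)
  img2 <- rep(0, v); img2[100] <- 100; img2[500] <- 4
  expect_equal(find_local_maxima(img2, m)$peak_vertices, 100L)
  expect_error(find_local_maxima(img[-1], m), "length")
})

test_that("SAI matches the hand-worked three-peak case", {
  m <- small_head()$mesh
  true_v <- 100
  d <- sqrt(colSums((t(m$vertices) - m$vertices[true_v, ])^2))
  near <- which(d < 15)         # true positives for r = 15
  far <- which(d > 50)
  pk <- peakset(c(near[1], far[1], near[2]), c(10, 5, 5))
  rep5 <- compute_sai(pk, true_v, m, search_sizes = 15)
  # walk: TP 10 -> Y=1; FP 5 -> 10/15; TP 5 -> 15/20
  expect_equal(rep5$ppv_curves[[1]]$Y, c(1, 10 / 15, 15 / 20), tolerance = 1e-12)
  auc_hand <- 1 / 3 * 1 + (1 + 10 / 15) / 2 / 3 + (10 / 15 + 15 / 20) / 2 / 3
  expect_equal(rep5$sai[1], auc_hand, tolerance = 1e-12)
  expect_equal(rep5$sai[1],
               sai_oracle(c(10, 5, 5), c(TRUE, FALSE, TRUE)), tolerance = 1e-12)
})

test_that("SAI spans [0, 1]: all-TP gives 1, all-FP gives 0", {
  m <- small_head()$mesh
  true_v <- 100
  d <- sqrt(colSums((t(m$vertices) - m$vertices[true_v, ])^2))
  near <- which(d < 20); far <- which(d > 50)
  expect_equal(compute_sai(peakset(near[1:3], c(3, 2, 1)), true_v, m,
                           search_sizes = 20)$sai, 1)
  expect_equal(compute_sai(peakset(far[1:3], c(3, 2, 1)), true_v, m,
                           search_sizes = 20)$sai, 0)
  # empty peak set: SAI 0 at every size
  empty <- peakset(integer(0), numeric(0))
  expect_true(all(compute_sai(empty, true_v, m)$sai == 0))
})

test_that("SAI agrees with the brute-force oracle on random instances", {
  m <- small_head()$mesh
  v <- nrow(m$vertices)
  set.seed(2)
  for (k in 1:50) {
    npk <- sample(1:10, 1)
    pkv <- sample(v, npk)
    vals <- sort(abs(rnorm(npk)) + 0.1, decreasing = TRUE)
    truth <- sample(v, sample(1:3, 1))
    r <- runif(1, 3, 30)
    rep1 <- compute_sai(peakset(pkv, vals), truth, m, search_sizes = r)
    dmat <- sapply(truth, function(tv) sqrt(colSums((t(m$vertices[pkv, , drop = FALSE]) -
                                                       m$vertices[tv, ])^2)))
    is_tp <- apply(as.matrix(dmat), 1, min) <= r
    expect_equal(rep1$sai[1], sai_oracle(vals, is_tp), tolerance = 1e-12)
  }
})

test_that("SAI is non-decreasing in the search size", {
  m <- small_head()$mesh
  v <- nrow(m$vertices)
  set.seed(3)
  for (k in 1:20) {
    pkv <- sample(v, 8)
    vals <- abs(rnorm(8)) + 0.1
    truth <- sample(v, 2)
    s <- compute_sai(peakset(pkv, vals), truth, m)$sai
    expect_true(all(diff(s) >= -1e-12))
  }
})

test_that("TAI is exact on closed-form cases and monotone in search size", {
  lf <- study_leadfield()
  ctr <- study_centers()
  mesh <- study_head()$mesh
  spec <- simulation_spec(1, "single", snr_db = 5, n_trials = 10, seed = 41)
  ds <- simulate_dataset(spec, lf, ctr)
  model <- reduce_epochs(ds$epochs, lf, mode_rule = "variance",
                         variance_fraction = 0.99)
  inv <- invert_scheme(model, "EBB")
  rep1 <- compute_tai(inv, model, ds$true_vertices, mesh)
  expect_true(all(diff(rep1$tai_at_size) >= -1e-9))
  expect_true(all(rep1$tai_at_size <= 1 + 1e-12))
  # a zeroed reconstruction explains no variance
  inv0 <- inv
  inv0$extractor$M <- inv$extractor$M * 0
  rep0 <- compute_tai(inv0, model, ds$true_vertices, mesh)
  expect_true(all(abs(rep0$tai_at_size) < 1e-12))
  expect_equal(rep0$tai_auc, 0)
})

test_that("TAI reaches 1 for a perfect reconstruction", {
  mesh <- small_head()$mesh
  lf <- small_leadfield()
  # invertible toy: sources only at two vertices, u >= 2 modes
  U <- spatial_projector(lf)
  L <- U %*% lf$gain
  truth <- c(50, 400)
  S <- rbind(sin(1:12), cos(1:12))
  Y <- L[, truth] %*% S
  model <- structure(list(U = U, T = diag(12), L_reduced = L,
                          Y_reduced = array(Y, c(nrow(U), 12, 1)),
                          u = nrow(U), nu = 12, n_trials = 1,
                          sample_cov = tcrossprod(Y) / 12),
                     class = "reduced_model")
  M <- matrix(0, ncol(L), nrow(L))
  M[truth, ] <- solve(crossprod(L[, truth]), t(L[, truth]))  # exact LS inverse
  inv <- structure(list(extractor = list(M = M)), class = "inversion_result")
  rep1 <- compute_tai(inv, model, truth, mesh, search_sizes = c(5, 15, 30))
  expect_equal(rep1$tai_at_size, rep(1, 3), tolerance = 1e-9)
})

test_that("TAI is undefined with a single temporal mode", {
  mesh <- small_head()$mesh
  model <- structure(list(nu = 1), class = "reduced_model")
  inv <- structure(list(extractor = list(M = NULL)), class = "inversion_result")
  rep1 <- compute_tai(inv, model, 1, mesh)
  expect_true(all(is.na(rep1$tai_at_size)))
  expect_true(is.na(rep1$tai_auc))
})

test_that("accuracy comparison: t-tests with Bonferroni correction", {
  set.seed(5)
  mk <- function(scheme, cond, snr, mu) data.frame(
    scheme = scheme, condition = cond, snr_db = snr,
    score = rnorm(50, mu, 0.01))
  scores <- rbind(mk("A", "c1", 0, 0.5), mk("B", "c1", 0, 0.9),
                  mk("A", "c1", 10, 0.7), mk("B", "c1", 10, 0.7),
                  mk("A", "c2", 0, 0.5), mk("B", "c2", 0, 0.5),
                  mk("A", "c2", 10, 0.5), mk("B", "c2", 10, 0.5))
  res <- compare_accuracy(scores)
  expect_equal(res$bonferroni_factor, 4)  # 2 conditions x 2 SNRs
  t1 <- res$tests[res$tests$condition == "c1" & res$tests$snr_db == 0, ]
  expect_true(t1$significant)
  expect_equal(t1$p_bonferroni, min(1, t1$p * 4))
  # identical vectors are never significant
  same <- data.frame(scheme = rep(c("A", "B"), each = 10), condition = "c",
                     snr_db = 0, score = rep(runif(10), 2))
  res2 <- compare_accuracy(same)
  expect_false(any(res2$tests$significant))
  # cell summaries carry mean and standard error
  cell <- res$cells[res$cells$scheme == "B" & res$cells$condition == "c1" &
                      res$cells$snr_db == 0, ]
  expect_equal(cell$mean, 0.9, tolerance = 0.01)
  expect_equal(cell$n, 50)
})

test_that("degenerate zero-variance cells are flagged", {
  scores <- data.frame(scheme = rep(c("A", "B"), each = 5), condition = "c",
                       snr_db = 0, score = rep(c(0.2, 0.8), each = 5))
  res <- compare_accuracy(scores)
  expect_true(res$tests$degenerate)
  expect_true(res$tests$significant)
})

test_that("free-energy comparison summarizes pairwise preferences", {
  ft <- data.frame(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4))
  res <- compare_free_energy(ft)
  expect_equal(res$mean_diff, 0)
  expect_equal(res$fraction_favor_a, 0.5)
  ft2 <- data.frame(A = c(1, 2, 3), B = c(1, 2, 3) - 3)
  res2 <- compare_free_energy(ft2)
  expect_equal(res2$mean_diff, 3)
  expect_equal(res2$fraction_favor_a, 1)
  expect_equal(res2$n_favor_a, 3)
  # incomplete rows are dropped with a message
  ft3 <- data.frame(A = c(1, NA, 3), B = c(0, 1, 1))
  expect_message(res3 <- compare_free_energy(ft3), "dropping")
  expect_equal(res3$n_favor_a + res3$n_favor_b + res3$n_tie, 2)
})
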