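test_that("unperturbed icosahedron has radial unit normals", {
  h <- build_synthetic_head(n_vertices = 12, n_sensors = 16, seed = 1,
                            wrinkle_amplitude = 0)
  m <- h$mesh
  expect_equal(nrow(m$vertices), 12L)
  rad <- m$vertices / sqrt(rowSums(m$vertices^2))
  expect_lt(max(abs(rowSums(m$normals * rad) - 1)), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(m$normals^2)) - 1)), 1e-9)
})

test_that("head generation is deterministic in the seed", {
  h1 <- build_synthetic_head(n_vertices = 162, n_sensors = 24, seed = 5)
  h2 <- build_synthetic_head(n_vertices = 162, n_sensors = 24, seed = 5)
  h3 <- build_synthetic_head(n_vertices = 162, n_sensors = 24, seed = 6)
  expect_identical(h1$mesh$vertices, h2$mesh$vertices)
  expect_identical(h1$sensors$orientations, h2$sensors$orientations)
  expect_false(identical(h1$mesh$vertices, h3$mesh$vertices))
})

test_that("default head matches the 5 mm mean vertex spacing within 20%", {
  h <- build_synthetic_head(seed = 1)
  expect_gt(h$mesh$mean_edge_mm, 4)
  expect_lt(h$mesh$mean_edge_mm, 6)
})

test_that("mesh invariants hold: inside conductor, unit normals, connected hemispheres", {
  m <- small_head()$mesh
  expect_true(all(sqrt(rowSums(m$vertices^2)) < m$conductor_radius_mm))
  expect_lt(max(abs(sqrt(rowSums(m$normals^2)) - 1)), 1e-9)
  expect_true(hemisphere_connected(m))
  expect_gt(m$mean_edge_mm, 0)
  s <- small_head()$sensors
  expect_true(all(sqrt(rowSums(s$positions^2)) > s$conductor_radius_mm))
  expect_lt(max(abs(sqrt(rowSums(s$orientations^2)) - 1)), 1e-9)
  # tangential orientations: orthogonal to the position vector
  rad <- s$positions / sqrt(rowSums(s$positions^2))
  expect_lt(max(abs(rowSums(s$orientations * rad))), 1e-9)
})

test_that("parameter validation rejects bad head requests", {
  expect_error(build_synthetic_head(n_vertices = 4), "n_vertices")
  expect_error(build_synthetic_head(n_sensors = 2), "n_sensors")
  expect_error(build_synthetic_head(cortex_radius_mm = 100,
                                    conductor_radius_mm = 90), "smaller")
})

test_that("radial dipoles are magnetically silent", {
  m <- small_head()$mesh
  s <- small_head()$sensors
  set.seed(1)
  idx <- sample(nrow(m$vertices), 100)
  rad <- m$vertices[idx, ] / sqrt(rowSums(m$vertices[idx, ]^2))
  ref <- matrix(rep(c(0, 0, 1), length(idx)), ncol = 3, byrow = TRUE)
  par <- abs(rowSums(rad * ref)) > 0.9
  ref[par, ] <- matrix(rep(c(1, 0, 0), sum(par)), ncol = 3, byrow = TRUE)
  tang <- bayesmeg:::normalize_rows(bayesmeg:::cross_rows(rad, ref))
  g_rad <- bayesmeg:::sarvas_gain(m$vertices[idx, ], rad, s$positions, s$orientations)
  g_tan <- bayesmeg:::sarvas_gain(m$vertices[idx, ], tang, s$positions, s$orientations)
  ratio <- sqrt(colSums(g_rad^2)) / sqrt(colSums(g_tan^2))
  expect_lt(max(ratio), 1e-8)
})

test_that("sphere leadfield matches the independent primary-current oracle", {
  # the radial field component in a spherical conductor carries no
  # volume-current contribution, so it must equal the Biot-Savart field
  # of the primary dipole alone -- an algebraically independent route
  r0 <- matrix(c(30, 10, 20), 1)
  q <- bayesmeg:::normalize_rows(matrix(c(0, 1, 0.5), 1))
  set.seed(2)
  for (k in 1:20) {
    dir <- bayesmeg:::normalize_rows(matrix(rnorm(3), 1))
    sp <- dir * 130
    ori <- dir                                   # radially oriented sensor
    sarvas <- bayesmeg:::sarvas_gain(r0, q, sp, ori)
    d <- (sp - r0) * 1e-3
    bs <- 1e-7 * bayesmeg:::cross_rows(q * 1e-9, d) / sum(d^2)^1.5
    oracle <- sum(bs * ori) * 1e15
    expect_lt(abs(sarvas - oracle) / abs(oracle), 1e-6)
  }
})

test_that("leadfield is linear in the dipole moment", {
  m <- small_head()$mesh
  s <- small_head()$sensors
  idx <- c(5, 50, 500)
  p <- m$normals[idx, ]
  q <- bayesmeg:::normalize_rows(matrix(rnorm(9), 3))
  a <- 2.5; b <- -1.3
  g_sum <- bayesmeg:::sarvas_gain(m$vertices[idx, ], a * p + b * q,
                                  s$positions, s$orientations)
  g_p <- bayesmeg:::sarvas_gain(m$vertices[idx, ], p, s$positions, s$orientations)
  g_q <- bayesmeg:::sarvas_gain(m$vertices[idx, ], q, s$positions, s$orientations)
  expect_lt(max(abs(g_sum - (a * g_p + b * g_q))), 1e-12 * max(abs(g_sum)))
  expect_equal(bayesmeg:::sarvas_gain(m$vertices[idx, ], 2 * p,
                                      s$positions, s$orientations), 2 * g_p)
})

test_that("leadfield geometry errors are caught", {
  h <- small_head()
  m <- h$mesh
  m$vertices[1, ] <- c(0, 0, 0)
  expect_error(compute_leadfield(m, h$sensors), "center")
  s <- h$sensors
  s$positions[1, ] <- c(10, 0, 0)
  expect_error(compute_leadfield(h$mesh, s), "inside")
})

test_that("green smoother: identity at s = 0, support within 8th-order neighborhood", {
  m <- small_head()$mesh
  G0 <- green_smoother(m, 0)
  expect_lt(max(abs(G0$G - Matrix::Diagonal(nrow(m$vertices), 1))), 1e-12)
  G <- small_smoother()
  expect_true(all(G$G@x >= 0))
  # BFS oracle: every column's support within 8 hops of its center
  g <- igraph::graph_from_adjacency_matrix(m$adjacency > 0, mode = "undirected")
  set.seed(3)
  for (cv in sample(nrow(m$vertices), 15)) {
    supp <- which(G$G[, cv] > 0)
    ball <- as.integer(igraph::ego(g, order = 8, nodes = cv)[[1]])
    expect_true(all(supp %in% ball))
    expect_equal(max(G$G[, cv]), 1)      # unit column maximum
    expect_equal(unname(which.max(G$G[, cv])), cv)
  }
})

test_that("green smoother patch extent grows monotonically with s", {
  m <- study_head()$mesh
  ctr <- study_centers()$vertices[1:8]
  counts <- sapply(c(0.2, 0.4, 0.6, 0.8), function(s) {
    G <- green_smoother(m, s)
    mean(sapply(ctr, function(cv) sum(G$G[, cv] > 0.6)))
  })
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[4], counts[1])  # strictly wider overall
})

test_that("green smoother influence is symmetric where degrees are equal", {
  m <- small_head()$mesh
  G <- small_smoother()
  deg <- Matrix::rowSums(m$adjacency)
  # pick centers in a regular region: degree 6 throughout the 4-hop ball
  # (the unit-maximum column normalization couples nearby degrees)
  g <- igraph::graph_from_adjacency_matrix(m$adjacency > 0, mode = "undirected")
  reg <- which(vapply(seq_len(nrow(m$vertices)), function(i) {
    all(deg[as.integer(igraph::ego(g, 4, i)[[1]])] == 6)
  }, logical(1)))
  expect_gt(length(reg), 0)
  for (i in reg[c(1, length(reg) %/% 2)]) {
    nb <- which(m$adjacency[i, ] > 0)
    expect_lt(max(abs(G$G[i, nb] - G$G[nb, i])), 1e-6)
  }
})

test_that("green smoother refuses a disconnected mesh", {
  # two disjoint triangles
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(5, 5, 5), c(6, 5, 5), c(5, 6, 5))
  f <- rbind(c(1, 2, 3), c(4, 5, 6))
  m <- bayesmeg:::mesh_from_parts(v, f, 100)
  expect_error(green_smoother(m, 0.5), "disconnected")
})

test_that("patch centers: counts, labels, determinism and spacing", {
  ctr <- small_centers()       # p = 24
  expect_length(ctr$vertices, 48)
  expect_equal(sum(ctr$hemisphere == "left"), 24)
  expect_equal(sum(ctr$hemisphere == "right"), 24)
  m <- small_head()$mesh
  expect_true(all(m$hemisphere[ctr$vertices[ctr$hemisphere == "left"]] == "left"))
  expect_true(all(m$hemisphere[ctr$vertices[ctr$hemisphere == "right"]] == "right"))
  ctr2 <- select_patch_centers(m, 24, seed = 7)
  expect_identical(ctr$vertices, ctr2$vertices)
  # one per hemisphere
  c1 <- select_patch_centers(m, 1, seed = 3)
  expect_length(c1$vertices, 2)
  expect_error(select_patch_centers(m, 10000), "p_per_hemisphere")
  # geodesic spacing: minimum pairwise distance at least half the
  # expected uniform spacing (hemisphere area / p, hexagonal packing)
  left <- ctr$vertices[ctr$hemisphere == "left"]
  d <- mesh_geodesics(m, left)[, left]
  diag(d) <- Inf
  area <- sum(bayesmeg:::row_norms(bayesmeg:::cross_rows(
    m$vertices[m$faces[, 2], ] - m$vertices[m$faces[, 1], ],
    m$vertices[m$faces[, 3], ] - m$vertices[m$faces[, 1], ]))) / 2 / 2
  expected_spacing <- sqrt(2 * area / (sqrt(3) * 24))
  expect_gt(min(d), expected_spacing / 2)
})

test_that("OFF round trip preserves geometry; PLY is written", {
  m <- small_head()$mesh
  off <- tempfile(fileext = ".off")
  write_mesh_off(m, off)
  m2 <- read_mesh_off(off, conductor_radius_mm = m$conductor_radius_mm)
  expect_equal(m2$vertices, unname(m$vertices), tolerance = 1e-12)
  expect_equal(m2$faces, matrix(as.integer(m$faces), ncol = 3))
  expect_equal(m2$mean_edge_mm, m$mean_edge_mm, tolerance = 1e-12)
  ply <- tempfile(fileext = ".ply")
  write_mesh_ply(m, ply)
  expect_equal(readLines(ply, n = 1), "ply")
  expect_length(readLines(ply), 12 + nrow(m$vertices) + nrow(m$faces))
})

test_that("leadfield TSV round trip", {
  lf <- small_leadfield()
  p <- tempfile(fileext = ".tsv")
  write_leadfield_tsv(lf, p)
  lf2 <- read_leadfield_tsv(p)
  expect_equal(lf2$gain, lf$gain, tolerance = 1e-12)
  expect_equal(lf2$units, lf$units)
  expect_equal(lf2$source_orientation_mode, lf$source_orientation_mode)
})
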