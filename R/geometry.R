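#' Synthetic head geometry for MEG simulation benches
#'
#' Builds a two-hemisphere cortical-like source mesh (a subdivided
#' icosahedron with a seeded radial "folding" perturbation, so that vertex
#' normals are not purely radial) inside a spherical volume conductor, and a
#' helmet of tangentially-oriented point magnetometers surrounding it.
#'
#' The perturbation emulates cortical folding: a band-limited random radial
#' displacement field, mirror-symmetric about the mid-sagittal plane
#' (`x = 0`), whose spatial wavelength tracks the mesh resolution so every
#' generated mesh resolves its own folds.  At the default resolution
#' (`n_vertices = 8196`, snapped to the nearest icosphere size) and a 71 mm
#' cortical radius the folded surface has a mean inter-vertex spacing of
#' about 5 mm.
#'
#' @param n_vertices requested number of mesh vertices (>= 12); snapped to
#'   the nearest subdivided-icosahedron size (12, 42, 162, 642, 2562,
#'   10242, ...).
#' @param cortex_radius_mm nominal (unfolded) cortical sphere radius in mm.
#' @param conductor_radius_mm radius of the spherical volume conductor in
#'   mm; must exceed the largest folded cortical radius.
#' @param n_sensors number of point magnetometers (>= 16).
#' @param seed integer seed; identical seeds give byte-identical geometry.
#' @param wrinkle_amplitude relative amplitude of the radial folding field
#'   (0 disables folding and yields a perfect sphere with radial normals).
#' @param wrinkle_cycles number of folding wavelengths across the mesh:
#'   the folding wavelength is `wrinkle_cycles` mean base edges.
#'
#' @return a list with elements `mesh` (a `source_mesh`) and `sensors`
#'   (a `sensor_array`).
#' @export
build_synthetic_head <- function(n_vertices = 8196,
                                 cortex_radius_mm = 71,
                                 conductor_radius_mm = 95,
                                 n_sensors = 275,
                                 seed = 1L,
                                 wrinkle_amplitude = 0.13,
                                 wrinkle_cycles = 5.5) {
  check_scalar(n_vertices, "n_vertices", lower = 12)
  check_scalar(cortex_radius_mm, "cortex_radius_mm", lower = 1)
  check_scalar(conductor_radius_mm, "conductor_radius_mm", lower = 1)
  check_scalar(n_sensors, "n_sensors", lower = 16)
  if (cortex_radius_mm >= conductor_radius_mm) {
    stop_param("cortex_radius_mm must be smaller than conductor_radius_mm")
  }
  mesh <- build_source_mesh(n_vertices, cortex_radius_mm, conductor_radius_mm,
                            seed, wrinkle_amplitude, wrinkle_cycles)
  sensors <- build_sensor_array(n_sensors, conductor_radius_mm, seed)
  list(mesh = mesh, sensors = sensors)
}

# ---- icosphere ------------------------------------------------------------

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- normalize_rows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(vertices = v, faces = f)
}

# One midpoint-subdivision step on the unit sphere (vectorized).
subdivide_once <- function(v, f) {
  nv <- nrow(v)
  ea <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- pmin(ea[, 1], ea[, 2]) * (nv + 1) + pmax(ea[, 1], ea[, 2])
  ukey <- unique(key)
  idx <- match(key, ukey)
  first <- match(ukey, key)
  mids <- (v[ea[first, 1], , drop = FALSE] + v[ea[first, 2], , drop = FALSE]) / 2
  mids <- normalize_rows(mids)
  mid_id <- nv + idx
  nf <- nrow(f)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m31 <- mid_id[2 * nf + seq_len(nf)]
  faces <- rbind(
    cbind(f[, 1], m12, m31),
    cbind(f[, 2], m23, m12),
    cbind(f[, 3], m31, m23),
    cbind(m12, m23, m31)
  )
  list(vertices = rbind(v, mids), faces = faces)
}

icosphere <- function(level) {
  m <- icosahedron()
  for (i in seq_len(level)) m <- subdivide_once(m$vertices, m$faces)
  m
}

icosphere_level_for <- function(n_vertices) {
  sizes <- 10 * 4^(0:7) + 2
  which.min(abs(sizes - n_vertices)) - 1L
}

# ---- folding field --------------------------------------------------------

# Band-limited random field on the unit sphere from a superposition of
# plane waves, symmetrized about x = 0 and standardized to unit sd.
folding_field <- function(dirs, mirror_index, kappa, n_waves = 48L) {
  u <- normalize_rows(matrix(rnorm(n_waves * 3), ncol = 3))
  amp <- rnorm(n_waves)
  ph <- runif(n_waves, 0, 2 * pi)
  g <- (cos(kappa * (dirs %*% t(u)) + rep(ph, each = nrow(dirs))) %*% amp)[, 1]
  g <- (g + g[mirror_index]) / 2
  g <- g - mean(g)
  g <- g / max(sd(g), .Machine$double.eps)
  # soft-limit extreme excursions so folds stay inside the conductor
  2 * tanh(g / 2)
}

mirror_match <- function(dirs, tol = 1e-8) {
  key <- function(m) paste(round(m[, 1] / tol), round(m[, 2] / tol),
                           round(m[, 3] / tol))
  idx <- match(key(cbind(-dirs[, 1], dirs[, 2], dirs[, 3])), key(dirs))
  if (anyNA(idx)) stop("mesh is not mirror-symmetric about x = 0")
  idx
}

# ---- mesh construction ----------------------------------------------------

vertex_normals <- function(vertices, faces) {
  e1 <- vertices[faces[, 2], ] - vertices[faces[, 1], ]
  e2 <- vertices[faces[, 3], ] - vertices[faces[, 1], ]
  fn <- cross_rows(e1, e2)  # area-weighted face normals
  n <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    for (ax in 1:3) {
      acc <- rowsum(fn[, ax], faces[, k])
      n[as.integer(rownames(acc)), ax] <- n[as.integer(rownames(acc)), ax] + acc
    }
  }
  normalize_rows(n)
}

mesh_adjacency <- function(nv, faces) {
  ea <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  i <- c(ea[, 1], ea[, 2])
  j <- c(ea[, 2], ea[, 1])
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(nv, nv))
  methods::as(methods::as(a > 0, "dMatrix"), "CsparseMatrix")
}

mesh_edges <- function(faces) {
  ea <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  ea <- cbind(pmin(ea[, 1], ea[, 2]), pmax(ea[, 1], ea[, 2]))
  unique(ea)
}

build_source_mesh <- function(n_vertices, cortex_radius_mm, conductor_radius_mm,
                              seed, wrinkle_amplitude, wrinkle_cycles) {
  level <- icosphere_level_for(n_vertices)
  ico <- icosphere(level)
  dirs <- ico$vertices
  mirror_index <- mirror_match(dirs)
  # mean base edge (arc) length on the unfolded sphere, in mm
  edges <- mesh_edges(ico$faces)
  base_edge <- mean(sqrt(rowSums((dirs[edges[, 1], ] - dirs[edges[, 2], ])^2))) *
    cortex_radius_mm
  radius <- rep(cortex_radius_mm, nrow(dirs))
  if (wrinkle_amplitude > 0) {
    kappa <- 2 * pi * cortex_radius_mm / (wrinkle_cycles * base_edge)
    g <- with_local_seed(seed, folding_field(dirs, mirror_index, kappa))
    radius <- cortex_radius_mm * (1 + wrinkle_amplitude * g)
  }
  vertices <- dirs * radius
  if (any(row_norms(vertices) >= conductor_radius_mm)) {
    stop_param("folded cortex exceeds the conductor sphere; reduce wrinkle_amplitude")
  }
  normals <- vertex_normals(vertices, ico$faces)
  hemisphere <- ifelse(dirs[, 1] < 0, "left", "right")
  edge_len <- sqrt(rowSums((vertices[edges[, 1], ] - vertices[edges[, 2], ])^2))
  mesh <- structure(list(
    vertices = vertices,
    faces = ico$faces,
    normals = normals,
    hemisphere = hemisphere,
    adjacency = mesh_adjacency(nrow(vertices), ico$faces),
    mean_edge_mm = mean(edge_len),
    mirror_index = mirror_index,
    base_dirs = dirs,
    conductor_center = c(0, 0, 0),
    conductor_radius_mm = conductor_radius_mm,
    seed = seed
  ), class = "source_mesh")
  mesh
}

#' @export
print.source_mesh <- function(x, ...) {
  cat(sprintf("source_mesh: %d vertices, %d faces, mean edge %.2f mm, conductor %.0f mm\n",
              nrow(x$vertices), nrow(x$faces), x$mean_edge_mm, x$conductor_radius_mm))
  invisible(x)
}

# ---- sensors --------------------------------------------------------------

build_sensor_array <- function(n_sensors, conductor_radius_mm, seed) {
  r <- conductor_radius_mm * 1.3
  n <- as.integer(n_sensors)
  # Fibonacci-spiral coverage of a helmet-like spherical cap z/r > -0.35
  k <- seq_len(n)
  z <- 1 - 1.35 * (k - 0.5) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  az <- golden * (k - 1)
  pos <- r * cbind(rho * cos(az), rho * sin(az), z)
  rad <- normalize_rows(pos)
  # tangential orientations: seeded angle in the local tangent plane
  ref <- cbind(-rad[, 2], rad[, 1], 0)
  deg <- row_norms(ref) < 1e-8
  ref[deg, ] <- c(1, 0, 0)
  east <- normalize_rows(ref - rad * rowSums(ref * rad))
  north <- cross_rows(rad, east)
  alpha <- with_local_seed(seed, runif(n, 0, 2 * pi))
  orient <- east * cos(alpha) + north * sin(alpha)
  structure(list(
    positions = pos,
    orientations = orient,
    conductor_center = c(0, 0, 0),
    conductor_radius_mm = conductor_radius_mm
  ), class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("sensor_array: %d point magnetometers, conductor radius %.0f mm\n",
              nrow(x$positions), x$conductor_radius_mm))
  invisible(x)
}

# ---- graph helpers --------------------------------------------------------

# Weighted mesh graph (edge weights = Euclidean edge lengths in mm),
# memoized on the mesh object environment.
mesh_graph <- function(mesh) {
  cache <- attr(mesh, "graph_cache")
  if (!is.null(cache) && !is.null(cache$graph)) return(cache$graph)
  edges <- mesh_edges(mesh$faces)
  w <- sqrt(rowSums((mesh$vertices[edges[, 1], ] - mesh$vertices[edges[, 2], ])^2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

#' Geodesic distances along the mesh surface
#'
#' Shortest-path distances (mm) along mesh edges from a set of source
#' vertices to every vertex.
#'
#' @param mesh a `source_mesh`.
#' @param from integer vertex indices.
#' @return a `length(from)` x `n_vertices` matrix of distances in mm.
#' @export
mesh_geodesics <- function(mesh, from) {
  g <- mesh_graph(mesh)
  igraph::distances(g, v = from)
}

hemisphere_connected <- function(mesh) {
  g <- mesh_graph(mesh)
  ok <- TRUE
  for (h in c("left", "right")) {
    sub <- igraph::induced_subgraph(g, which(mesh$hemisphere == h))
    ok <- ok && igraph::is_connected(sub)
  }
  ok
}
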