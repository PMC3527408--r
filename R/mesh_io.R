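#' Mesh export and import (ASCII OFF / PLY)
#'
#' Plain-text mesh interchange.  OFF files round-trip vertices and faces;
#' the PLY writer additionally stores per-vertex normals.  Hemisphere
#' labels, adjacency and conductor geometry are reconstructed on read
#' (labels from the sign of `x`), so a round-tripped mesh is usable by the
#' forward model but does not carry the generator's seed.
#'
#' @param mesh a `source_mesh`.
#' @param path file path.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  write.table(format(mesh$vertices, digits = 17, trim = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  write.table(cbind(3L, mesh$faces - 1L), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mesh_off
#' @param conductor_radius_mm conductor radius to attach on read.
#' @export
read_mesh_off <- function(path, conductor_radius_mm = 95) {
  lines <- readLines(path)
  stopifnot(lines[1] == "OFF")
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  vert <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE), nv, 3, byrow = TRUE)
  fr <- matrix(scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE),
               nf, 4, byrow = TRUE)
  faces <- fr[, 2:4, drop = FALSE] + 1L
  mesh_from_parts(vert, faces, conductor_radius_mm)
}

#' @rdname write_mesh_off
#' @export
write_mesh_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               "property double nx", "property double ny", "property double nz",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  write.table(format(cbind(mesh$vertices, mesh$normals), digits = 17, trim = TRUE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  write.table(cbind(3L, mesh$faces - 1L), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Rebuild derived mesh structure from raw vertices/faces.
mesh_from_parts <- function(vertices, faces, conductor_radius_mm) {
  storage.mode(faces) <- "integer"
  edges <- mesh_edges(faces)
  edge_len <- sqrt(rowSums((vertices[edges[, 1], ] - vertices[edges[, 2], ])^2))
  structure(list(
    vertices = vertices,
    faces = faces,
    normals = vertex_normals(vertices, faces),
    hemisphere = ifelse(vertices[, 1] < 0, "left", "right"),
    adjacency = mesh_adjacency(nrow(vertices), faces),
    mean_edge_mm = mean(edge_len),
    mirror_index = NULL,
    base_dirs = normalize_rows(vertices),
    conductor_center = c(0, 0, 0),
    conductor_radius_mm = conductor_radius_mm,
    seed = NA_integer_
  ), class = "source_mesh")
}
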