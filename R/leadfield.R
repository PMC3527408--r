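#' Single-sphere MEG leadfield (Sarvas closed form)
#'
#' Computes the gain matrix mapping unit-moment dipoles at the mesh
#' vertices (oriented along the vertex normals) to the magnetic field
#' component along each sensor's orientation, using the closed-form
#' magnetic field of a current dipole in a homogeneous spherical volume
#' conductor.  Radially-oriented dipoles are magnetically silent, a
#' property of the spherical conductor that the closed form reproduces
#' exactly.
#'
#' @param mesh a `source_mesh`.
#' @param sensors a `sensor_array` sharing the mesh's conductor sphere.
#' @param orientations optional `n_vertices x 3` dipole orientation matrix;
#'   defaults to the mesh vertex normals (fixed-orientation model).
#' @return a `leadfield` object with `gain` (`n_sensors x n_vertices`,
#'   fT per nAm) and `source_orientation_mode`.
#' @export
compute_leadfield <- function(mesh, sensors, orientations = NULL) {
  stopifnot(inherits(mesh, "source_mesh"), inherits(sensors, "sensor_array"))
  if (is.null(orientations)) orientations <- mesh$normals
  rpos <- sweep(mesh$vertices, 2, mesh$conductor_center)  # dipole positions
  spos <- sweep(sensors$positions, 2, mesh$conductor_center)
  if (any(row_norms(rpos) < 1e-6)) {
    stop_param("dipole at the conductor center: field is undefined")
  }
  if (any(row_norms(spos) <= mesh$conductor_radius_mm)) {
    stop_param("sensor inside the conductor sphere")
  }
  gain <- sarvas_gain(rpos, orientations, spos, sensors$orientations)
  structure(list(
    gain = gain,
    source_orientation_mode = "fixed-normal",
    units = "fT/nAm"
  ), class = "leadfield")
}

# Sarvas field of current dipoles in a sphere centred at the origin.
# r0: v x 3 dipole positions (mm); q: v x 3 unit moments (interpreted in
# nAm); r: n x 3 sensor positions (mm); ori: n x 3 sensor orientations.
# Returns n x v matrix in fT per nAm.
sarvas_gain <- function(r0, q, r, ori) {
  mm <- 1e-3
  r0 <- r0 * mm
  r <- r * mm
  qm <- q * 1e-9                     # 1 nAm moment
  qxr0 <- cross_rows(qm, r0)         # v x 3
  n <- nrow(r)
  v <- nrow(r0)
  out <- matrix(0, n, v)
  mu0_4pi <- 1e-7
  for (i in seq_len(n)) {
    ri <- r[i, ]
    Rn <- sqrt(sum(ri^2))
    avec <- matrix(ri, v, 3, byrow = TRUE) - r0  # r - r0
    a <- row_norms(avec)
    adotr <- avec %*% ri
    r0dotr <- r0 %*% ri
    Fv <- a * (Rn * a + Rn^2 - r0dotr)
    c1 <- a^2 / Rn + adotr / a + 2 * a + 2 * Rn
    c2 <- a + 2 * Rn + adotr / a
    gradF <- outer(c(c1), ri) - c(c2) * r0       # v x 3
    qxr0_dot_r <- qxr0 %*% ri
    Bv <- (c(Fv) * qxr0 - c(qxr0_dot_r) * gradF) / c(Fv^2)
    out[i, ] <- mu0_4pi * (Bv %*% ori[i, ])
  }
  out * 1e15
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("leadfield: %d sensors x %d sources (%s), %s orientation\n",
              nrow(x$gain), ncol(x$gain), x$units, x$source_orientation_mode))
  invisible(x)
}

#' Write / read a gain matrix as TSV
#'
#' Plain-text container for leadfield gain matrices: one sensor per row,
#' one source per column, with a one-line `#` header carrying units and
#' orientation mode.
#'
#' @param lf a `leadfield`.
#' @param path output file path.
#' @export
write_leadfield_tsv <- function(lf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bayesmeg leadfield\tunits=%s\tmode=%s",
                     lf$units, lf$source_orientation_mode), con)
  write.table(lf$gain, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_leadfield_tsv
#' @param path input file path.
#' @export
read_leadfield_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  fields <- strsplit(sub("^# bayesmeg leadfield\t", "", header), "\t")[[1]]
  kv <- strsplit(fields, "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  gain <- as.matrix(read.table(path, sep = "\t", skip = 1L))
  dimnames(gain) <- NULL
  structure(list(gain = gain,
                 source_orientation_mode = unname(meta["mode"]),
                 units = unname(meta["units"])), class = "leadfield")
}
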