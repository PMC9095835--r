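# Toy head geometry: icosphere cortical mesh, Fibonacci electrode montage,
# homogeneous spherical conductor. Units are mm throughout.

#' Build an icosphere cortical mesh
#'
#' Constructs a triangulated sphere by recursive 4-way subdivision of a
#' regular icosahedron, giving `10 * 4^level + 2` vertices, scaled to the
#' requested cortical radius. Dipole orientations are the outward unit vertex
#' normals (area-weighted face-normal average, radial for a sphere).
#'
#' @param subdivision_level integer in 0..5; level 0 is the icosahedron
#'   (12 vertices), level 3 (default) gives 642 vertices.
#' @param cortical_radius sphere radius in mm (default 70).
#' @return An object of class `cortical_mesh` with fields `vertices`
#'   (n x 3, mm), `faces` (m x 3, 1-based vertex indices), `normals`
#'   (n x 3 unit vectors), `n_vertices`, `radius`.
#' @examples
#' m <- build_toy_mesh(0)
#' m$n_vertices # 12
#' @export
build_toy_mesh <- function(subdivision_level = 3L, cortical_radius = 70) {
  if (!is.numeric(subdivision_level) || length(subdivision_level) != 1 ||
      subdivision_level != round(subdivision_level) ||
      subdivision_level < 0 || subdivision_level > 5) {
    stop_param("subdivision_level must be an integer in 0..5 (got %s)",
               format(subdivision_level))
  }
  if (!is.numeric(cortical_radius) || cortical_radius <= 0) {
    stop_param("cortical_radius must be positive")
  }
  ico <- icosahedron()
  v <- ico$vertices
  f <- ico$faces
  for (i in seq_len(subdivision_level)) {
    sub <- subdivide_once(v, f)
    v <- sub$vertices
    f <- sub$faces
  }
  v <- v / sqrt(rowSums(v^2)) * cortical_radius
  storage.mode(f) <- "integer"
  dimnames(f) <- NULL
  mesh <- structure(
    list(
      vertices = v,
      faces = f,
      normals = vertex_normals(v, f),
      n_vertices = nrow(v),
      radius = cortical_radius
    ),
    class = "cortical_mesh"
  )
  mesh
}

# Regular icosahedron on the unit sphere, consistent outward winding.
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(vertices = v, faces = f)
}

# One 4-way ("Loop") subdivision step; midpoints re-projected onto the
# unit sphere, shared-edge midpoints deduplicated by edge key.
subdivide_once <- function(v, f) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "_")
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ek <- key(edges[, 1], edges[, 2])
  uk <- unique(ek)
  idx <- match(ek, uk)
  ue <- edges[!duplicated(ek), , drop = FALSE]
  mid <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  mid <- mid / sqrt(rowSums(mid^2))
  n0 <- nrow(v)
  vv <- rbind(v, mid)
  m12 <- n0 + idx[seq_len(nrow(f))]
  m23 <- n0 + idx[nrow(f) + seq_len(nrow(f))]
  m31 <- n0 + idx[2 * nrow(f) + seq_len(nrow(f))]
  ff <- rbind(
    cbind(f[, 1], m12, m31),
    cbind(f[, 2], m23, m12),
    cbind(f[, 3], m31, m23),
    cbind(m12, m23, m31)
  )
  list(vertices = vv, faces = ff)
}

# Area-weighted vertex normals from face cross products, unit-normalized.
vertex_normals <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    for (c in 1:3) {
      n[, c] <- n[, c] + tabulate2(f[, k], fn[, c], nrow(v))
    }
  }
  n / sqrt(rowSums(n^2))
}

# sum `w` into bins `i` of length n (rowsum without dimnames fuss)
tabulate2 <- function(i, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, i)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Unique undirected edges of a mesh
#' @param mesh a `cortical_mesh`
#' @return 2-column integer matrix, one row per unique edge
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(paste(e[, 1], e[, 2])), , drop = FALSE]
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf(
    "cortical_mesh: %d vertices, %d faces, radius %.1f mm\n",
    x$n_vertices, nrow(x$faces), x$radius
  ))
  invisible(x)
}

#' Place electrodes quasi-uniformly on the scalp sphere
#'
#' Deterministic Fibonacci (golden-angle) lattice on the sphere of the given
#' radius. Labels are "E001", "E002", ...
#'
#' @param n_channels number of electrodes, at least 8
#' @param scalp_radius scalp sphere radius in mm (default 90)
#' @return An `electrode_montage` with `labels` and `positions` (n x 3, mm).
#' @export
place_electrodes <- function(n_channels, scalp_radius = 90) {
  if (!is.numeric(n_channels) || n_channels < 8 ||
      n_channels != round(n_channels)) {
    stop_param("n_channels must be an integer >= 8 (got %s)", format(n_channels))
  }
  n <- as.integer(n_channels)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  theta <- golden * (i - 0.5)
  pos <- cbind(r * cos(theta), r * sin(theta), z) * scalp_radius
  dimnames(pos) <- NULL
  structure(
    list(
      labels = sprintf("E%03d", seq_len(n)),
      positions = pos,
      scalp_radius = scalp_radius
    ),
    class = "electrode_montage"
  )
}

#' @export
print.electrode_montage <- function(x, ...) {
  cat(sprintf(
    "electrode_montage: %d channels on a %.1f mm sphere\n",
    length(x$labels), x$scalp_radius
  ))
  invisible(x)
}

#' Homogeneous spherical conductor model
#'
#' @param center 3-vector, mm (default origin)
#' @param scalp_radius sphere radius in mm (default 90)
#' @param conductivity homogeneous conductivity in S/m (default 0.33, the
#'   conventional brain/scalp value)
#' @return A `sphere_model`.
#' @export
sphere_model <- function(center = c(0, 0, 0), scalp_radius = 90,
                         conductivity = 0.33) {
  if (scalp_radius <= 0) stop_param("scalp_radius must be positive")
  if (conductivity <= 0) stop_param("conductivity must be positive")
  structure(
    list(center = as.numeric(center), scalp_radius = scalp_radius,
         conductivity = conductivity),
    class = "sphere_model"
  )
}

#' Write / read a mesh as Wavefront OBJ
#'
#' Only `v` and `f` records are used; normals are recomputed on load.
#' @param mesh a `cortical_mesh`
#' @param path file path
#' @return `read_mesh_obj` returns a `cortical_mesh`.
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_mesh_obj
#' @export
read_mesh_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
    as.integer(sub("/.*", "", x[2:4]))
  }))
  structure(
    list(
      vertices = v, faces = f, normals = vertex_normals(v, f),
      n_vertices = nrow(v), radius = mean(sqrt(rowSums(v^2)))
    ),
    class = "cortical_mesh"
  )
}

#' Write / read an electrode montage as sfp-style text
#'
#' Whitespace-delimited `label x y z` rows, coordinates in mm.
#' @param montage an `electrode_montage`
#' @param path file path
#' @export
write_montage_sfp <- function(montage, path) {
  writeLines(sprintf("%s\t%.9g\t%.9g\t%.9g", montage$labels,
                     montage$positions[, 1], montage$positions[, 2],
                     montage$positions[, 3]), path)
  invisible(path)
}

#' @rdname write_montage_sfp
#' @export
read_montage_sfp <- function(path) {
  tab <- utils::read.table(path, col.names = c("label", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  pos <- as.matrix(tab[, c("x", "y", "z")])
  dimnames(pos) <- NULL
  structure(
    list(labels = tab$label, positions = pos,
         scalp_radius = mean(sqrt(rowSums(pos^2)))),
    class = "electrode_montage"
  )
}
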