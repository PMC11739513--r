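#' Triangulated organ volume
#'
#' A `volume_mesh` is a closed (watertight) triangulated surface bounding the
#' organ domain. Vertices are in millimetres. The enclosed volume is computed
#' by the divergence theorem over signed tetrahedra and the inside test uses
#' the generalized winding number, which is robust to near-degenerate
#' triangles and insensitive to triangle ordering.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices with outward
#'   consistent orientation.
#' @param validate check watertightness and positive volume (default `TRUE`).
#' @return an object of class `volume_mesh` with elements `vertices`, `faces`.
#' @export
volume_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "volume_mesh")
  if (validate) {
    n_open <- count_open_edges(mesh)
    if (n_open > 0L) {
      stop("surface is not watertight: ", n_open,
           " edge(s) are not shared by exactly 2 faces", call. = FALSE)
    }
    v <- mesh_volume(mesh)
    if (v <= 0) {
      # flip orientation rather than fail if the surface is merely inverted
      if (v < 0) {
        mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
      } else {
        stop("mesh encloses zero volume", call. = FALSE)
      }
    }
  }
  mesh
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat(sprintf("<volume_mesh> %d vertices, %d faces, volume %.4g mm^3\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

# number of edges not shared by exactly two faces
count_open_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  sum(table(key) != 2L)
}

#' Enclosed volume of a closed surface
#'
#' Signed volume by summing tetrahedra (origin, a, b, c) over all faces.
#'
#' @param mesh a [volume_mesh()].
#' @return volume in mm^3 (signed; positive for outward orientation).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cr)) / 6
}

#' Uniformly scale a mesh to a target enclosed volume
#'
#' Scaling is about the volumetric centroid, so the shape and position are
#' preserved while the enclosed volume is matched exactly (cube-root law).
#'
#' @param mesh a [volume_mesh()]; must be watertight.
#' @param target target volume in mm^3 (> 0).
#' @return a new `volume_mesh` with enclosed volume equal to `target`.
#' @export
scale_to_volume <- function(mesh, target) {
  stopifnot(is.numeric(target), length(target) == 1, target > 0)
  n_open <- count_open_edges(mesh)
  if (n_open > 0L) {
    stop("surface is not watertight: ", n_open,
         " edge(s) are not shared by exactly 2 faces", call. = FALSE)
  }
  v0 <- mesh_volume(mesh)
  if (v0 <= 0) stop("mesh encloses zero or negative volume", call. = FALSE)
  s <- (target / v0)^(1 / 3)
  ctr <- mesh_centroid(mesh)
  verts <- sweep(sweep(mesh$vertices, 2, ctr, "-") * s, 2, ctr, "+")
  volume_mesh(verts, mesh$faces, validate = FALSE)
}

# volumetric centroid (first moment of the enclosed solid)
mesh_centroid <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  w <- rowSums(a * cr) / 6            # signed tet volumes
  tc <- (a + b + c_) / 4              # tet centroids (4th vertex = origin)
  colSums(tc * w) / sum(w)
}

#' Axis-aligned bounding box of a mesh
#'
#' @param mesh a [volume_mesh()].
#' @return 2 x 3 matrix with rows `min`, `max`.
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min),
        max = apply(mesh$vertices, 2, max))
}

#' Generalized winding number inside test
#'
#' Sums the signed solid angle subtended by every face at each query point
#' (van Oosterom-Strackee formula). Points with winding number close to 1
#' (total solid angle 4*pi) are inside.
#'
#' @param mesh a [volume_mesh()].
#' @param points numeric matrix, q x 3 query points (mm).
#' @return logical vector of length q.
#' @export
points_inside <- function(mesh, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  q <- nrow(points)
  if (q == 0L) return(logical(0))
  wn <- numeric(q)
  v <- mesh$vertices
  f <- mesh$faces
  px <- points[, 1]; py <- points[, 2]; pz <- points[, 3]
  for (i in seq_len(nrow(f))) {
    ax <- v[f[i, 1], 1] - px; ay <- v[f[i, 1], 2] - py; az <- v[f[i, 1], 3] - pz
    bx <- v[f[i, 2], 1] - px; by <- v[f[i, 2], 2] - py; bz <- v[f[i, 2], 3] - pz
    cx <- v[f[i, 3], 1] - px; cy <- v[f[i, 3], 2] - py; cz <- v[f[i, 3], 3] - pz
    la <- sqrt(ax * ax + ay * ay + az * az)
    lb <- sqrt(bx * bx + by * by + bz * bz)
    lc <- sqrt(cx * cx + cy * cy + cz * cz)
    num <- ax * (by * cz - bz * cy) +
           ay * (bz * cx - bx * cz) +
           az * (bx * cy - by * cx)
    den <- la * lb * lc +
           (ax * bx + ay * by + az * bz) * lc +
           (bx * cx + by * cy + bz * cz) * la +
           (cx * ax + cy * ay + cz * az) * lb
    wn <- wn + 2 * atan2(num, den)
  }
  wn / (4 * pi) > 0.5
}

#' Synthetic triaxial ellipsoid volume
#'
#' Builds an icosphere-subdivision ellipsoid with semi-axis ratio 2:1.2:0.8
#' scaled to a target volume. This is the built-in stand-in geometry, shaped
#' to be elongated and flattened like a liver, so that every example and test
#' runs without downloading an organ mesh.
#'
#' @param target_volume enclosed volume in mm^3 (default 1.6e6, i.e. 1.6 L,
#'   the mean healthy human liver volume used for the boundary conditions).
#' @param subdivisions icosphere subdivision level (default 2, 320 faces).
#' @param axes semi-axis ratio, length 3.
#' @return a [volume_mesh()].
#' @export
ellipsoid_mesh <- function(target_volume = 1.6e6, subdivisions = 2,
                           axes = c(2, 1.2, 0.8)) {
  stopifnot(length(axes) == 3, all(axes > 0), target_volume > 0)
  ico <- icosphere(subdivisions)
  verts <- sweep(ico$vertices, 2, axes, "*")
  scale_to_volume(volume_mesh(verts, ico$faces, validate = FALSE),
                  target_volume)
}

# unit icosphere by repeated triangle subdivision of an icosahedron
icosphere <- function(subdivisions = 2) {
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  verts <- verts / sqrt(rowSums(verts^2))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    vlist <- lapply(seq_len(nrow(verts)), function(i) verts[i, ])
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- edge_mid[[key]]
      if (is.null(idx)) {
        m <- (vlist[[i]] + vlist[[j]]) / 2
        m <- m / sqrt(sum(m^2))
        vlist[[length(vlist) + 1]] <<- m
        idx <- length(vlist)
        edge_mid[[key]] <- idx
      }
      idx
    }
    new_faces <- matrix(0L, nrow(faces) * 4, 3)
    r <- 1L
    for (i in seq_len(nrow(faces))) {
      a <- faces[i, 1]; b <- faces[i, 2]; c_ <- faces[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      new_faces[r, ] <- c(a, ab, ca)
      new_faces[r + 1L, ] <- c(b, bc, ab)
      new_faces[r + 2L, ] <- c(c_, ca, bc)
      new_faces[r + 3L, ] <- c(ab, bc, ca)
      r <- r + 4L
    }
    verts <- do.call(rbind, vlist)
    faces <- new_faces
  }
  list(vertices = verts, faces = faces)
}
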