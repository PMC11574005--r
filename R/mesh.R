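#' Surface meshes with spherical topology
#'
#' A `surface_mesh` is a closed, orientable triangulated 2-manifold of genus
#' zero (Euler characteristic V - E + F = 2). Vertices are 3-D points in mm;
#' faces are triples of 1-based vertex indices with consistent
#' (counter-clockwise, outward-normal) winding.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param structure_name label of the anatomical structure.
#' @param hemisphere `"left"` or `"right"`.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, structure_name = "sphere",
                         hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  storage.mode(vertices) <- "double"
  structure(
    list(vertices = vertices, faces = faces,
         structure_name = structure_name, hemisphere = hemisphere),
    class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %s (%s): %d vertices, %d faces\n",
              x$structure_name, x$hemisphere,
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Undirected edge list of a mesh
#'
#' @param mesh a `surface_mesh`, or a faces matrix.
#' @return Integer matrix, one row per undirected edge, columns `i < j`.
#' @export
mesh_edges <- function(mesh) {
  faces <- if (inherits(mesh, "surface_mesh")) mesh$faces else mesh
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

#' Validate mesh invariants
#'
#' Checks that a mesh is a closed orientable triangulated 2-manifold of
#' spherical topology: every undirected edge is shared by exactly two faces
#' with opposite orientation, there are no degenerate or duplicate faces,
#' all indices are in range, and V - E + F = 2.
#'
#' @param mesh a `surface_mesh`.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  nv <- nrow(v)
  if (any(f < 1L) || any(f > nv))
    stop("face indices out of range [1, ", nv, "]")
  if (any(f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]))
    stop("degenerate face (repeated vertex index)")
  key <- apply(f, 1L, function(r) paste(sort(r), collapse = "-"))
  if (anyDuplicated(key)) stop("duplicate faces present")
  # directed half-edges; manifold+orientable <=> each directed edge unique
  # and each undirected edge seen exactly twice
  he <- rbind(f[, 1:2], f[, 2:3], f[, c(3L, 1L)])
  dkey <- he[, 1L] * (nv + 1) + he[, 2L]
  if (anyDuplicated(dkey))
    stop("inconsistent face winding (repeated directed edge); not orientable")
  ukey <- pmin(he[, 1L], he[, 2L]) * (nv + 1) + pmax(he[, 1L], he[, 2L])
  cnt <- table(ukey)
  if (any(cnt != 2L)) stop("mesh is not closed: boundary or non-manifold edge")
  ne <- length(cnt)
  chi <- nv - ne + nrow(f)
  if (chi != 2L)
    stop("Euler characteristic is ", chi, ", expected 2 (spherical topology)")
  invisible(TRUE)
}

# unit icosahedron (12 vertices, 20 faces), outward CCW winding
.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

# one 4-to-1 subdivision step, midpoints projected to the unit sphere
.subdivide_sphere <- function(v, f) {
  nv <- nrow(v)
  edges <- mesh_edges(f)
  mid <- (v[edges[, 1L], , drop = FALSE] + v[edges[, 2L], , drop = FALSE]) / 2
  mid <- mid / sqrt(rowSums(mid^2))
  midindex <- new.env(hash = TRUE)
  keys <- paste(edges[, 1L], edges[, 2L])
  for (i in seq_along(keys)) assign(keys[i], nv + i, envir = midindex)
  getmid <- function(a, b)
    get(paste(min(a, b), max(a, b)), envir = midindex)
  nf <- matrix(0L, nrow(f) * 4L, 3L)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1L]; b <- f[i, 2L]; cc <- f[i, 3L]
    ab <- getmid(a, b); bc <- getmid(b, cc); ca <- getmid(cc, a)
    nf[(i - 1L) * 4L + 1:4, ] <- rbind(
      c(a, ab, ca), c(ab, b, bc), c(ca, bc, cc), c(ab, bc, ca))
  }
  list(vertices = rbind(v, mid), faces = nf)
}

#' Build a triangulated sphere mesh
#'
#' Constructs a unit sphere either as a subdivided icosahedron
#' (`V = 10 * 4^s + 2` vertices at subdivision level `s`) or as a uv-sphere
#' with `rings` latitude rows of `cols` vertices plus two poles
#' (`V = rings * cols + 2`).
#'
#' @param kind `"icosphere"` or `"uv"`.
#' @param subdivisions icosphere subdivision level `s >= 0`.
#' @param rings,cols uv-sphere latitude rows and longitude columns.
#' @param n_vertices optional requested vertex count; an error is raised if
#'   the size parameters cannot realize it.
#' @param structure_name,hemisphere labels stored on the mesh.
#' @return A `surface_mesh` on the unit sphere.
#' @examples
#' m <- build_sphere_mesh("icosphere", subdivisions = 1)
#' nrow(m$vertices)  # 42
#' @export
build_sphere_mesh <- function(kind = c("icosphere", "uv"), subdivisions = 0L,
                              rings = 8L, cols = 12L, n_vertices = NULL,
                              structure_name = "sphere",
                              hemisphere = "left") {
  kind <- match.arg(kind)
  if (kind == "icosphere") {
    if (subdivisions < 0L) stop("subdivisions must be >= 0")
    v_expect <- 10L * 4L^subdivisions + 2L
    if (!is.null(n_vertices) && n_vertices != v_expect)
      stop("icosphere at subdivision ", subdivisions, " has ", v_expect,
           " vertices, not ", n_vertices)
    m <- .icosahedron()
    s <- subdivisions
    while (s > 0L) { m <- .subdivide_sphere(m$vertices, m$faces); s <- s - 1L }
    return(surface_mesh(m$vertices, m$faces, structure_name, hemisphere))
  }
  rings <- as.integer(rings); cols <- as.integer(cols)
  if (rings < 1L || cols < 3L) stop("uv sphere needs rings >= 1, cols >= 3")
  if (!is.null(n_vertices) && rings * cols + 2L != n_vertices)
    stop("uv sphere with ", rings, " rings x ", cols, " cols has ",
         rings * cols + 2L, " vertices; cannot realize ", n_vertices)
  theta <- pi * seq_len(rings) / (rings + 1)      # polar angle per ring
  phi <- 2 * pi * (seq_len(cols) - 1L) / cols     # azimuth per column
  ring_v <- do.call(rbind, lapply(theta, function(th)
    cbind(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))))
  v <- rbind(c(0, 0, 1), ring_v, c(0, 0, -1))
  idx <- function(r, c) 1L + (r - 1L) * cols + ((c - 1L) %% cols) + 1L
  faces <- vector("list", 2L * rings)
  # top fan (north pole = 1); CCW seen from outside
  faces[[1L]] <- cbind(1L, idx(1L, seq_len(cols)), idx(1L, seq_len(cols) + 1L))
  k <- 2L
  if (rings > 1L) for (r in seq_len(rings - 1L)) {
    c1 <- seq_len(cols)
    faces[[k]] <- rbind(
      cbind(idx(r, c1), idx(r + 1L, c1), idx(r + 1L, c1 + 1L)),
      cbind(idx(r, c1), idx(r + 1L, c1 + 1L), idx(r, c1 + 1L)))
    k <- k + 1L
  }
  south <- rings * cols + 2L
  faces[[k]] <- cbind(south, idx(rings, seq_len(cols) + 1L),
                      idx(rings, seq_len(cols)))
  surface_mesh(v, do.call(rbind, faces), structure_name, hemisphere)
}

#' Deform a sphere mesh into a structure-like shape
#'
#' Applies, in order: anisotropic scaling by `axes` (semi-axis lengths in
#' mm), linear taper of the cross-section along the first axis, a circular
#' bend of the first axis in the xy-plane, and an optional smooth radial
#' jitter. Topology (the face set) is unchanged and the map is
#' deterministic given `seed`.
#'
#' Bending maps the centerline point at abscissa `x` to
#' `(rho * sin(x / rho), rho * (1 - cos(x / rho)), 0)` with
#' `rho = L / bend`, `L` the axis extent — an arc of total turning angle
#' `bend` radians that preserves centerline arc length.
#'
#' @param mesh a `surface_mesh` (typically a unit sphere).
#' @param axes length-3 positive semi-axis scale factors (mm).
#' @param taper relative widening (+) or narrowing (-) of the yz
#'   cross-section from tail to tip, in (-1, 1).
#' @param bend total bend angle in radians (0 = straight).
#' @param jitter standard deviation (mm) of a smooth random radial bump
#'   field; 0 disables it.
#' @param seed integer seed controlling the jitter field.
#' @param check_intersections if `TRUE`, run an exact triangle-triangle
#'   self-intersection test (quadratic in faces; small meshes only).
#' @return The deformed `surface_mesh`.
#' @export
deform_to_structure <- function(mesh, axes = c(1, 1, 1), taper = 0, bend = 0,
                                jitter = 0, seed = 1L,
                                check_intersections = FALSE) {
  stopifnot(length(axes) == 3L, all(axes > 0), abs(taper) < 1)
  v <- mesh$vertices
  v <- sweep(v, 2L, as.numeric(axes), `*`)
  xr <- range(v[, 1L])
  L <- diff(xr)
  if (L > 0) {
    t01 <- (v[, 1L] - xr[1L]) / L          # 0 at tail, 1 at tip
    if (taper != 0) {
      s <- 1 + taper * (t01 - 0.5)
      v[, 2L] <- v[, 2L] * s
      v[, 3L] <- v[, 3L] * s
    }
    if (bend != 0) {
      rho <- L / bend
      xc <- v[, 1L] - mean(xr)
      ang <- xc / rho
      # translate each cross-section rigidly along the bent centerline
      x_new <- (rho + v[, 2L]) * sin(ang)
      y_new <- rho - (rho + v[, 2L]) * cos(ang)
      v[, 1L] <- x_new
      v[, 2L] <- y_new
    }
  }
  if (jitter > 0) {
    # smooth field: low-order random spherical harmonics of the pre-deform
    # unit directions, deterministic under seed
    u <- mesh$vertices / sqrt(rowSums(mesh$vertices^2))
    a <- .with_seed(seed, stats::rnorm(9L))
    field <- a[1L] * u[, 1L] + a[2L] * u[, 2L] + a[3L] * u[, 3L] +
      a[4L] * u[, 1L] * u[, 2L] + a[5L] * u[, 2L] * u[, 3L] +
      a[6L] * u[, 1L] * u[, 3L] + a[7L] * (u[, 1L]^2 - u[, 2L]^2) +
      a[8L] * (3 * u[, 3L]^2 - 1) / 2 + a[9L] * (u[, 1L]^2 - u[, 3L]^2)
    n <- v / pmax(sqrt(rowSums(v^2)), 1e-12)
    v <- v + jitter * field * n
  }
  out <- surface_mesh(v, mesh$faces, mesh$structure_name, mesh$hemisphere)
  if (check_intersections && mesh_self_intersects(out))
    stop("deformation produced a self-intersecting surface")
  out
}

# exact segment-triangle intersection (Moller-Trumbore), interior hits only
.seg_tri_intersect <- function(p0, p1, a, b, c, eps = 1e-12) {
  d <- p1 - p0
  e1 <- b - a; e2 <- c - a
  h <- c(d[2] * e2[3] - d[3] * e2[2],
         d[3] * e2[1] - d[1] * e2[3],
         d[1] * e2[2] - d[2] * e2[1])
  det <- sum(e1 * h)
  if (abs(det) < eps) return(FALSE)
  s <- p0 - a
  u <- sum(s * h) / det
  if (u <= eps || u >= 1 - eps) return(FALSE)
  q <- c(s[2] * e1[3] - s[3] * e1[2],
         s[3] * e1[1] - s[1] * e1[3],
         s[1] * e1[2] - s[2] * e1[1])
  v <- sum(d * q) / det
  if (v <= eps || u + v >= 1 - eps) return(FALSE)
  t <- sum(e2 * q) / det
  t > eps && t < 1 - eps
}

#' Test a small mesh for self-intersection
#'
#' Exact edge-against-triangle test over all face pairs that share no vertex
#' and have overlapping bounding boxes. Quadratic in the number of faces;
#' intended for small meshes.
#'
#' @param mesh a `surface_mesh`.
#' @return `TRUE` if any non-adjacent face pair intersects.
#' @export
mesh_self_intersects <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  nf <- nrow(f)
  bb_lo <- t(vapply(seq_len(nf), function(i)
    pmin(v[f[i, 1L], ], v[f[i, 2L], ], v[f[i, 3L], ]), numeric(3L)))
  bb_hi <- t(vapply(seq_len(nf), function(i)
    pmax(v[f[i, 1L], ], v[f[i, 2L], ], v[f[i, 3L], ]), numeric(3L)))
  for (i in seq_len(nf - 1L)) for (j in seq.int(i + 1L, nf)) {
    if (any(bb_lo[i, ] > bb_hi[j, ] | bb_lo[j, ] > bb_hi[i, ])) next
    if (length(intersect(f[i, ], f[j, ])) > 0L) next
    ti <- f[i, ]; tj <- f[j, ]
    hit <- FALSE
    for (e in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
      if (.seg_tri_intersect(v[ti[e[1L]], ], v[ti[e[2L]], ],
                             v[tj[1L], ], v[tj[2L], ], v[tj[3L], ]) ||
          .seg_tri_intersect(v[tj[e[1L]], ], v[tj[e[2L]], ],
                             v[ti[1L], ], v[ti[2L], ], v[ti[3L], ])) {
        hit <- TRUE; break
      }
    }
    if (hit) return(TRUE)
  }
  FALSE
}
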