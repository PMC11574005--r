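#' Uniform random 3-D rotation via quaternions
#'
#' Draws a unit quaternion by normalizing a standard 4-D Gaussian draw
#' (Haar-uniform on the rotation group) and converts it to a 3 x 3 rotation
#' matrix. Uses the current RNG stream.
#'
#' @return A 3 x 3 rotation matrix (`R^T R = I`, `det R = +1`).
#' @export
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4L)
    n2 <- sum(q^2)
    if (n2 > 1e-12) { q <- q / sqrt(n2); break }
  }
  quaternion_to_rotation(q)
}

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q length-4 numeric `(w, x, y, z)`; normalized internally.
#' @return 3 x 3 rotation matrix. `(1, 0, 0, 0)` maps to the identity.
#' @export
quaternion_to_rotation <- function(q) {
  stopifnot(length(q) == 4L, sum(q^2) > 0)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3L, 3L, byrow = TRUE)
}

#' Rotate a spherical map and resample by nearest neighbour
#'
#' Each vertex `v` receives the value of the vertex whose spherical
#' registration coordinate is nearest (greatest dot product) to
#' `R %*% coords[v, ]`. Nearest-neighbour resampling keeps the null maps'
#' value set identical to the data's. The identity rotation returns the
#' input exactly.
#'
#' @param map_values per-vertex values.
#' @param sphere n x 3 matrix of unit spherical coordinates (the
#'   `sphere` element of an atlas structure).
#' @param R 3 x 3 rotation matrix.
#' @return Rotated/resampled map values.
#' @export
rotate_and_resample <- function(map_values, sphere, R) {
  sphere <- as.matrix(sphere)
  if (length(map_values) != nrow(sphere))
    stop("map length (", length(map_values),
         ") does not match sphere vertex count (", nrow(sphere), ")")
  if (max(abs(rowSums(sphere^2) - 1)) > 1e-6)
    stop("sphere coordinates are not unit vectors")
  rot <- sphere %*% t(R)          # R %*% coords(v) for each vertex (rows)
  sim <- rot %*% t(sphere)        # dot products against all source vertices
  nn <- max.col(sim, ties.method = "first")
  map_values[nn]
}

#' Spin permutation test of spatial similarity between two maps
#'
#' Computes the Pearson correlation of two vertex maps sharing one
#' spherical registration, and compares it with a null distribution built
#' by randomly rotating the first map `n_rotations` times (quaternion-
#' uniform rotations, nearest-neighbour resampling) and re-correlating.
#' Significance is two-sided on absolute correlations with the add-one
#' permutation estimator: `p = (1 + #\{|null| >= |r_obs|\}) / (1 + N)`.
#'
#' @param map_a,map_b numeric per-vertex maps (non-constant).
#' @param sphere n x 3 unit spherical coordinates shared by both maps.
#' @param n_rotations number of random rotations (>= 1).
#' @param seed integer seed; the null draws are bit-for-bit reproducible.
#' @param permutations optional precomputed rotation permutations from
#'   [spin_permutations()] (e.g. to share one rotation set across many
#'   tests of maps on the same sphere); overrides `n_rotations`/`seed`.
#' @return An object of class `spin_result`: list with `r_obs`, `null_r`,
#'   `p`, `n_rotations`, `seed`.
#' @export
spin_test <- function(map_a, map_b, sphere, n_rotations = 1000L, seed = 1L,
                      permutations = NULL) {
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0)
    stop("constant map: spatial correlation undefined")
  sphere <- as.matrix(sphere)
  if (is.null(permutations)) {
    if (n_rotations < 1L) stop("n_rotations must be >= 1")
    permutations <- spin_permutations(sphere, n_rotations, seed)
  } else {
    if (nrow(permutations) != nrow(sphere))
      stop("permutations do not match the sphere vertex count")
    n_rotations <- ncol(permutations)
    seed <- attr(permutations, "seed") %||% NA_integer_
  }
  r_obs <- stats::cor(map_a, map_b)
  nv <- nrow(sphere)
  A <- matrix(map_a[permutations], nv, n_rotations)
  null_r <- drop(stats::cor(A, map_b))
  p <- (1 + sum(abs(null_r) >= abs(r_obs))) / (1 + n_rotations)
  structure(list(r_obs = r_obs, null_r = null_r, p = p,
                 n_rotations = n_rotations, seed = seed),
            class = "spin_result")
}

#' Precompute nearest-neighbour vertex permutations for random rotations
#'
#' Draws `n_rotations` quaternion-uniform rotations and returns, for each,
#' the nearest-neighbour resampling permutation of the sphere's vertices
#' (column `k` holds the source vertex for each target vertex under
#' rotation `k`). Rotations are processed in blocks so the dominant cost is
#' one large matrix product per block.
#'
#' @param sphere n x 3 unit spherical coordinates.
#' @param n_rotations number of rotations.
#' @param seed integer seed.
#' @return Integer matrix (vertices x rotations) with attribute `seed`.
#' @export
spin_permutations <- function(sphere, n_rotations, seed = 1L) {
  sphere <- as.matrix(sphere)
  nv <- nrow(sphere)
  rotations <- .with_seed(seed,
    lapply(seq_len(n_rotations), function(k) random_rotation()))
  block <- max(1L, min(n_rotations, ceiling(8e6 / nv^2)))
  out <- matrix(NA_integer_, nv, n_rotations)
  tsph <- t(sphere)
  for (a in seq(1L, n_rotations, by = block)) {
    ks <- a:min(a + block - 1L, n_rotations)
    rc <- do.call(rbind, lapply(rotations[ks],
                                function(R) sphere %*% t(R)))
    out[, ks] <- max.col(rc %*% tsph, ties.method = "first")
  }
  attr(out, "seed") <- seed
  out
}

#' @export
print.spin_result <- function(x, ...) {
  cat(sprintf("<spin_result> r = %.3f, p = %.4g (%d rotations)\n",
              x$r_obs, x$p, x$n_rotations))
  invisible(x)
}
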