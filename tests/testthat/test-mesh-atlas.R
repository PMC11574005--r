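# mesh construction, PLY round trips, and atlas assembly

test_that("icosphere and uv-sphere meshes have the expected counts and topology", {
  ico0 <- build_sphere_mesh("icosphere", subdivisions = 0)
  expect_equal(nrow(ico0$vertices), 12L)
  expect_equal(nrow(ico0$faces), 20L)
  expect_true(validate_mesh(ico0))

  # one subdivision adds a vertex per edge: V' = V + E = 12 + 30
  ico1 <- build_sphere_mesh("icosphere", subdivisions = 1)
  expect_equal(nrow(ico1$vertices), 42L)
  expect_true(validate_mesh(ico1))

  for (m in list(ico1,
                 build_sphere_mesh("uv", rings = 5, cols = 8),
                 build_sphere_mesh("uv", rings = 12, cols = 20))) {
    V <- nrow(m$vertices); f <- nrow(m$faces); e <- nrow(mesh_edges(m))
    expect_equal(V - e + f, 2L)   # closed genus-0 surface
    expect_equal(max(abs(sqrt(rowSums(m$vertices^2)) - 1)), 0,
                 tolerance = 1e-12)
  }
  expect_equal(nrow(build_sphere_mesh("uv", rings = 5, cols = 8)$vertices),
               42L)
  expect_error(build_sphere_mesh("uv", rings = 5, cols = 8,
                                 n_vertices = 50),
               "cannot realize")
})

test_that("deformation preserves topology, is deterministic, and bends the centerline", {
  m <- build_sphere_mesh("uv", rings = 12, cols = 16)
  ident <- deform_to_structure(m, axes = c(1, 1, 1))
  expect_equal(ident$vertices, m$vertices)

  scaled <- deform_to_structure(m, axes = c(1, 1, 2))
  d <- as.matrix(dist(scaled$vertices))
  expect_equal(max(d), 4, tolerance = 1e-6)  # pole-to-pole after scaling

  a <- deform_to_structure(m, axes = c(3, 1, 1), bend = 0.8, taper = 0.2,
                           jitter = 0.1, seed = 11)
  b <- deform_to_structure(m, axes = c(3, 1, 1), bend = 0.8, taper = 0.2,
                           jitter = 0.1, seed = 11)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, m$faces)
  expect_true(validate_mesh(a))

  # bending moves section centroids off the principal axis
  bent <- deform_to_structure(m, axes = c(4, 1, 1), bend = 1.2)
  v <- bent$vertices
  pc1 <- prcomp(v)$rotation[, 1]
  ctr <- colMeans(v)
  s <- drop(sweep(v, 2, ctr) %*% pc1)
  bins <- cut(s, 8, labels = FALSE)
  cents <- t(sapply(1:8, function(b2) colMeans(v[bins == b2, , drop = FALSE])))
  resid <- cents - (outer(drop(sweep(cents, 2, ctr) %*% pc1), pc1) +
                      rep(ctr, each = 8))
  expect_gt(max(sqrt(rowSums(resid^2))), 0.1)
})

test_that("self-intersection test flags a folded surface and passes valid ones", {
  m <- build_sphere_mesh("icosphere", 1)
  expect_false(mesh_self_intersects(m))
  folded <- m
  folded$vertices[1, ] <- c(0, 0, -1.5)  # push north-pole vertex through
  expect_true(mesh_self_intersects(folded))
})

test_that("PLY write/read round-trips both dialects and rejects malformed input", {
  m <- deform_to_structure(build_sphere_mesh("uv", rings = 6, cols = 9),
                           axes = c(2, 1.2, 1), bend = 0.5, jitter = 0.05,
                           seed = 3)
  fa <- tempfile(fileext = ".ply"); fb <- tempfile(fileext = ".ply")
  write_ply(m, fa, "ascii")
  write_ply(m, fb, "binary_little_endian")
  ra <- read_ply(fa); rb <- read_ply(fb)
  expect_identical(ra$faces, m$faces)
  expect_identical(rb$faces, m$faces)
  expect_lt(max(abs(ra$vertices - m$vertices)), 1e-6)
  expect_equal(ra$vertices, rb$vertices)
  expect_identical(ra$structure_name, m$structure_name)

  bad <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "elemen vertex 3"), bad)
  expect_error(read_ply(bad), "line 3")

  quad <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property double x", "property double y", "property double z",
               "element face 1",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0", "4 0 1 2 3"), quad)
  expect_error(read_ply(quad), "non-triangle")
})

test_that("default atlas totals 27,120 vertices across 14 structures", {
  atlas <- build_atlas(default_atlas_config())
  expect_equal(length(atlas$structures), 14L)
  expect_equal(atlas$n_vertices, 27120L)
  counts <- atlas$offsets$end - atlas$offsets$start + 1L
  expect_equal(sum(counts), 27120L)
  # registration spheres are unit and match vertex counts
  for (s in atlas$structures) {
    expect_equal(nrow(s$sphere), nrow(s$mesh$vertices))
    expect_lt(max(abs(rowSums(s$sphere^2) - 1)), 1e-9)
  }
})

test_that("atlas adjacency is symmetric-free of self-loops and never crosses structures", {
  atlas <- build_atlas(demo_atlas_config())
  e <- atlas$edges
  expect_true(all(e[, 1L] < e[, 2L]))           # canonical, no self-loops
  expect_equal(anyDuplicated(e), 0L)
  off <- atlas$offsets
  block <- function(idx) findInterval(idx, off$start)
  expect_true(all(block(e[, 1L]) == block(e[, 2L])))

  cfg <- demo_atlas_config()
  dup <- rbind(cfg, cfg[1, ])
  expect_error(build_atlas(dup), "duplicate")

  # icosahedron-based toy: every vertex of an icosahedron has degree 5
  ico <- build_sphere_mesh("icosphere", 0)
  deg <- tabulate(mesh_edges(ico), 12L)
  expect_true(all(deg == 5L))
})

test_that("atlas construction is deterministic under a fixed seed", {
  a1 <- build_atlas(demo_atlas_config(), seed = 5)
  a2 <- build_atlas(demo_atlas_config(), seed = 5)
  expect_identical(a1$structures[[1]]$mesh$vertices,
                   a2$structures[[1]]$mesh$vertices)
  a3 <- build_atlas(demo_atlas_config(), seed = 6)
  expect_false(identical(a1$structures[[1]]$mesh$vertices,
                         a3$structures[[1]]$mesh$vertices))
})
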