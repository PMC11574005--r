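# medial curves, radial thickness, and the discrepancy QC statistic

test_that("sphere: section centroids sit on the central axis and the degenerate curve gives unit thickness", {
  m <- build_sphere_mesh("icosphere", 4)
  cv <- fit_medial_curve(m, n_sections = 8, smoothing = 0)
  # centroids lie near the first principal axis through the origin
  cps <- cv$control_points
  pc1 <- prcomp(m$vertices)$rotation[, 1]
  off_axis <- cps - outer(drop(cps %*% pc1), pc1)
  expect_lt(max(sqrt(rowSums(off_axis^2))), 0.01)  # < 1% of radius

  expect_warning(th <- radial_thickness(m, c(0, 0, 0)), "degenerate")
  expect_equal(th, rep(1, nrow(m$vertices)), tolerance = 1e-9)
})

test_that("cylinder phantom: curve tracks the axis and lateral thickness equals the radius", {
  m <- cylinder_phantom(rings = 40, cols = 24, radius = 1, height = 6)
  expect_true(validate_mesh(m))
  cv <- fit_medial_curve(m, n_sections = 10, smoothing = 0)
  expect_lt(max(sqrt(rowSums(cv$control_points[, 1:2]^2))), 0.02)
  th <- radial_thickness(m, cv)
  lateral <- abs(m$vertices[, 3]) < 2   # wall, away from caps and curve ends
  expect_lt(max(abs(th[lateral] - 1)), 0.01)
})

test_that("bent tube: the medial curve tracks the analytic bent centerline", {
  m <- build_sphere_mesh("uv", rings = 72, cols = 36)
  m$vertices <- m$vertices[, c(3, 1, 2)]  # poles onto the long axis
  bend <- 0.8
  tube <- deform_to_structure(m, axes = c(8, 1, 1), bend = bend)
  cv <- fit_medial_curve(tube, n_sections = 8, smoothing = 0)
  # analytic centerline of the bend: (rho sin(t), rho (1 - cos(t)), 0)
  rho <- 16 / bend
  tt <- seq(-bend / 2, bend / 2, length.out = 3000)
  center <- cbind(rho * sin(tt), rho - rho * cos(tt), 0)
  cps <- cv$control_points
  dmin <- apply(cps, 1, function(pt)
    min(sqrt(colSums((t(center) - pt)^2))))
  expect_lt(max(dmin), 0.05 * 1)        # within 5% of tube radius
})

test_that("pole thickness on an elongated ellipsoid matches a brute-force closest-point oracle", {
  m <- build_sphere_mesh("uv", rings = 20, cols = 16)
  ell <- deform_to_structure(m, axes = c(2, 1, 1))
  cv <- fit_medial_curve(ell, n_sections = 8, smoothing = 0)
  th <- radial_thickness(ell, cv, n_samples = 1024)
  dense <- cv$evaluate(seq(0, 1, length.out = 1e5))
  oracle <- vapply(seq_len(nrow(ell$vertices)), function(i)
    sqrt(min(colSums((t(dense) - ell$vertices[i, ])^2))), numeric(1))
  expect_lt(max(abs(th - oracle)), 1e-4)
  pole <- which.max(ell$vertices[, 1])
  ends <- cv$evaluate(c(0, 1))
  expect_equal(th[pole],
               min(sqrt(rowSums(sweep(ends, 2, ell$vertices[pole, ])^2))),
               tolerance = 1e-6)
})

test_that("thickness is invariant under rigid motion and monotone in sampling density", {
  m <- deform_to_structure(build_sphere_mesh("uv", rings = 16, cols = 14),
                           axes = c(3, 1.5, 1), bend = 0.6, jitter = 0.05,
                           seed = 2)
  cv <- fit_medial_curve(m, n_sections = 8, smoothing = 0)
  th <- radial_thickness(m, cv, n_samples = 512)

  set.seed(42)
  for (rep in 1:3) {
    R <- quaternion_to_rotation(rnorm(4))
    shift <- rnorm(3, sd = 10)
    mr <- m
    mr$vertices <- sweep(m$vertices %*% t(R), 2, -shift)
    cvr <- cv                     # transform mesh and curve together
    cvr$control_points <- sweep(cv$control_points %*% t(R), 2, -shift)
    cvr$evaluate <- local({
      ev <- cv$evaluate; R1 <- R; s1 <- shift
      function(t) sweep(ev(t) %*% t(R1), 2, -s1)
    })
    thr <- radial_thickness(mr, cvr, n_samples = 512)
    expect_lt(max(abs(thr - th)), 1e-9)
  }

  # refining the dense sampling never increases a vertex's thickness
  th_coarse <- radial_thickness(m, cv, n_samples = 512, tol = 1e-15)
  th_fine <- radial_thickness(m, cv, n_samples = 2048, tol = 1e-15)
  expect_true(all(th_fine <= th_coarse + 1e-10))
})

test_that("medial discrepancy is zero for interpolating splines and grows with smoothing", {
  m <- build_sphere_mesh("uv", rings = 30, cols = 20)
  tube <- deform_to_structure(m, axes = c(8, 1, 1), bend = 1.2)
  cv0 <- fit_medial_curve(tube, n_sections = 10, smoothing = 0)
  expect_lt(medial_discrepancy(tube, cv0), 1e-7)

  cv_light <- fit_medial_curve(tube, n_sections = 10, smoothing = 1e-3)
  cv_heavy <- fit_medial_curve(tube, n_sections = 10, smoothing = 10)
  d_light <- medial_discrepancy(tube, cv_light)
  d_heavy <- medial_discrepancy(tube, cv_heavy)
  expect_gt(d_heavy, d_light)

  sph <- build_sphere_mesh("icosphere", 4)
  cvs <- fit_medial_curve(sph, n_sections = 8, smoothing = 1e-3)
  expect_lt(medial_discrepancy(sph, cvs), 1e-6)  # collinear centroids
})

test_that("over-resolved sectioning of a coarse mesh raises a helpful error", {
  m <- build_sphere_mesh("icosphere", 0)
  expect_error(fit_medial_curve(m, n_sections = 10), "n_sections")
})
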