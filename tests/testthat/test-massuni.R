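# vertex-wise mixed models and searchlight FDR

sim_design_data <- function(n = 120, n_cohorts = 4, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%03d", 1:n),
    group = factor(rep(c("control", "PD"), length.out = n),
                   levels = c("control", "PD")),
    age = rnorm(n, 63, 9), sex = rbinom(n, 1, 0.4),
    icv = rnorm(n, 1.5e6, 1.5e5),
    cohort_id = paste0("c", rep_len(seq_len(n_cohorts), n)))
}

test_that("single-cohort mixed model equals ordinary least squares", {
  d <- sim_design_data(n = 80, n_cohorts = 1)
  set.seed(2)
  y <- 2 + 0.2 * (d$group == "PD") + rnorm(80, 0, 0.3)
  res <- fit_vertex_lmm(y, design_spec("group"), d)
  ols <- lm(y ~ group + scale(age) + scale(sex) + scale(icv), data = d)
  sm <- summary(ols)$coefficients["groupPD", ]
  expect_equal(unname(res["beta"]), unname(sm["Estimate"]), tolerance = 1e-8)
  expect_equal(unname(res["se"]), unname(sm["Std. Error"]), tolerance = 1e-8)
})

test_that("the mixed model recovers a planted effect across cohorts", {
  d <- sim_design_data(n = 300, n_cohorts = 5, seed = 3)
  u <- rnorm(5, 0, 0.15)
  set.seed(4)
  y <- 2 - 0.15 * (d$group == "PD") +
    u[as.integer(factor(d$cohort_id))] + rnorm(300, 0, 0.2)
  res <- local_quiet_fit(fit_vertex_lmm(y, design_spec("group"), d))
  expect_lt(abs(res["beta"] - (-0.15)), 2.5 * res["se"])
  expect_lt(res["p"], 0.01)
})

test_that("rank-deficient and constant-predictor designs raise clear errors", {
  d <- sim_design_data(n = 40)
  d2 <- d; d2$icv <- d2$age   # collinear after standardization
  set.seed(5); y <- rnorm(40)
  expect_error(fit_vertex_lmm(y, design_spec("group"), d2), "collinear")
  d3 <- d; d3$group <- factor(rep("PD", 40))
  expect_error(fit_vertex_lmm(y, design_spec("group"), d3), "constant")
})

test_that("map_effects equals per-vertex fits and is equivariant to row permutation", {
  d <- sim_design_data(n = 90, n_cohorts = 3, seed = 6)
  set.seed(7)
  th <- matrix(rnorm(90 * 8, 2.5, 0.3), 90, 8)
  th[, 3] <- th[, 3] - 0.3 * (d$group == "PD")
  rownames(th) <- d$subject_id
  map <- local_quiet_fit(map_effects(th, design_spec("group"), d))
  for (v in c(1L, 3L, 6L)) {
    one <- local_quiet_fit(fit_vertex_lmm(th[, v], design_spec("group"), d))
    expect_equal(unname(map$beta[v]), unname(one["beta"]), tolerance = 1e-8)
    expect_equal(unname(map$p[v]), unname(one["p"]), tolerance = 1e-8)
  }
  set.seed(8)
  perm <- sample(90)
  map2 <- local_quiet_fit(
    map_effects(th[perm, ], design_spec("group"), d[perm, ]))
  expect_equal(map2$beta, map$beta, tolerance = 1e-7)

  expect_error(map_effects(th[1:10, ], design_spec("group"), d),
               "misaligned")
})

test_that("the target beta is invariant to affine rescaling of nuisance covariates", {
  d <- sim_design_data(n = 100, n_cohorts = 4, seed = 9)
  set.seed(10)
  y <- 2 - 0.2 * (d$group == "PD") + 0.01 * d$age + rnorm(100, 0, 0.2)
  r1 <- local_quiet_fit(fit_vertex_lmm(y, design_spec("group"), d))
  d2 <- d; d2$age <- (d$age - 60) / 10; d2$icv <- d$icv / 1e6
  r2 <- local_quiet_fit(fit_vertex_lmm(y, design_spec("group"), d2))
  expect_equal(unname(r1["beta"]), unname(r2["beta"]), tolerance = 1e-6)
})

test_that("searchlight FDR handles the trivial masks and the degenerate isolated vertex", {
  ring <- cbind(1:20, c(2:20, 1))
  expect_equal(searchlight_fdr(rep(1, 20), ring, 3, 0.05), rep(FALSE, 20))
  expect_equal(searchlight_fdr(rep(1e-12, 20), ring, 3, 0.05),
               rep(TRUE, 20))
  # isolated vertex, radius 0: single-test rule p <= q
  lone <- matrix(integer(0), 0, 2)
  expect_true(searchlight_fdr(0.04, lone, 0, 0.05))
  expect_false(searchlight_fdr(0.06, lone, 0, 0.05))
})

test_that("ring-graph searchlight matches an exhaustive per-vertex BH oracle", {
  set.seed(11)
  n <- 200
  ring <- cbind(1:n, c(2:n, 1))
  p <- runif(n)
  p[sample(n, 25)] <- runif(25, 0, 1e-3)
  got <- searchlight_fdr(p, ring, radius_hops = 3, q = 0.05)
  adj <- adjacency_list_of(ring, n)
  oracle <- vapply(seq_len(n), function(v) {
    nb <- ((v - 4):(v + 2)) %% n + 1   # all vertices within 3 hops on a ring
    p[v] <= max(-Inf, {
      ps <- sort(p[nb]); m <- length(ps)
      ok <- ps <= seq_len(m) / m * 0.05
      if (any(ok)) ps[max(which(ok))] else -Inf
    })
  }, logical(1))
  expect_equal(got, oracle)
})

test_that("radius-infinity searchlight agrees with textbook Benjamini-Hochberg", {
  set.seed(12)
  ring <- cbind(1:150, c(2:150, 1))
  for (rep in 1:20) {
    p <- runif(150)^sample(c(1, 3), 1)
    got <- searchlight_fdr(p, ring, radius_hops = Inf, q = 0.05)
    expect_equal(got, bh_reject(p, 0.05))
    expect_equal(got, p <= max(-Inf, p[p.adjust(p, "BH") <= 0.05]))
  }
})

test_that("map summaries report percent-significant and signed peak beta", {
  atlas <- build_atlas(demo_atlas_config(rings = 4, cols = 8))
  V <- atlas$n_vertices
  map <- structure(data.frame(vertex = 1:V, beta = 0, se = 1, p = 1,
                              sig = FALSE),
                   class = c("effect_map", "data.frame"))
  s0 <- summarize_map(map, atlas)
  expect_true(all(s0$pct_significant == 0))
  expect_true(all(s0$peak_beta == 0))

  idx <- atlas_vertex_range(atlas, "putamen", "left")
  map$sig[idx[1:17]] <- TRUE
  map$beta[idx[1:17]] <- -seq(0.1, 0.26,.01)
  s1 <- summarize_map(map, atlas)
  row <- s1[s1$structure == "putamen" & s1$hemisphere == "left", ]
  expect_equal(row$pct_significant, 100 * 17 / length(idx))
  expect_equal(row$peak_beta, -0.26)

  full <- map; full$sig <- TRUE; full$beta <- -0.2
  s2 <- summarize_map(full, atlas)
  expect_true(all(s2$pct_significant == 100))
  expect_true(all(s2$peak_beta == -0.2))
})

test_that("effect maps round-trip through TSV", {
  map <- structure(data.frame(vertex = 1:5, beta = rnorm(5), se = runif(5),
                              p = runif(5), sig = c(TRUE, FALSE, TRUE,
                                                    FALSE, TRUE)),
                   class = c("effect_map", "data.frame"))
  f <- tempfile(fileext = ".tsv")
  write_effect_map(map, f)
  back <- read_effect_map(f)
  expect_equal(back$beta, map$beta, tolerance = 1e-9)
  expect_equal(back$sig, map$sig)
})
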