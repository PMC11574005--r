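# structured classifiers: binary Logit-TVL1 and ordinal Ordit

no_edges <- matrix(integer(0), 0, 2)

test_that("heavy L1 zeroes the weights and leaves the weighted base-rate intercept", {
  set.seed(1)
  X <- matrix(rnorm(120 * 6), 120)
  y <- rbinom(120, 1, 0.3)
  m <- fit_logit_tvl1(X, y, lambda_l1 = 1e5, lambda_tv = 0, no_edges)
  expect_true(all(m$w == 0))
  expect_equal(m$intercept, qlogis(mean(y)), tolerance = 1e-5)
  # with balance weights the weighted base rate is 1/2
  mb <- fit_logit_tvl1(X, y, 1e5, 0, no_edges,
                       class_weights = class_balance_weights(y))
  expect_equal(mb$intercept, 0, tolerance = 1e-5)
  expect_error(fit_logit_tvl1(X, rep(1, 120), 0, 0, no_edges), "two classes")
})

test_that("the unregularized logistic fit matches glm and the separable toy keeps its sign", {
  set.seed(2)
  X <- matrix(rnorm(250 * 4), 250)
  y <- rbinom(250, 1, plogis(X %*% c(1.2, -0.8, 0, 0.3)))
  m <- fit_logit_tvl1(X, y, 0, 0, no_edges,
                      opts = solver_options(max_iter = 4000, tol = 1e-13))
  g <- glm(y ~ X, family = binomial)
  expect_lt(max(abs(c(m$intercept, m$w) - coef(g))), 1e-5)

  # 2-feature linearly separable toy: direction matches the oracle fit
  X2 <- cbind(c(-2, -1.5, -1, 1, 1.5, 2), c(0.3, -0.2, 0.1, -0.1, 0.2, 0))
  y2 <- c(0, 0, 0, 1, 1, 1)
  m2 <- fit_logit_tvl1(X2, y2, 0.05, 0.01, matrix(c(1L, 2L), 1, 2))
  expect_gt(m2$w[1], 0)
  expect_gt(abs(m2$w[1]), abs(m2$w[2]))
})

test_that("objective traces are non-increasing for both fitters", {
  set.seed(3)
  X <- matrix(rnorm(80 * 10), 80)
  y <- rbinom(80, 1, 0.5)
  g <- random_connected_graph(10)
  m <- fit_logit_tvl1(X, y, 0.3, 0.3, g)
  expect_true(all(diff(m$solver_report$trace) <= 1e-12))
  st <- sample(1:3, 80, TRUE)
  mo <- fit_ordit(X, st, 0.3, 0.3, g)
  expect_true(all(diff(mo$solver_report$trace) <= 1e-12))
})

test_that("fitters reach a long-run reference objective on small instances", {
  set.seed(4)
  X <- matrix(rnorm(60 * 8), 60)
  y <- rbinom(60, 1, 0.5)
  g <- random_connected_graph(8)
  quick <- fit_logit_tvl1(X, y, 0.4, 0.2, g,
                          opts = solver_options(max_iter = 400, tol = 1e-10))
  ref <- fit_logit_tvl1(X, y, 0.4, 0.2, g,
                        opts = solver_options(max_iter = 20000, tol = 1e-15,
                                              prox_tol = 1e-8))
  expect_lt(quick$solver_report$objective - ref$solver_report$objective,
            1e-5)
})

test_that("unpenalized Ordit matches MASS::polr and enforces ordered thresholds", {
  set.seed(5)
  X <- matrix(rnorm(300 * 4), 300)
  s <- drop(X %*% c(1, -0.5, 0, 0.8)) + rlogis(300)
  st <- cut(s, c(-Inf, -0.5, 1, Inf), labels = FALSE)
  m <- fit_ordit(X, st, 0, 0, no_edges,
                 opts = solver_options(max_iter = 8000, tol = 1e-14))
  po <- MASS::polr(factor(st) ~ X, method = "logistic")
  expect_lt(max(abs(m$w - coef(po))), 1e-4)
  expect_lt(max(abs(m$thresholds - po$zeta)), 1e-4)
  expect_true(all(diff(m$thresholds) > 0))
})

test_that("K = 2 Ordit and the binary model reach the same objective under theta1 = -intercept", {
  set.seed(6)
  for (i in 1:5) {
    X <- matrix(rnorm(60 * 6), 60)
    y <- rbinom(60, 1, 0.5)
    g <- random_connected_graph(6)
    l1 <- runif(1, 0.05, 0.5); tv <- runif(1, 0.05, 0.5)
    ob <- solver_options(max_iter = 6000, tol = 1e-14)
    mb <- fit_logit_tvl1(X, y, l1, tv, g, opts = ob)
    mo <- fit_ordit(X, y + 1, l1, tv, g, opts = ob)
    expect_lt(abs(mb$solver_report$objective - mo$solver_report$objective),
              1e-6)
    expect_lt(abs(mo$thresholds[1] - (-mb$intercept)), 1e-3)
  }
})

test_that("predictions: probabilities sum to one, the null model is indifferent, and theta crossings give 0.5", {
  set.seed(7)
  X <- matrix(rnorm(40 * 5), 40)
  null_model <- structure(
    list(w = rep(0, 5), intercept = 0, kind = "binary", K = 2L,
         thresholds = NULL, levels = c("a", "b"), lambda_l1 = 0,
         lambda_tv = 0),
    class = "structured_linear_model")
  pr <- predict(null_model, X)
  expect_true(all(pr$prob == 0.5))

  om <- structure(
    list(w = c(1, 0, 0, 0, 0), intercept = NULL,
         thresholds = c(-1, 0.5, 2), kind = "ordinal", K = 4L,
         levels = paste0("k", 1:4), lambda_l1 = 0, lambda_tv = 0),
    class = "structured_linear_model")
  po <- predict(om, X)
  expect_lt(max(abs(rowSums(po$prob) - 1)), 1e-12)
  # subject sitting exactly at theta_1: P(class <= 1) = 0.5
  x_at <- matrix(c(-1, 0, 0, 0, 0), 1)
  expect_equal(unname(predict(om, x_at)$prob[1, 1]), 0.5)
  # predicted class is non-decreasing in the linear score
  xs <- cbind(seq(-4, 4, 0.1), 0, 0, 0, 0)
  cls <- match(predict(om, xs)$label, om$levels)
  expect_true(all(diff(cls) >= 0))
  expect_error(predict(om, X[, 1:3]), "expects")
})

test_that("weight maps are in SD units with the sign pattern of w", {
  m <- structure(
    list(w = c(0.4, -0.2, 0, 0.1), intercept = 0, kind = "binary", K = 2L,
         thresholds = NULL, levels = c("a", "b"), lambda_l1 = 0,
         lambda_tv = 0),
    class = "structured_linear_model")
  wm <- weight_map(m)
  expect_equal(sd(wm), 1)
  expect_equal(sign(wm), sign(m$w))
  z <- m; z$w <- rep(0, 4)
  expect_warning(wz <- weight_map(z), "all-zero")
  expect_true(all(wz == 0))
})

test_that("one-against-all fits one binary model per class and predicts the argmax class", {
  set.seed(8)
  X <- matrix(rnorm(120 * 4), 120)
  mu <- rbind(c(2, 0, 0, 0), c(0, 2, 0, 0), c(0, 0, 2, 0))
  y <- rep(1:3, each = 40)
  X <- X + mu[y, ]
  m <- fit_one_vs_rest(X, y, 0.05, 0.02, random_connected_graph(4))
  expect_length(m$models, 3L)
  pr <- predict(m, X)
  expect_gt(mean(pr$label == as.character(y)), 0.8)
  expect_equal(colnames(pr$prob), c("1", "2", "3"))
})
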