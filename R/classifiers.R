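# ---- structured-sparsity classifiers: binary Logit-TVL1 and ordinal Ordit

.sigmoid <- function(x) stats::plogis(x)
.log1pexp <- function(x) ifelse(x > 35, x, log1p(exp(pmin(x, 35))))
.softplus <- function(x) .log1pexp(x)

#' Default solver options for the structured classifiers
#'
#' @param max_iter outer accelerated-proximal-gradient iteration cap.
#' @param tol relative objective-decrease convergence tolerance.
#' @param prox_tol accuracy of the inner TV prox solves.
#' @param prox_iter inner dual-iteration cap per prox solve; the dual
#'   variable is warm-started across outer iterations, so a modest cap
#'   yields an increasingly exact composite prox.
#' @return List of solver options.
#' @export
solver_options <- function(max_iter = 3000L, tol = 1e-10, prox_tol = 1e-5,
                           prox_iter = 2000L) {
  list(max_iter = max_iter, tol = tol, prox_tol = prox_tol,
       prox_iter = prox_iter)
}

# weighted logistic negative log-likelihood and gradient; par = c(w, b)
.logit_smooth <- function(X, y01, wts) {
  p <- ncol(X)
  function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    s <- drop(X %*% w) + b
    value <- sum(wts * (.log1pexp(s) - y01 * s))
    r <- wts * (.sigmoid(s) - y01)
    list(value = value, grad = c(drop(crossprod(X, r)), sum(r)))
  }
}

#' Fit a TV-L1 regularized logistic classifier (Logit-TVL1)
#'
#' Minimizes the (class-weighted) logistic loss plus `lambda_l1 ||w||_1 +
#' lambda_tv TV(w)` over the mesh graph by monotone accelerated proximal
#' gradient with backtracking and adaptive restart. The intercept is not
#' penalized. The recorded objective trace is non-increasing.
#'
#' @param X subjects x vertices feature matrix.
#' @param y binary labels: logical, 0/1, or a 2-level factor (level 2 is
#'   the positive class).
#' @param lambda_l1,lambda_tv nonnegative regularization strengths.
#' @param edges undirected vertex edge matrix (e.g. `atlas$edges`).
#' @param class_weights optional per-class weights named by class; default
#'   from [class_balance_weights()] use 1 for both classes.
#' @param opts solver options, see [solver_options()].
#' @return An object of class `structured_linear_model` with fields `w`,
#'   `intercept`, `kind = "binary"`, `lambda_l1`, `lambda_tv`, `levels`,
#'   and `solver_report` (iterations, objective trace, convergence flag).
#' @export
fit_logit_tvl1 <- function(X, y, lambda_l1 = 0, lambda_tv = 0, edges,
                           class_weights = NULL, opts = solver_options()) {
  X <- as.matrix(X)
  f <- if (is.factor(y)) droplevels(y)
       else factor(y, levels = sort(unique(y)))
  levels_y <- levels(f)
  if (nlevels(f) != 2L) stop("y must contain exactly two classes")
  y01 <- as.integer(f) - 1L
  if (nrow(edges) > 0L && max(edges) > ncol(X))
    stop("edge endpoints exceed feature count")
  wts <- .per_subject_weights(f, class_weights)
  p <- ncol(X)
  attr(edges, "D") <- .D_matrix(edges, p)
  smooth_fn <- .logit_smooth(X, y01, wts)
  env <- new.env(); env$z <- NULL
  prox_fn <- function(par, step) {
    w <- .prox_l1tv(par[seq_len(p)], lambda_l1 * step, lambda_tv * step,
                    edges, tol = opts$prox_tol, z0 = env$z,
                    max_iter = opts$prox_iter %||% 2000L)
    env$z <- attr(w, "z")
    c(as.numeric(w), par[p + 1L])
  }
  pen_fn <- function(par)
    lambda_l1 * sum(abs(par[seq_len(p)])) +
    lambda_tv * tv_norm(par[seq_len(p)], edges)
  base_rate <- sum(wts * y01) / sum(wts)
  par0 <- c(numeric(p), stats::qlogis(min(max(base_rate, 1e-6), 1 - 1e-6)))
  res <- .fista(par0, smooth_fn, prox_fn, pen_fn,
                max_iter = opts$max_iter, tol = opts$tol,
                L0 = 0.25 * sum(wts) / length(wts) * mean(rowSums(X^2) + 1))
  structure(list(
    w = res$par[seq_len(p)], intercept = res$par[p + 1L],
    kind = "binary", K = 2L, thresholds = NULL, levels = levels_y,
    lambda_l1 = lambda_l1, lambda_tv = lambda_tv,
    solver_report = res[c("objective", "trace", "iterations", "converged")]),
    class = "structured_linear_model")
}

# cumulative-logit NLL and gradient; par = c(w, a_1..a_{K-1}) with
# theta_1 = a_1 and theta_k = theta_{k-1} + softplus(a_k)
.ordit_smooth <- function(X, yk, K, wts) {
  p <- ncol(X)
  n <- nrow(X)
  function(par) {
    w <- par[seq_len(p)]; a <- par[p + seq_len(K - 1L)]
    inc <- c(a[1L], .softplus(a[-1L]))
    theta <- cumsum(inc)
    s <- drop(X %*% w)
    Fk <- function(k) {                 # P(y <= k | x), k in 0..K
      if (k == 0L) rep(0, n)
      else if (k == K) rep(1, n)
      else .sigmoid(theta[k] - s)
    }
    Fu <- Fk(0L); val <- 0
    dNLL_ds <- numeric(n)
    grad_theta <- numeric(K - 1L)
    for (k in seq_len(K)) {
      Fl <- Fu; Fu <- Fk(k)
      sel <- yk == k
      if (!any(sel)) next
      pik <- pmax(Fu[sel] - Fl[sel], 1e-300)
      val <- val - sum(wts[sel] * log(pik))
      du <- if (k < K) Fu[sel] * (1 - Fu[sel]) else 0   # dF_k / d theta_k
      dl <- if (k > 1L) Fl[sel] * (1 - Fl[sel]) else 0
      # d/ds pi_k = -du + dl ; dNLL/ds = -(d pi/ds)/pi
      dNLL_ds[sel] <- wts[sel] * (du - dl) / pik
      if (k < K) grad_theta[k] <- grad_theta[k] - sum(wts[sel] * du / pik)
      if (k > 1L) grad_theta[k - 1L] <- grad_theta[k - 1L] +
          sum(wts[sel] * dl / pik)
    }
    grad_w <- drop(crossprod(X, dNLL_ds))
    # chain rule: theta_k = a_1 + sum_{m=2}^{k} softplus(a_m)
    cum_rev <- rev(cumsum(rev(grad_theta)))  # sum_{k >= m} dNLL/dtheta_k
    grad_a <- cum_rev
    if (K > 2L) grad_a[-1L] <- grad_a[-1L] * .sigmoid(a[-1L])
    list(value = val, grad = c(grad_w, grad_a))
  }
}

#' Fit an ordinal TV-L1 classifier (Ordit)
#'
#' Cumulative-logit (proportional-odds) model with one shared weight
#' vector: `P(stage <= k | x) = sigmoid(theta_k - w^T x)` with strictly
#' increasing thresholds `theta_1 < ... < theta_{K-1}` (enforced by a
#' softplus parameterization of the increments). Shares the TV + L1
#' penalty and solver contract of [fit_logit_tvl1()]. With `K = 2` the
#' decision function coincides with the binary model's under
#' `theta_1 = -intercept`.
#'
#' @param X subjects x vertices feature matrix.
#' @param stages ordered labels forming a contiguous set (coded 1..K after
#'   factor conversion; an ordered factor or integer vector).
#' @param lambda_l1,lambda_tv,edges,class_weights,opts as in
#'   [fit_logit_tvl1()].
#' @return A `structured_linear_model` with `kind = "ordinal"`, `w`,
#'   `thresholds` (strictly increasing), `K`, `levels`.
#' @export
fit_ordit <- function(X, stages, lambda_l1 = 0, lambda_tv = 0, edges,
                      class_weights = NULL, opts = solver_options()) {
  X <- as.matrix(X)
  f <- if (is.factor(stages)) droplevels(stages)
       else factor(stages, levels = sort(unique(stages)))
  K <- nlevels(f)
  if (K < 2L) stop("need at least 2 ordered classes")
  yk <- as.integer(f)
  if (!all(seq_len(K) %in% yk)) stop("all K classes must be present")
  wts <- .per_subject_weights(f, class_weights)
  p <- ncol(X)
  attr(edges, "D") <- .D_matrix(edges, p)
  smooth_fn <- .ordit_smooth(X, yk, K, wts)
  env <- new.env(); env$z <- NULL
  prox_fn <- function(par, step) {
    w <- .prox_l1tv(par[seq_len(p)], lambda_l1 * step, lambda_tv * step,
                    edges, tol = opts$prox_tol, z0 = env$z,
                    max_iter = opts$prox_iter %||% 2000L)
    env$z <- attr(w, "z")
    c(as.numeric(w), par[p + seq_len(K - 1L)])
  }
  pen_fn <- function(par)
    lambda_l1 * sum(abs(par[seq_len(p)])) +
    lambda_tv * tv_norm(par[seq_len(p)], edges)
  # start thresholds at the weighted empirical cumulative logits
  cum <- cumsum(tapply(wts, yk, sum))[seq_len(K - 1L)] / sum(wts)
  theta0 <- stats::qlogis(pmin(pmax(cum, 1e-6), 1 - 1e-6))
  theta0 <- cummax(theta0 + seq_len(K - 1L) * 1e-6)  # strictly increasing
  a0 <- c(theta0[1L], if (K > 2L) log(expm1(pmax(diff(theta0), 1e-6))))
  par0 <- c(numeric(p), a0)
  res <- .fista(par0, smooth_fn, prox_fn, pen_fn,
                max_iter = opts$max_iter, tol = opts$tol,
                L0 = 0.25 * mean(rowSums(X^2) + 1))
  a <- res$par[p + seq_len(K - 1L)]
  theta <- cumsum(c(a[1L], .softplus(a[-1L])))
  structure(list(
    w = res$par[seq_len(p)], intercept = NULL, thresholds = theta,
    kind = "ordinal", K = K, levels = levels(f),
    lambda_l1 = lambda_l1, lambda_tv = lambda_tv,
    solver_report = res[c("objective", "trace", "iterations", "converged")]),
    class = "structured_linear_model")
}

#' @export
print.structured_linear_model <- function(x, ...) {
  cat(sprintf(
    "<structured_linear_model> %s, %d features (%d nonzero), l1 = %g, tv = %g\n",
    x$kind, length(x$w), sum(x$w != 0), x$lambda_l1, x$lambda_tv))
  if (x$kind == "ordinal")
    cat("  thresholds:", paste(signif(x$thresholds, 4), collapse = " < "), "\n")
  invisible(x)
}

#' Predict from a structured linear model
#'
#' Binary models return `P(positive class)`; ordinal models return the
#' K-class probability matrix from consecutive threshold differences
#' (`P(y = k) = sigmoid(theta_k - s) - sigmoid(theta_{k-1} - s)`), which
#' sums to 1 by construction. Labels are the argmax class.
#'
#' @param object a `structured_linear_model`.
#' @param X feature matrix with the model's feature count.
#' @param ... unused.
#' @return List with `score` (`w^T x` plus intercept for binary),
#'   `prob` (vector or matrix), and `label`.
#' @export
predict.structured_linear_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$w))
    stop("X has ", ncol(X), " columns; model expects ", length(object$w))
  s <- drop(X %*% object$w)
  if (object$kind == "binary") {
    pr <- .sigmoid(s + object$intercept)
    list(score = s + object$intercept, prob = pr,
         label = object$levels[1L + (pr >= 0.5)])
  } else {
    cdf <- cbind(0, .sigmoid(outer(-s, object$thresholds, `+`)), 1)
    prob <- cdf[, -1L, drop = FALSE] - cdf[, -ncol(cdf), drop = FALSE]
    colnames(prob) <- object$levels
    list(score = s, prob = prob,
         label = object$levels[max.col(prob, ties.method = "first")])
  }
}

#' Standardized weight map of a fitted model
#'
#' Weights divided by their standard deviation over vertices (the map
#' display convention: values in SD units of the learned weights). An
#' all-zero model returns zeros with a warning.
#'
#' @param model a `structured_linear_model`.
#' @param atlas optional `mesh_atlas` for labeling; when given, the result
#'   carries structure/hemisphere columns.
#' @return Numeric vector, or a labeled data frame when `atlas` is given.
#' @export
weight_map <- function(model, atlas = NULL) {
  sdw <- stats::sd(model$w)
  if (sdw == 0) {
    warning("all-zero weight vector; returning zeros")
    wm <- model$w
  } else wm <- model$w / sdw
  if (is.null(atlas)) return(wm)
  off <- atlas$offsets
  lab_s <- character(atlas$n_vertices); lab_h <- character(atlas$n_vertices)
  for (i in seq_len(nrow(off))) {
    idx <- seq.int(off$start[i], off$end[i])
    lab_s[idx] <- off$structure[i]; lab_h[idx] <- off$hemisphere[i]
  }
  data.frame(vertex = seq_along(wm), structure = lab_s, hemisphere = lab_h,
             weight_sd = wm)
}

#' One-against-all multiclass comparator
#'
#' Fits one [fit_logit_tvl1()] model per class (that class versus the
#' rest) with shared penalties; prediction takes the class whose binary
#' model assigns the highest probability. Serves as the flat multiclass
#' baseline against which the ordinal model is compared.
#'
#' @param X subjects x vertices feature matrix.
#' @param y class labels (factor or vector; >= 2 classes).
#' @param lambda_l1,lambda_tv,edges,opts as in [fit_logit_tvl1()].
#' @param balance apply [class_balance_weights()] per binary subproblem.
#' @return Object of class `one_vs_rest_model`: list of binary models
#'   named by class.
#' @export
fit_one_vs_rest <- function(X, y, lambda_l1 = 0, lambda_tv = 0, edges,
                            balance = TRUE, opts = solver_options()) {
  f <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nlevels(f) < 2L) stop("need at least 2 classes")
  models <- lapply(levels(f), function(cl) {
    yb <- factor(ifelse(f == cl, cl, "rest"), levels = c("rest", cl))
    cw <- if (balance) class_balance_weights(yb)
    fit_logit_tvl1(X, yb, lambda_l1, lambda_tv, edges,
                   class_weights = cw, opts = opts)
  })
  names(models) <- levels(f)
  structure(list(models = models, levels = levels(f)),
            class = "one_vs_rest_model")
}

#' @export
predict.one_vs_rest_model <- function(object, X, ...) {
  probs <- vapply(object$models, function(m) predict(m, X)$prob,
                  numeric(nrow(as.matrix(X))))
  probs <- matrix(probs, ncol = length(object$models),
                  dimnames = list(NULL, object$levels))
  list(prob = probs,
       label = object$levels[max.col(probs, ties.method = "first")])
}
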