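# ---- imputation, class weighting, metrics, nested cross-validation

#' Inverse-frequency class balance weights
#'
#' `weight_c = n_total / (n_classes * n_c)`, so every class carries equal
#' total weight and the weights of all subjects sum to `n_total`.
#'
#' @param y class labels (factor or vector).
#' @return Named numeric vector of per-class weights.
#' @export
class_balance_weights <- function(y) {
  f <- if (is.factor(y)) droplevels(y) else factor(y)
  tab <- table(f)
  w <- length(f) / (nlevels(f) * as.numeric(tab))
  names(w) <- names(tab)
  w
}

# expand per-class weights to per-subject weights; NULL class_weights
# means unweighted (all ones)
.per_subject_weights <- function(f, class_weights) {
  if (is.null(class_weights)) return(rep(1, length(f)))
  if (is.null(names(class_weights)))
    stop("class_weights must be named by class")
  miss <- setdiff(levels(droplevels(f)), names(class_weights))
  if (length(miss)) stop("class_weights missing class(es): ",
                         paste(miss, collapse = ", "))
  as.numeric(class_weights[as.character(f)])
}

#' Train-mean imputation without test leakage
#'
#' Fills missing cells in both matrices with the column means computed on
#' the training matrix only.
#'
#' @param X_train,X_test numeric matrices with matching columns (`X_test`
#'   may be `NULL`).
#' @return List with filled `train` and `test` and the `means` used.
#' @export
impute_missing <- function(X_train, X_test = NULL) {
  X_train <- as.matrix(X_train)
  mu <- colMeans(X_train, na.rm = TRUE)
  bad <- !is.finite(mu)
  if (any(bad))
    stop("column(s) with no observed training values: ",
         paste(which(bad), collapse = ", "))
  fill <- function(X) {
    idx <- which(is.na(X), arr.ind = TRUE)
    if (nrow(idx)) X[idx] <- mu[idx[, 2L]]
    X
  }
  list(train = fill(X_train),
       test = if (!is.null(X_test)) fill(as.matrix(X_test)), means = mu)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with midrank tie handling.
#'
#' @param scores predicted scores, larger = more positive.
#' @param labels binary labels; the larger value / second factor level is
#'   positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.factor(labels)) as.integer(labels) == 2L
       else as.numeric(labels) == max(as.numeric(labels))
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged (balanced) F1 score
#'
#' F1 computed one-vs-rest per class and averaged with equal class weight;
#' a class with no predicted and no true positives contributes F1 = 0.
#'
#' @param predicted,truth class labels.
#' @return Balanced F1 in `[0, 1]`.
#' @export
balanced_f1 <- function(predicted, truth) {
  classes <- sort(unique(c(as.character(truth), as.character(predicted))))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1L))
  mean(f1)
}

# stratified k-fold assignment, deterministic given seed
.stratified_folds <- function(y, k, seed) {
  f <- if (is.factor(y)) droplevels(y) else factor(y)
  fold <- integer(length(f))
  .with_seed(seed, {
    for (cl in levels(f)) {
      idx <- sample(which(f == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  if (any(table(fold, f) == 0))
    stop("a class is absent from some fold; reduce k or add subjects")
  fold
}

#' Logarithmic hyperparameter grid
#'
#' Penalty strengths as fractions of the data-dependent `lambda_max` (the
#' smallest L1 strength that zeroes the weights at the unpenalized
#' intercept), crossed over the L1 and TV terms.
#'
#' @param n_l1,n_tv grid resolution per axis.
#' @param lo,hi log10 range of the fractions.
#' @return Data frame of `l1_frac`, `tv_frac` pairs.
#' @export
default_lambda_grid <- function(n_l1 = 5L, n_tv = 5L, lo = -3, hi = -0.5) {
  expand.grid(l1_frac = 10^seq(lo, hi, length.out = n_l1),
              tv_frac = 10^seq(lo, hi, length.out = n_tv))
}

# smallest lambda_l1 that zeroes w when fitting intercept only
.lambda_max <- function(X, y, task, class_weights) {
  if (task == "binary") {
    f <- droplevels(factor(y))
    y01 <- as.integer(f) - 1L
    wts <- .per_subject_weights(f, class_weights)
    pbar <- sum(wts * y01) / sum(wts)
    max(abs(crossprod(X, wts * (pbar - y01))))
  } else {
    f <- droplevels(factor(y))
    wts <- .per_subject_weights(f, class_weights)
    yk <- as.integer(f)
    # gradient of the cumulative-logit NLL in w at w = 0, empirical thetas
    sm <- .ordit_smooth(X, yk, nlevels(f), wts)
    cum <- cumsum(tapply(wts, yk, sum))[seq_len(nlevels(f) - 1L)] / sum(wts)
    theta0 <- stats::qlogis(pmin(pmax(cum, 1e-6), 1 - 1e-6))
    theta0 <- cummax(theta0 + seq_len(nlevels(f) - 1L) * 1e-6)
    a0 <- c(theta0[1L],
            if (nlevels(f) > 2L) log(expm1(pmax(diff(theta0), 1e-6))))
    g <- sm(c(numeric(ncol(X)), a0))$grad
    max(abs(g[seq_len(ncol(X))]))
  }
}

#' Nested cross-validated training of a structured classifier
#'
#' Outer `outer_k`-fold stratified CV estimates generalization; within each
#' outer training fold an inner `inner_k`-fold grid search selects the
#' (L1, TV) strengths maximizing the metric (ROC-AUC for binary tasks,
#' macro F1 for ordinal). Imputation means and class weights are computed
#' inside each training fold only. Metric ties are broken toward the
#' larger total penalty (the sparser, smoother model).
#'
#' @param X subjects x vertices features (may contain `NA`; train-mean
#'   imputed per fold).
#' @param y labels: 2-level factor (binary) or ordered stages (ordinal).
#' @param edges vertex edge matrix.
#' @param task `"binary"` or `"ordinal"`.
#' @param grid data frame of `l1_frac`, `tv_frac` (fractions of the
#'   data-dependent `lambda_max`), see [default_lambda_grid()].
#' @param outer_k,inner_k fold counts (both default 4).
#' @param metric `"roc_auc"` (binary default) or `"balanced_f1"` (ordinal
#'   default and the only option for ordinal tasks).
#' @param balance if `TRUE` (default), apply [class_balance_weights()]
#'   computed on each training fold.
#' @param select selection rule over the inner grid: `"1se"` (default)
#'   keeps every pair whose mean inner metric is within one standard error
#'   of the best and takes the most-penalized of them (the
#'   one-standard-error rule); `"best"` uses exact ties only.
#' @param seed integer seed; folds and hence the whole report are
#'   deterministic given it.
#' @param opts solver options for the fits.
#' @return An object of class `cv_report`: outer fold assignments, selected
#'   lambdas and metric per outer fold, mean metric, the final model
#'   refitted on all data at the modal selected lambdas, and `seed`.
#' @export
nested_cv <- function(X, y, edges, task = c("binary", "ordinal"),
                      grid = default_lambda_grid(), outer_k = 4L,
                      inner_k = 4L, metric = NULL, balance = TRUE,
                      select = c("1se", "best"), seed = 1L,
                      opts = solver_options(max_iter = 400L, tol = 1e-7,
                                            prox_tol = 1e-3,
                                            prox_iter = 50L)) {
  task <- match.arg(task)
  select <- match.arg(select)
  if (nrow(grid) == 0L) stop("empty hyperparameter grid")
  X <- as.matrix(X)
  y <- if (is.factor(y)) droplevels(y) else factor(y, levels = sort(unique(y)))
  metric <- metric %||% if (task == "binary") "roc_auc" else "balanced_f1"
  if (task == "ordinal" && metric != "balanced_f1")
    stop("ordinal tasks use the balanced F1 metric")
  fit_one <- function(Xtr, ytr, l1, tv, cw)
    if (task == "binary")
      fit_logit_tvl1(Xtr, ytr, l1, tv, edges, class_weights = cw, opts = opts)
    else
      fit_ordit(Xtr, ytr, l1, tv, edges, class_weights = cw, opts = opts)
  eval_metric <- function(model, Xte, yte) {
    pr <- predict(model, Xte)
    if (metric == "roc_auc") roc_auc(pr$score, yte)
    else balanced_f1(pr$label, as.character(yte))
  }
  outer_fold <- .stratified_folds(y, outer_k, .child_seed(seed, "outer"))
  fold_rows <- vector("list", outer_k)
  for (of in seq_len(outer_k)) {
    tr <- outer_fold != of
    Xtr_raw <- X[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
    inner_fold <- .stratified_folds(ytr, inner_k,
                                    .child_seed(seed, paste0("inner", of)))
    score <- matrix(NA_real_, nrow(grid), inner_k)
    for (inf in seq_len(inner_k)) {
      itr <- inner_fold != inf
      imp <- impute_missing(Xtr_raw[itr, , drop = FALSE],
                            Xtr_raw[!itr, , drop = FALSE])
      cw <- if (balance) class_balance_weights(ytr[itr])
      lmax <- .lambda_max(imp$train, ytr[itr], task, cw)
      for (g in seq_len(nrow(grid))) {
        m <- fit_one(imp$train, ytr[itr],
                     grid$l1_frac[g] * lmax, grid$tv_frac[g] * lmax, cw)
        score[g, inf] <- eval_metric(m, imp$test, ytr[!itr])
      }
    }
    mean_score <- rowMeans(score)
    best_idx <- which.max(mean_score)
    slack <- if (select == "1se")
      stats::sd(score[best_idx, ]) / sqrt(inner_k) else 1e-12
    cand <- which(mean_score >= mean_score[best_idx] - slack)
    pick <- cand[which.max(grid$l1_frac[cand] + grid$tv_frac[cand])]
    imp <- impute_missing(Xtr_raw, X[!tr, , drop = FALSE])
    cw <- if (balance) class_balance_weights(ytr)
    lmax <- .lambda_max(imp$train, ytr, task, cw)
    model <- fit_one(imp$train, ytr,
                     grid$l1_frac[pick] * lmax, grid$tv_frac[pick] * lmax, cw)
    fold_rows[[of]] <- data.frame(
      fold = of, l1_frac = grid$l1_frac[pick], tv_frac = grid$tv_frac[pick],
      lambda_l1 = grid$l1_frac[pick] * lmax,
      lambda_tv = grid$tv_frac[pick] * lmax,
      metric = eval_metric(model, imp$test, y[!tr]))
  }
  folds_df <- do.call(rbind, fold_rows)
  # final model on all data at the modal (most often selected) fractions
  sel <- paste(folds_df$l1_frac, folds_df$tv_frac)
  modal <- which.max(tabulate(factor(sel, levels = unique(sel))))
  imp <- impute_missing(X)
  cw <- if (balance) class_balance_weights(y)
  lmax <- .lambda_max(imp$train, y, task, cw)
  final <- fit_one(imp$train, y,
                   folds_df$l1_frac[modal] * lmax,
                   folds_df$tv_frac[modal] * lmax, cw)
  structure(list(task = task, metric = metric, outer_fold = outer_fold,
                 folds = folds_df, mean_metric = mean(folds_df$metric),
                 model = final, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s task, %d outer folds, mean %s = %.3f\n",
              x$task, nrow(x$folds), x$metric, x$mean_metric))
  invisible(x)
}

#' Serialize a fitted model (sparse weights) to JSON
#'
#' @param model a `structured_linear_model`.
#' @param path output JSON path.
#' @return `path` invisibly.
#' @export
write_model_json <- function(model, path) {
  nz <- which(model$w != 0)
  obj <- list(kind = model$kind, n_features = length(model$w),
              levels = model$levels,
              w_index = nz, w_value = model$w[nz],
              intercept = model$intercept, thresholds = model$thresholds,
              lambda_l1 = model$lambda_l1, lambda_tv = model$lambda_tv)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
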