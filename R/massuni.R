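#' Design specification for vertex-wise models
#'
#' @param predictor name of the predictor of interest: `"group"` (a group
#'   contrast column) or a clinical score column such as
#'   `"time_since_diagnosis"`, `"moca"`, `"updrs3"`.
#' @param nuisance nuisance covariate columns; defaults to age, sex, and
#'   intracranial volume.
#' @param grouping random-intercept grouping column (acquisition cohort).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(predictor = "group",
                        nuisance = c("age", "sex", "icv"),
                        grouping = "cohort_id") {
  structure(list(predictor = predictor, nuisance = nuisance,
                 grouping = grouping), class = "design_spec")
}

# build model frame; drops rows with missing values (complete-case per
# analysis) and validates the design
.design_frame <- function(design, data, y = NULL) {
  cols <- c(design$predictor, design$nuisance, design$grouping)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L)
    stop("design columns absent from data: ",
         paste(missing_cols, collapse = ", "))
  df <- data[, cols, drop = FALSE]
  # standardize numeric nuisance covariates: the target beta is invariant
  # to affine rescaling of nuisance columns, and conditioning improves
  for (nc in design$nuisance) {
    x <- df[[nc]]
    if (is.numeric(x) && stats::sd(x, na.rm = TRUE) > 0)
      df[[nc]] <- (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  }
  if (is.character(df[[design$predictor]])) {
    # locale-independent level order; pass a factor to control the
    # reference level explicitly (beta is level 2 vs level 1)
    lev <- sort(unique(df[[design$predictor]]), method = "radix")
    df[[design$predictor]] <- factor(df[[design$predictor]], levels = lev)
  }
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (length(unique(df[[design$predictor]])) < 2L)
    stop("predictor of interest '", design$predictor, "' is constant")
  X <- stats::model.matrix(
    stats::reformulate(c(design$predictor, design$nuisance)), df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (nrow(df) < ncol(X) + 2L)
    stop("need at least ", ncol(X) + 2L, " complete rows, have ", nrow(df))
  list(df = df, keep = keep, X = X)
}

#' Fit the linear mixed model at one vertex
#'
#' REML fit of `y ~ predictor + nuisance + (1 | cohort)` via `lme4::lmer`,
#' returning the coefficient of the predictor of interest, its standard
#' error, and a two-sided Wald (normal) p-value. When the grouping factor
#' has a single level, or the random-intercept variance is estimated at the
#' zero boundary, the result coincides with the ordinary-least-squares fit.
#'
#' @param y per-subject thickness (mm) at one vertex.
#' @param design a `design_spec`.
#' @param data a `cohort_table` (or data frame) aligned with `y`.
#' @return Named numeric vector `c(beta, se, p)` for the first contrast of
#'   the predictor of interest.
#' @export
fit_vertex_lmm <- function(y, design, data) {
  prep <- .design_frame(design, data)
  df <- prep$df
  df$.y <- y[prep$keep]
  .lmm_engine(design, df)$coef
}

# shared fitting core; returns coef and, for multi-level grouping, the
# fitted lmer object for fast refitting across vertices
.lmm_engine <- function(design, df) {
  target <- .target_term(design, df)
  if (length(unique(df[[design$grouping]])) < 2L) {
    fml <- stats::reformulate(c(design$predictor, design$nuisance),
                              response = ".y")
    fit <- stats::lm(fml, data = df)
    sm <- summary(fit)$coefficients
    return(list(coef = .wald_row(sm, target), fit = NULL))
  }
  fml <- stats::as.formula(paste(
    ".y ~", paste(c(design$predictor, design$nuisance), collapse = " + "),
    "+ (1 |", design$grouping, ")"))
  fit <- suppressMessages(lme4::lmer(
    fml, data = df, REML = TRUE, control = .lmm_control()))
  sm <- stats::coef(summary(fit))
  list(coef = .wald_row(sm, target), fit = fit)
}

# tight variance-parameter optimization so per-vertex refits agree with
# fresh fits to numerical precision
.lmm_control <- function() {
  lme4::lmerControl(calc.derivs = FALSE, optimizer = "bobyqa",
                    optCtrl = list(rhobeg = 0.2, rhoend = 2e-9))
}

# name of the coefficient of interest in the fitted model
.target_term <- function(design, df) {
  x <- df[[design$predictor]]
  if (is.factor(x)) paste0(design$predictor, levels(x)[2L])
  else design$predictor
}

.wald_row <- function(sm, term) {
  if (!term %in% rownames(sm)) stop("coefficient '", term, "' not in fit")
  b <- sm[term, "Estimate"]; se <- sm[term, "Std. Error"]
  c(beta = b, se = se, p = 2 * stats::pnorm(-abs(b / se)))
}

#' Vertex-wise effect map
#'
#' Applies [fit_vertex_lmm()] independently at every vertex (with a shared
#' model skeleton refitted per vertex for speed). Vertices where the fit
#' fails get `beta = 0`, `se = NA`, `p = 1` and a warning is collected.
#'
#' @param thickness subjects x vertices matrix aligned with `data` rows.
#' @param design a `design_spec`.
#' @param data a `cohort_table` aligned with `thickness` rows.
#' @return An object of class `effect_map`: data frame with columns
#'   `vertex`, `beta`, `se`, `p` (and later `sig` from
#'   [searchlight_fdr()]).
#' @export
map_effects <- function(thickness, design, data) {
  if (nrow(thickness) != nrow(data))
    stop("thickness rows (", nrow(thickness), ") and cohort rows (",
         nrow(data), ") are misaligned")
  if (!is.null(rownames(thickness)) && !is.null(data$subject_id) &&
      !identical(rownames(thickness), as.character(data$subject_id)))
    stop("thickness row names and cohort subject ids are misaligned")
  prep <- .design_frame(design, data)
  df <- prep$df
  V <- ncol(thickness)
  out <- matrix(NA_real_, V, 3L, dimnames = list(NULL, c("beta", "se", "p")))
  n_fail <- 0L
  for (v in seq_len(V)) {
    df$.y <- thickness[prep$keep, v]
    res <- tryCatch(.lmm_engine(design, df)$coef,
                    error = function(e) NULL)
    if (is.null(res)) {
      n_fail <- n_fail + 1L
      out[v, ] <- c(0, NA, 1)
    } else out[v, ] <- res
  }
  if (n_fail > 0L)
    warning(n_fail, " vertex fit(s) failed; assigned p = 1")
  structure(data.frame(vertex = seq_len(V), out),
            class = c("effect_map", "data.frame"),
            design = design)
}

#' Searchlight false discovery rate correction
#'
#' For each vertex, Benjamini-Hochberg at level `q` is applied to the
#' p-values of its geodesic neighbourhood (all vertices within
#' `radius_hops` edge hops); the vertex is declared significant iff its own
#' p-value passes its neighbourhood's BH threshold. `radius_hops = Inf`
#' reduces to global BH. An isolated vertex at radius 0 is a single test
#' (significant iff `p <= q`).
#'
#' @param p per-vertex p-values.
#' @param edges undirected edge matrix over vertex indices (e.g.
#'   `atlas$edges`), or an adjacency list.
#' @param radius_hops neighbourhood radius in edge hops (default 5).
#' @param q FDR level in (0, 1).
#' @return Logical significance mask.
#' @export
searchlight_fdr <- function(p, edges, radius_hops = 5, q = 0.05) {
  stopifnot(q > 0, q < 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  V <- length(p)
  bh_thresh <- function(pv) {
    # largest p_(i) <= (i/m) q, else -Inf
    m <- length(pv)
    ps <- sort(pv)
    ok <- ps <= (seq_len(m) / m) * q
    if (any(ok)) ps[max(which(ok))] else -Inf
  }
  if (is.infinite(radius_hops)) {
    thr <- bh_thresh(p)
    return(!is.na(p) & p <= thr)
  }
  adj <- if (is.list(edges)) edges else .adjacency_list(edges, V)
  sig <- logical(V)
  for (v in seq_len(V)) {
    if (is.na(p[v])) next
    nb <- .bfs_ball(adj, v, radius_hops)
    pv <- p[nb]
    pv <- pv[!is.na(pv)]
    sig[v] <- p[v] <= bh_thresh(pv)
  }
  sig
}

#' Apply searchlight FDR to an effect map
#'
#' @param map an `effect_map`.
#' @param atlas a `mesh_atlas` supplying the vertex adjacency.
#' @param radius_hops,q see [searchlight_fdr()].
#' @return The map with a logical `sig` column and attribute `q_level`.
#' @export
threshold_map <- function(map, atlas, radius_hops = 5, q = 0.05) {
  map$sig <- searchlight_fdr(map$p, atlas$edges, radius_hops, q)
  attr(map, "q_level") <- q
  map
}

#' Per-structure summary of an effect map
#'
#' For each structure: the percentage of its vertices that are significant
#' and the peak beta (the signed coefficient of greatest magnitude among
#' significant vertices; 0 when none are significant) — the reporting
#' convention `[% significant, peak beta]`.
#'
#' @param map a thresholded `effect_map` (with `sig` column).
#' @param atlas a `mesh_atlas`.
#' @return Data frame with columns `structure`, `hemisphere`,
#'   `pct_significant`, `peak_beta`.
#' @export
summarize_map <- function(map, atlas) {
  if (is.null(map$sig)) stop("map has no significance mask; run threshold_map()")
  if (nrow(map) != atlas$n_vertices)
    stop("map length does not match atlas vertex count")
  off <- atlas$offsets
  out <- off[, c("structure", "hemisphere")]
  out$pct_significant <- NA_real_
  out$peak_beta <- NA_real_
  for (i in seq_len(nrow(off))) {
    idx <- seq.int(off$start[i], off$end[i])
    s <- map$sig[idx]
    out$pct_significant[i] <- 100 * sum(s) / length(idx)
    out$peak_beta[i] <- if (any(s)) {
      b <- map$beta[idx][s]
      b[which.max(abs(b))]
    } else 0
  }
  out
}

#' Write / read an effect map as TSV
#'
#' @param map an `effect_map`.
#' @param path TSV path.
#' @return `path` invisibly ([write_effect_map()]); an `effect_map`
#'   ([read_effect_map()]).
#' @export
write_effect_map <- function(map, path) {
  df <- as.data.frame(map)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_effect_map
#' @export
read_effect_map <- function(path) {
  df <- utils::read.delim(path)
  class(df) <- c("effect_map", "data.frame")
  df
}
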