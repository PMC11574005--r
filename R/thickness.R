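#' Effect specification for the thickness generator
#'
#' An `effect_spec` describes the generative model for vertex-wise
#' thickness: fixed nuisance effects of age, sex and intracranial volume, a
#' cohort random intercept, i.i.d. vertex noise, and a list of stage-
#' dependent, spatially smooth local effects ("bumps"). Each bump is a
#' geodesic Gaussian on one structure's mesh graph:
#' `delta_v(stage) = amplitude[stage] * exp(-hops(v, center)^2 / (2 * radius^2))`
#' with `hops` the edge-hop distance from the bump center.
#'
#' @param effects list of bumps; each a list with `structure`, `hemisphere`
#'   (`"both"` expands to left+right), `center_dir` (length-3 unit direction
#'   on the registration sphere; the nearest vertex is the bump center) or
#'   `center` (local vertex index), `radius` (hops, > 0), and `amp` (length-5
#'   numeric: signed peak amplitude in mm at analysis stages 1..5).
#' @param beta_age,beta_sex,beta_icv nuisance coefficients (mm per year,
#'   mm, mm per mm^3); applied to age - 65, sex, and icv - 1.5e6 so that
#'   simulated thickness stays near the structural baseline.
#' @param cohort_sd standard deviation (mm) of the cohort random intercept.
#' @param residual_sd standard deviation (mm) of the vertex-level noise.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(effects = list(), beta_age = -0.01, beta_sex = 0.1,
                        beta_icv = 2e-7, cohort_sd = 0.1,
                        residual_sd = 0.2) {
  stopifnot(residual_sd > 0, cohort_sd >= 0)
  for (e in effects) {
    stopifnot(e$radius > 0, length(e$amp) == 5L)
  }
  structure(list(effects = effects, beta_age = beta_age,
                 beta_sex = beta_sex, beta_icv = beta_icv,
                 cohort_sd = cohort_sd, residual_sd = residual_sd),
            class = "effect_spec")
}

#' Default stage-effect specification
#'
#' Encodes the qualitative staging pattern of Parkinson's disease shape
#' studies as a generative target: focal putamen thinning growing from the
#' mildest stage, caudate and amygdala thinning from stage 2, hippocampus,
#' accumbens and thalamus thinning from stage 3, pallidum thinning only at
#' stages 4-5, and a focal thalamic subregion that is *thicker* at stages 1
#' and 2 and normalizes later. Peak amplitudes (0.1-0.3 mm) are on the
#' scale of reported peak vertex effects; radii are in mesh hops.
#'
#' @param radius bump radius in edge hops.
#' @return An `effect_spec`.
#' @export
default_effect_spec <- function(radius = 6) {
  both <- function(structure, dir, amp, r = radius)
    list(structure = structure, hemisphere = "both", center_dir = dir,
         radius = r, amp = amp)
  effect_spec(effects = list(
    both("putamen", c(0, 1, 0),  -c(0.12, 0.17, 0.22, 0.28, 0.32)),
    both("putamen", c(0, 0, 1),  -c(0.00, 0.08, 0.14, 0.20, 0.24)),
    both("caudate", c(0, 1, 0),  -c(0.00, 0.10, 0.16, 0.22, 0.26)),
    both("amygdala", c(1, 0, 0), -c(0.00, 0.08, 0.14, 0.20, 0.24)),
    both("hippocampus", c(0, 1, 0), -c(0, 0.00, 0.12, 0.18, 0.22)),
    both("accumbens", c(0, 0, 1),  -c(0, 0.00, 0.10, 0.16, 0.20)),
    both("thalamus", c(0, -1, 0),  -c(0, 0.00, 0.10, 0.16, 0.20)),
    both("pallidum", c(0, 1, 0),   -c(0, 0.00, 0.00, 0.14, 0.20)),
    both("thalamus", c(0, 0, 1),    c(0.16, 0.13, 0.00, 0.00, 0.00))))
}

# resolve a bump's center to a local vertex index within its structure
.resolve_center <- function(entry, sphere_coords) {
  if (!is.null(entry[["center"]])) return(as.integer(entry[["center"]]))
  d <- sphere_coords %*% (entry$center_dir / sqrt(sum(entry$center_dir^2)))
  which.max(d)
}

# per-stage (5 x V) matrix of planted vertex effects
.stage_deltas <- function(atlas, spec) {
  V <- atlas$n_vertices
  delta <- matrix(0, 5L, V)
  adj <- .atlas_adjacency(atlas)
  for (e in spec$effects) {
    hemis <- if (identical(e$hemisphere, "both")) c("left", "right")
             else e$hemisphere
    for (h in hemis) {
      idx <- tryCatch(atlas_vertex_range(atlas, e$structure, h),
                      error = function(err) NULL)
      if (is.null(idx)) next  # structure absent from this atlas
      s <- atlas$structures[[paste(e$structure, h)]]
      local_center <- .resolve_center(e, s$sphere)
      if (local_center < 1L || local_center > length(idx))
        stop("bump center vertex out of range for ", e$structure)
      gcenter <- idx[local_center]
      hops <- .bfs_hops(adj, gcenter, max_hops = ceiling(3 * e$radius))
      w <- exp(-hops^2 / (2 * e$radius^2))
      w[!is.finite(hops)] <- 0
      for (st in 1:5) delta[st, ] <- delta[st, ] + e$amp[st] * w
    }
  }
  delta
}

#' Simulate a subjects-by-vertices thickness matrix
#'
#' Generates `thickness[i, v] = baseline(v) + beta_age (age_i - 65) +
#' beta_sex sex_i + beta_icv (icv_i - 1.5e6) + u_cohort(i) + delta_v(stage_i)
#' + eps_iv`, with `baseline` the atlas template's own radial thickness,
#' `u_cohort ~ N(0, cohort_sd^2)`, `delta` the effect specification's
#' stage bumps (zero for
#' controls), and `eps ~ N(0, residual_sd^2)` i.i.d. Values are clipped to
#' a 0.01 mm floor; clipping is reported via the `n_clipped` attribute and
#' a warning.
#'
#' @param atlas a `mesh_atlas`.
#' @param cohort a `cohort_table`.
#' @param spec an `effect_spec`.
#' @param seed integer seed; bit-for-bit deterministic given it.
#' @param baseline optional precomputed per-vertex baseline (mm); computed
#'   from the atlas meshes when `NULL`.
#' @return Numeric matrix (subjects x vertices), rows named by subject id,
#'   with attributes `baseline` and `n_clipped`.
#' @export
simulate_thickness <- function(atlas, cohort, spec = default_effect_spec(),
                               seed = 1L, baseline = NULL) {
  stopifnot(inherits(atlas, "mesh_atlas"), inherits(spec, "effect_spec"))
  n <- nrow(cohort); V <- atlas$n_vertices
  if (is.null(baseline)) baseline <- atlas_baseline_thickness(atlas)
  stopifnot(length(baseline) == V)
  delta <- .stage_deltas(atlas, spec)
  stage <- regroup_stage(cohort$hy_stage)
  .with_seed(seed, {
    cohort_levels <- sort(unique(cohort$cohort_id))
    u <- stats::rnorm(length(cohort_levels), 0, spec$cohort_sd)
    names(u) <- cohort_levels
    subj_shift <- spec$beta_age * (cohort$age - 65) +
      spec$beta_sex * cohort$sex + spec$beta_icv * (cohort$icv - 1.5e6) +
      if (n > 0) u[cohort$cohort_id] else numeric(0)
    mat <- matrix(stats::rnorm(n * V, 0, spec$residual_sd), n, V)
    mat <- mat + rep(baseline, each = n) + subj_shift
    planted <- !is.na(stage)
    if (any(planted))
      mat[planted, ] <- mat[planted, ] + delta[stage[planted], , drop = FALSE]
    nclip <- sum(mat < 0.01)
    if (nclip > 0) {
      warning(nclip, " thickness value(s) clipped to the 0.01 mm floor")
      mat[mat < 0.01] <- 0.01
    }
    rownames(mat) <- cohort$subject_id
    attr(mat, "baseline") <- baseline
    attr(mat, "n_clipped") <- nclip
    mat
  })
}

#' Template radial thickness of every atlas vertex
#'
#' Fits a medial curve to each structure mesh and returns the concatenated
#' per-vertex radial distances, the baseline around which the generator
#' simulates individual thickness.
#'
#' @param atlas a `mesh_atlas`.
#' @param n_sections,smoothing medial-curve settings per structure.
#' @return Numeric vector of length `atlas$n_vertices`.
#' @export
atlas_baseline_thickness <- function(atlas, n_sections = 10L, smoothing = 0) {
  out <- numeric(atlas$n_vertices)
  for (i in seq_along(atlas$structures)) {
    mesh <- atlas$structures[[i]]$mesh
    # coarse meshes cannot support many sections; keep >= ~12 vertices each
    ns <- max(2L, min(n_sections, nrow(mesh$vertices) %/% 12L))
    cv <- fit_medial_curve(mesh, n_sections = ns,
                           smoothing = smoothing)
    idx <- seq.int(atlas$offsets$start[i], atlas$offsets$end[i])
    out[idx] <- radial_thickness(mesh, cv)
  }
  out
}

#' Write / read a thickness matrix as TSV
#'
#' Subjects in rows (first column `subject_id`), vertices in columns named
#' `v<global index>`.
#'
#' @param thickness subjects x vertices matrix with subject-id rownames.
#' @param path TSV path.
#' @return `path` invisibly ([write_thickness()]); a matrix
#'   ([read_thickness()]).
#' @export
write_thickness <- function(thickness, path) {
  df <- data.frame(subject_id = rownames(thickness),
                   thickness, check.names = FALSE)
  colnames(df) <- c("subject_id", paste0("v", seq_len(ncol(thickness))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_thickness
#' @export
read_thickness <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
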