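#' Default covariate distributions for the synthetic cohort
#'
#' Means and spreads emulating a large multi-cohort Parkinson's disease
#' sample: patients average 63.7 +/- 9.8 years and 35% female, controls
#' 60.0 +/- 12.2 years and 46% female; time since diagnosis lengthens,
#' MoCA falls and MDS-UPDRS3 rises monotonically with HY stage. Missing
#' clinical scores are generated completely at random at roughly the rates
#' such consortium data show (about half of patients lack MoCA and UPDRS3,
#' few lack disease duration).
#'
#' @return Nested list of distribution parameters; edit and pass to
#'   [simulate_cohort()].
#' @export
default_cohort_params <- function() {
  list(
    age = list(pd_mean = 63.7, pd_sd = 9.8, hc_mean = 60.0, hc_sd = 12.2),
    female_prop = list(pd = 0.35, hc = 0.46),
    icv = list(mean = 1.5e6, sd = 1.5e5),                 # mm^3
    # per analysis stage 1..5 (1.5/2.5 inherit from their floor stage)
    duration = list(mean = c(2.5, 5, 8, 10.5, 12.5), sd = 3, min = 0.1),
    moca = list(mean = c(27, 26, 24.5, 23, 21), sd = 3,
                hc_mean = 27.7, hc_sd = 1.8),
    updrs3 = list(mean = c(20, 27, 35, 45, 55), sd = 12),
    missing = list(duration = 0.07, moca = 0.5, updrs3 = 0.55),
    cohort_age_sd = 2,       # between-cohort shift of mean age
    cohort_icv_sd = 3e4)     # between-cohort shift of mean ICV
}

#' Simulate a multi-cohort staged cohort table
#'
#' Draws subjects per group with stage-dependent clinical scores: higher
#' stages have longer time since diagnosis, lower MoCA, and higher
#' MDS-UPDRS3, mirroring the monotone clinical gradient across HY stages.
#' Subjects are spread over `n_cohorts` acquisition cohorts with small
#' cohort-level shifts in mean age and ICV.
#'
#' @param n_per_group named integer vector of group sizes; names are
#'   `"control"` and raw modified-HY stages among
#'   `"1", "1.5", "2", "2.5", "3", "4", "5"`.
#' @param n_cohorts number of acquisition cohorts (>= 1).
#' @param params distribution parameters, see [default_cohort_params()].
#' @param seed integer seed; output is deterministic given it.
#' @return A `data.frame` (class `cohort_table`) with columns `subject_id`,
#'   `group` (`"PD"`/`"control"`), `hy_stage` (raw modified stage, `NA` for
#'   controls), `age`, `sex` (0 = male, 1 = female), `icv`, `cohort_id`,
#'   `time_since_diagnosis`, `moca`, `updrs3`.
#' @export
simulate_cohort <- function(n_per_group = c(control = 200, `1` = 60,
                                            `1.5` = 10, `2` = 120,
                                            `2.5` = 15, `3` = 60,
                                            `4` = 20, `5` = 10),
                            n_cohorts = 5L,
                            params = default_cohort_params(),
                            seed = 1L) {
  if (any(n_per_group < 0)) stop("group sizes must be nonnegative")
  if (n_cohorts < 1L) stop("n_cohorts must be >= 1")
  valid <- c("control", "1", "1.5", "2", "2.5", "3", "4", "5")
  if (!all(names(n_per_group) %in% valid))
    stop("unknown group label(s): ",
         paste(setdiff(names(n_per_group), valid), collapse = ", "))
  .with_seed(seed, {
    ca <- stats::rnorm(n_cohorts, 0, params$cohort_age_sd)
    ci <- stats::rnorm(n_cohorts, 0, params$cohort_icv_sd)
    rows <- lapply(names(n_per_group), function(g) {
      n <- n_per_group[[g]]
      if (n == 0L) return(NULL)
      is_pd <- g != "control"
      cohort <- sample.int(n_cohorts, n, replace = TRUE)
      sex_p <- if (is_pd) params$female_prop$pd else params$female_prop$hc
      age_m <- if (is_pd) params$age$pd_mean else params$age$hc_mean
      age_s <- if (is_pd) params$age$pd_sd else params$age$hc_sd
      stage_idx <- if (is_pd) floor(as.numeric(g)) else NA_integer_
      dur <- moca <- up3 <- rep(NA_real_, n)
      if (is_pd) {
        dur <- pmax(stats::rnorm(n, params$duration$mean[stage_idx],
                                 params$duration$sd), params$duration$min)
        moca <- round(pmin(pmax(stats::rnorm(
          n, params$moca$mean[stage_idx], params$moca$sd), 0), 30))
        up3 <- round(pmax(stats::rnorm(
          n, params$updrs3$mean[stage_idx], params$updrs3$sd), 0))
        dur[stats::runif(n) < params$missing$duration] <- NA
        moca[stats::runif(n) < params$missing$moca] <- NA
        up3[stats::runif(n) < params$missing$updrs3] <- NA
      } else {
        moca <- round(pmin(pmax(stats::rnorm(
          n, params$moca$hc_mean, params$moca$hc_sd), 0), 30))
        moca[stats::runif(n) < params$missing$moca] <- NA
      }
      data.frame(
        group = if (is_pd) "PD" else "control",
        hy_stage = if (is_pd) as.numeric(g) else NA_real_,
        age = pmax(stats::rnorm(n, age_m + ca[cohort], age_s), 18),
        sex = as.integer(stats::runif(n) < sex_p),
        icv = pmax(stats::rnorm(n, params$icv$mean + ci[cohort],
                                params$icv$sd), 8e5),
        cohort_id = paste0("cohort", cohort),
        time_since_diagnosis = dur, moca = moca, updrs3 = up3)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(group = character(), hy_stage = numeric(),
                        age = numeric(), sex = integer(), icv = numeric(),
                        cohort_id = character(),
                        time_since_diagnosis = numeric(), moca = numeric(),
                        updrs3 = numeric())
    out <- cbind(subject_id = sprintf("S%04d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Regroup modified HY stages for analysis
#'
#' Subjects staged 1.5 or 2.5 on the modified scale are regrouped into
#' stage 2; integer stages are unchanged.
#'
#' @param raw_stage numeric vector of raw modified-HY stages
#'   (`NA` allowed, passed through).
#' @return Numeric vector of analysis stages in `{1, 2, 3, 4, 5}`.
#' @export
regroup_stage <- function(raw_stage) {
  ok <- is.na(raw_stage) | raw_stage %in% c(1, 1.5, 2, 2.5, 3, 4, 5)
  if (!all(ok))
    stop("invalid modified HY stage value(s): ",
         paste(unique(raw_stage[!ok]), collapse = ", "))
  out <- raw_stage
  out[!is.na(out) & out %in% c(1.5, 2.5)] <- 2
  out
}

#' Merge severe stages into a combined class
#'
#' Scheme `"HY45"` merges stages 4 and 5 (used for the mass-univariate
#' stage contrasts); scheme `"HY345"` merges 3, 4, and 5 (used for the
#' ordinal classifier's three classes HY1, HY2, HY345).
#'
#' @param stages numeric vector of analysis stages (see [regroup_stage()]).
#' @param scheme `"HY45"` or `"HY345"`.
#' @return Character factor-like vector of grouped labels
#'   (`"HY1"`, `"HY2"`, ... `"HY45"`/`"HY345"`); `NA` passed through.
#' @export
group_stages <- function(stages, scheme = c("HY45", "HY345")) {
  scheme <- match.arg(scheme)
  stages <- regroup_stage(stages)
  out <- rep(NA_character_, length(stages))
  if (scheme == "HY45") {
    out[!is.na(stages) & stages <= 3] <- paste0("HY", stages[!is.na(stages) & stages <= 3])
    out[!is.na(stages) & stages >= 4] <- "HY45"
  } else {
    out[!is.na(stages) & stages <= 2] <- paste0("HY", stages[!is.na(stages) & stages <= 2])
    out[!is.na(stages) & stages >= 3] <- "HY345"
  }
  out
}

#' Greedy nearest-neighbour matching of controls to cases
#'
#' Selects for each case up to `ratio` controls nearest in standardized
#' covariate distance, without replacement. Cases are processed in
#' descending order of their distance to the control pool (hardest first).
#' By default sex must match exactly (cross-sex distance is infinite).
#'
#' @param cases,controls `cohort_table` rows (data frames).
#' @param covariates columns used in the distance (standardized jointly).
#' @param exact columns that must match exactly; default `"sex"`.
#' @param ratio maximum controls selected per case.
#' @param caliper optional maximum standardized distance; candidates beyond
#'   it are not matched.
#' @param seed integer seed used only to break exact distance ties.
#' @return The selected subset of `controls` (rows, original order).
#' @export
match_controls <- function(cases, controls, covariates = c("age"),
                           exact = c("sex"), ratio = 1L, caliper = NULL,
                           seed = 1L) {
  if (nrow(controls) == 0L) stop("empty control pool")
  if (nrow(cases) == 0L) return(controls[0L, , drop = FALSE])
  for (cv in c(covariates, exact)) {
    if (anyNA(cases[[cv]]) || anyNA(controls[[cv]]))
      stop("missing values in matching covariate '", cv, "'")
  }
  allv <- rbind(cases[, covariates, drop = FALSE],
                controls[, covariates, drop = FALSE])
  mu <- colMeans(allv); sdv <- pmax(apply(allv, 2L, stats::sd), 1e-12)
  zc <- sweep(sweep(as.matrix(cases[, covariates, drop = FALSE]), 2L, mu), 2L, sdv, `/`)
  zk <- sweep(sweep(as.matrix(controls[, covariates, drop = FALSE]), 2L, mu), 2L, sdv, `/`)
  d <- outer(rowSums(zc^2), rep(1, nrow(zk))) - 2 * zc %*% t(zk) +
    outer(rep(1, nrow(zc)), rowSums(zk^2))
  d <- sqrt(pmax(d, 0))
  for (cv in exact) {
    mism <- outer(cases[[cv]], controls[[cv]], `!=`)
    d[mism] <- Inf
  }
  # deterministic tie-breaking: tiny seed-keyed perturbation of ranks
  eps <- .with_seed(seed, matrix(stats::runif(length(d)), nrow(d))) * 1e-9
  order_cases <- order(apply(d, 1L, min), decreasing = TRUE)
  taken <- logical(nrow(controls))
  for (r in seq_len(ratio)) {
    for (i in order_cases) {
      di <- d[i, ] + eps[i, ]
      di[taken] <- Inf
      j <- which.min(di)
      if (!is.finite(d[i, j])) next
      if (!is.null(caliper) && d[i, j] > caliper) next
      taken[j] <- TRUE
    }
  }
  controls[taken, , drop = FALSE]
}

#' Write / read a cohort table as CSV
#'
#' @param cohort a `cohort_table`.
#' @param path CSV path.
#' @return `path` invisibly ([write_cohort()]); a `cohort_table`
#'   ([read_cohort()]).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}
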