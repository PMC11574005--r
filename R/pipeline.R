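# ---- end-to-end orchestration: simulate -> thickness -> mass-univariate
# ---- -> spin similarity -> classification, from one config

#' Default (demo-scale) pipeline configuration
#'
#' A small but complete configuration: a four-structure atlas (bilateral
#' putamen with planted stage-dependent thinning, bilateral pallidum with
#' no planted effect at mild stages), a staged multi-cohort sample, the
#' full analysis list, and reduced rotation / grid counts so the whole
#' pipeline runs in minutes. All fields can be overridden.
#'
#' @param seed master seed; every random stage derives a named child seed
#'   from it.
#' @return Nested configuration list understood by [run_pipeline()].
#' @export
demo_pipeline_config <- function(seed = 7L) {
  list(
    seed = seed,
    atlas = list(config = demo_atlas_config()),
    cohort = list(
      n_per_group = c(control = 160, `1` = 50, `1.5` = 8, `2` = 90,
                      `2.5` = 10, `3` = 50, `4` = 18, `5` = 8),
      n_cohorts = 4L),
    # putamen carries the planted stage-progressive thinning plus a focal
    # early thickening; the pallidum is the zero-effect control structure
    effects = list(spec = effect_spec(effects = list(
      list(structure = "putamen", hemisphere = "both",
           center_dir = c(0, 1, 0), radius = 3,
           amp = -c(0.12, 0.17, 0.22, 0.28, 0.32)),
      list(structure = "putamen", hemisphere = "both",
           center_dir = c(0, 0, 1), radius = 3,
           amp = c(0.15, 0.12, 0, 0, 0))))),
    analyses = list(
      case_control = TRUE,
      stage_contrasts = TRUE,
      clinical = c("time_since_diagnosis"),
      spin_pairs = "consecutive",
      classification = c("pd_vs_control", "hy1_vs_hy2", "hy2_vs_hy345",
                         "ordinal")),
    match = list(covariates = "age", exact = "sex", ratio = 2L),
    q = 0.05, radius_hops = 3L,
    n_rotations = 200L,
    cv = list(outer_k = 4L, inner_k = 4L,
              grid = default_lambda_grid(2L, 2L, lo = -2, hi = -0.75),
              max_iter = 150L))
}

# demo-scale effect spec: stage-progressive putamen thinning, pallidum
# untouched until stage 4 (the negative-control structure at mild stages)
.pipeline_effect_spec <- function(cfg) {
  if (!is.null(cfg$effects$spec)) return(cfg$effects$spec)
  default_effect_spec(radius = cfg$effects$radius %||% 6)
}

.log_line <- function(con, stage, msg) {
  line <- sprintf("[%s] %-14s %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Validate thickness / cohort / atlas alignment
#'
#' Checks subject alignment, vertex-count match, covariate ranges, and
#' stage validity. Issues are returned as data, not raised as errors.
#'
#' @param thickness subjects x vertices matrix.
#' @param cohort a `cohort_table`.
#' @param atlas a `mesh_atlas`.
#' @return Data frame with columns `check` and `detail`; zero rows when
#'   everything is consistent.
#' @export
validate_inputs <- function(thickness, cohort, atlas) {
  issues <- list()
  add <- function(check, detail)
    issues[[length(issues) + 1L]] <<- data.frame(check = check,
                                                 detail = detail)
  if (nrow(thickness) != nrow(cohort))
    add("subject_count", sprintf("thickness has %d rows, cohort %d",
                                 nrow(thickness), nrow(cohort)))
  else if (!is.null(rownames(thickness)) &&
           !identical(rownames(thickness), as.character(cohort$subject_id)))
    add("subject_order", "thickness row names differ from cohort subject ids")
  if (ncol(thickness) != atlas$n_vertices)
    add("vertex_count", sprintf("thickness has %d columns, atlas %d vertices",
                                ncol(thickness), atlas$n_vertices))
  if (any(thickness <= 0, na.rm = TRUE))
    add("thickness_range", "non-positive thickness values present")
  if (any(cohort$age <= 0, na.rm = TRUE)) add("age_range", "non-positive age")
  if (any(cohort$icv <= 0, na.rm = TRUE)) add("icv_range", "non-positive ICV")
  if (!is.null(cohort$moca) &&
      any(cohort$moca < 0 | cohort$moca > 30, na.rm = TRUE))
    add("moca_range", "MoCA outside [0, 30]")
  bad_stage <- !is.na(cohort$hy_stage) &
    !cohort$hy_stage %in% c(1, 1.5, 2, 2.5, 3, 4, 5)
  if (any(bad_stage))
    add("stage_values", paste("invalid HY stage:",
                              paste(unique(cohort$hy_stage[bad_stage]),
                                    collapse = ", ")))
  if (any(cohort$group == "control" & !is.na(cohort$hy_stage)))
    add("control_stage", "control subject(s) carry an HY stage")
  if (length(issues) == 0L)
    data.frame(check = character(), detail = character())
  else do.call(rbind, issues)
}

# fit one group contrast (cases vs matched controls) and write outputs
.run_contrast <- function(name, cases, controls, thickness, atlas, cfg,
                          out_dir, log) {
  cases <- cases[, names(controls), drop = FALSE]
  matched <- match_controls(cases, controls,
                            covariates = cfg$match$covariates,
                            exact = cfg$match$exact,
                            ratio = cfg$match$ratio,
                            seed = .child_seed(cfg$seed, paste0("match_", name)))
  dat <- rbind(controls[controls$subject_id %in% matched$subject_id, ],
               cases)
  dat$group <- factor(dat$group, levels = c("control", "PD"))
  th <- thickness[match(dat$subject_id, rownames(thickness)), , drop = FALSE]
  map <- map_effects(th, design_spec("group"), dat)
  map <- threshold_map(map, atlas, radius_hops = cfg$radius_hops, q = cfg$q)
  summ <- summarize_map(map, atlas)
  write_effect_map(map, file.path(out_dir, paste0("map_", name, ".tsv")))
  utils::write.table(cbind(contrast = name, summ),
                     file.path(out_dir, paste0("summary_", name, ".tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log("massuni", sprintf("%s: n=%d cases, %d matched controls, %d sig vertices",
                         name, nrow(cases), nrow(matched), sum(map$sig)))
  map
}

#' Run the full shape-staging pipeline
#'
#' Simulates the atlas, cohort and thickness data, then runs the analysis
#' sequence: case-control and per-stage mass-univariate contrasts against
#' age/sex-matched controls with searchlight FDR, clinical-score
#' correlations, spin-test spatial similarity between consecutive stage
#' maps per structure, and the binary / ordinal structured classifiers
#' with nested cross-validation. Every numeric output is reproduced
#' bit-for-bit when re-run with the same configuration.
#'
#' @param config configuration list, see [demo_pipeline_config()].
#' @param out_dir output directory (created; existing files overwritten).
#' @return `out_dir` invisibly. Outputs: effect-map and summary TSVs,
#'   `spin_*.json`, `cv_*.json`, `weights_*.tsv`, `validation.tsv`,
#'   `manifest.json`, and `pipeline.log`.
#' @export
run_pipeline <- function(config = demo_pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out_dir, "pipeline.log"), "w")
  log <- function(stage, msg) .log_line(logcon, stage, msg)
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) file.remove(failed_marker)
  stage_name <- "setup"
  result <- tryCatch({
    cfg <- config
    log("setup", sprintf("master seed %d", cfg$seed))

    stage_name <- "atlas"
    atlas <- build_atlas(cfg$atlas$config %||% default_atlas_config(),
                         seed = .child_seed(cfg$seed, "atlas"))
    log("atlas", sprintf("%d structures, %d vertices",
                         length(atlas$structures), atlas$n_vertices))

    stage_name <- "simulate"
    cohort <- simulate_cohort(cfg$cohort$n_per_group,
                              cfg$cohort$n_cohorts %||% 5L,
                              seed = .child_seed(cfg$seed, "cohort"))
    spec <- .pipeline_effect_spec(cfg)
    thickness <- withCallingHandlers(
      simulate_thickness(atlas, cohort, spec,
                         seed = .child_seed(cfg$seed, "thickness")),
      warning = function(w) {
        log("simulate", conditionMessage(w)); invokeRestart("muffleWarning")
      })
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    log("simulate", sprintf("%d subjects x %d vertices",
                            nrow(thickness), ncol(thickness)))

    stage_name <- "validate"
    issues <- validate_inputs(thickness, cohort, atlas)
    utils::write.table(issues, file.path(out_dir, "validation.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (nrow(issues) > 0L)
      log("validate", paste(nrow(issues), "issue(s); see validation.tsv"))

    controls <- cohort[cohort$group == "control", ]
    pd <- cohort[cohort$group == "PD", ]
    pd$stage45 <- group_stages(pd$hy_stage, "HY45")
    maps <- list()

    if (isTRUE(cfg$analyses$case_control)) {
      stage_name <- "massuni_case_control"
      maps[["PD"]] <- .run_contrast("pd_vs_control", pd, controls,
                                    thickness, atlas, cfg, out_dir, log)
    }
    if (isTRUE(cfg$analyses$stage_contrasts)) {
      for (stg in intersect(c("HY1", "HY2", "HY3", "HY45"),
                            unique(pd$stage45))) {
        stage_name <- paste0("massuni_", stg)
        maps[[stg]] <- .run_contrast(
          tolower(stg), pd[pd$stage45 == stg, ], controls,
          thickness, atlas, cfg, out_dir, log)
      }
    }
    for (cl in cfg$analyses$clinical %||% character()) {
      stage_name <- paste0("massuni_", cl)
      ok <- !is.na(pd[[cl]])
      th <- thickness[match(pd$subject_id[ok], rownames(thickness)), ,
                      drop = FALSE]
      map <- map_effects(th, design_spec(cl), pd[ok, ])
      map <- threshold_map(map, atlas, cfg$radius_hops, cfg$q)
      write_effect_map(map, file.path(out_dir, paste0("map_", cl, ".tsv")))
      utils::write.table(
        cbind(contrast = cl, summarize_map(map, atlas)),
        file.path(out_dir, paste0("summary_", cl, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
      log("massuni", sprintf("%s: n=%d, %d sig vertices", cl, sum(ok),
                             sum(map$sig)))
    }

    if (identical(cfg$analyses$spin_pairs, "consecutive")) {
      stage_name <- "spin"
      pairs <- list(c("HY1", "HY2"), c("HY2", "HY3"), c("HY3", "HY45"))
      spin_out <- list()
      for (pr in pairs) {
        if (!all(pr %in% names(maps))) next
        for (i in seq_along(atlas$structures)) {
          key <- names(atlas$structures)[i]
          idx <- seq.int(atlas$offsets$start[i], atlas$offsets$end[i])
          res <- spin_test(maps[[pr[1L]]]$beta[idx], maps[[pr[2L]]]$beta[idx],
                           atlas$structures[[i]]$sphere,
                           n_rotations = cfg$n_rotations,
                           seed = .child_seed(cfg$seed,
                                              paste("spin", pr[1L], pr[2L], key)))
          spin_out[[paste(pr[1L], pr[2L], key, sep = "_")]] <-
            list(pair = paste(pr, collapse = "-"), structure = key,
                 r_obs = res$r_obs, p = res$p,
                 n_rotations = res$n_rotations, seed = res$seed)
        }
        log("spin", sprintf("%s vs %s: %d structures tested",
                            pr[1L], pr[2L], length(atlas$structures)))
      }
      jsonlite::write_json(spin_out,
                           file.path(out_dir, "spin_results.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }

    cls <- cfg$analyses$classification %||% character()
    cv_opts <- solver_options(max_iter = cfg$cv$max_iter %||% 150L,
                              tol = 1e-7, prox_tol = 1e-3, prox_iter = 50L)
    run_cls <- function(name, keep, y, task) {
      stage_name <<- paste0("classify_", name)
      X <- thickness[match(cohort$subject_id[keep], rownames(thickness)), ,
                     drop = FALSE]
      cvrep <- nested_cv(X, y, atlas$edges, task = task,
                         grid = cfg$cv$grid %||% default_lambda_grid(),
                         outer_k = cfg$cv$outer_k %||% 4L,
                         inner_k = cfg$cv$inner_k %||% 4L,
                         seed = .child_seed(cfg$seed, paste0("cv_", name)),
                         opts = cv_opts)
      jsonlite::write_json(
        list(task = cvrep$task, metric = cvrep$metric,
             folds = cvrep$folds, mean_metric = cvrep$mean_metric,
             seed = cvrep$seed),
        file.path(out_dir, paste0("cv_", name, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      wm <- weight_map(cvrep$model, atlas)
      wm$weight_sd <- signif(wm$weight_sd, 10)
      utils::write.table(wm, file.path(out_dir, paste0("weights_", name, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      log("classify", sprintf("%s: mean %s = %.3f", name, cvrep$metric,
                              cvrep$mean_metric))
    }
    stage345 <- group_stages(cohort$hy_stage, "HY345")
    if ("pd_vs_control" %in% cls)
      run_cls("pd_vs_control", rep(TRUE, nrow(cohort)),
              factor(cohort$group, levels = c("control", "PD")), "binary")
    if ("hy1_vs_hy2" %in% cls) {
      keep <- !is.na(stage345) & stage345 %in% c("HY1", "HY2")
      run_cls("hy1_vs_hy2", keep,
              factor(stage345[keep], levels = c("HY1", "HY2")), "binary")
    }
    if ("hy2_vs_hy345" %in% cls) {
      keep <- !is.na(stage345) & stage345 %in% c("HY2", "HY345")
      run_cls("hy2_vs_hy345", keep,
              factor(stage345[keep], levels = c("HY2", "HY345")), "binary")
    }
    if ("ordinal" %in% cls) {
      keep <- !is.na(stage345)
      run_cls("ordinal", keep,
              factor(stage345[keep], levels = c("HY1", "HY2", "HY345")),
              "ordinal")
    }

    stage_name <- "manifest"
    manifest <- list(
      package = "shapestage",
      package_version = as.character(utils::packageVersion("shapestage")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      master_seed = cfg$seed,
      child_seeds = list(
        atlas = .child_seed(cfg$seed, "atlas"),
        cohort = .child_seed(cfg$seed, "cohort"),
        thickness = .child_seed(cfg$seed, "thickness")),
      n_subjects = nrow(cohort), n_vertices = atlas$n_vertices,
      q = cfg$q, radius_hops = cfg$radius_hops,
      n_rotations = cfg$n_rotations)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log("done", "pipeline complete")
    out_dir
  }, error = function(e) {
    writeLines(paste("stage:", stage_name, "-", conditionMessage(e)),
               failed_marker)
    close(logcon)
    stop("pipeline failed at stage '", stage_name, "': ",
         conditionMessage(e), call. = FALSE)
  })
  close(logcon)
  invisible(result)
}

#' Read a pipeline YAML configuration
#'
#' @param path YAML file; keys mirror [demo_pipeline_config()]. A `grid`
#'   entry under `cv` with `n_l1`, `n_tv`, `lo`, `hi` is expanded via
#'   [default_lambda_grid()]; an `atlas: demo` / `atlas: default` shorthand
#'   selects the corresponding atlas config.
#' @return Configuration list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(demo_pipeline_config(), raw)
  if (identical(raw$atlas, "demo"))
    cfg$atlas <- list(config = demo_atlas_config())
  if (identical(raw$atlas, "default"))
    cfg$atlas <- list(config = default_atlas_config())
  if (!is.null(raw$cohort$n_per_group))
    cfg$cohort$n_per_group <- unlist(raw$cohort$n_per_group)
  if (!is.null(raw$cv$grid) && is.list(raw$cv$grid))
    cfg$cv$grid <- do.call(default_lambda_grid, raw$cv$grid)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
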