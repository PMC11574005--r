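#' Default atlas configuration: 14 subcortical structures, 27,120 vertices
#'
#' Seven bilateral structures (thalamus, caudate nucleus, putamen, globus
#' pallidus, hippocampus, amygdala, nucleus accumbens) as uv-spheres whose
#' per-structure vertex counts sum to 13,560 per hemisphere (27,120 total).
#' The true template's per-structure counts are not public; these counts and
#' the ellipsoid/bend shape parameters (mm, loosely anatomical) are the
#' package's own synthetic choices and are fully configurable.
#'
#' @return A data frame with one row per (structure, hemisphere) and columns
#'   `structure`, `hemisphere`, `rings`, `cols`, `axes1..3`, `taper`,
#'   `bend`, `jitter`.
#' @export
default_atlas_config <- function() {
  base <- data.frame(
    structure = c("thalamus", "putamen", "caudate", "hippocampus",
                  "pallidum", "amygdala", "accumbens"),
    rings = c(54L, 48L, 48L, 48L, 30L, 24L, 22L),
    cols  = c(50L, 50L, 50L, 50L, 50L, 50L, 43L),
    axes1 = c(15, 17, 20, 20, 10, 9, 6),
    axes2 = c(10,  7,  6,  8,  6, 7, 5),
    axes3 = c( 9,  6,  5,  6,  5, 6, 4),
    taper = c(0.1, 0.2, 0.4, 0.25, 0.1, 0.05, 0),
    bend  = c(0.3, 0.8, 1.5, 1.2, 0.2, 0.1, 0),
    jitter = c(0.4, 0.4, 0.3, 0.4, 0.3, 0.3, 0.2))
  cfg <- rbind(transform(base, hemisphere = "left"),
               transform(base, hemisphere = "right"))
  cfg[, c("structure", "hemisphere", "rings", "cols",
          paste0("axes", 1:3), "taper", "bend", "jitter")]
}

#' Small atlas configuration for demonstrations and tests
#'
#' Same schema as [default_atlas_config()] but with few structures and
#' small vertex counts, so end-to-end analyses run in seconds.
#'
#' @param structures character vector of structure names to include
#'   (bilateral).
#' @param rings,cols uv-sphere resolution shared by all structures.
#' @return Configuration data frame (see [default_atlas_config()]).
#' @export
demo_atlas_config <- function(structures = c("putamen", "pallidum"),
                              rings = 10L, cols = 16L) {
  full <- default_atlas_config()
  cfg <- full[full$structure %in% structures, ]
  cfg$rings <- as.integer(rings)
  cfg$cols <- as.integer(cols)
  rownames(cfg) <- NULL
  cfg
}

#' Build a registered mesh atlas
#'
#' Constructs one deformed uv-sphere mesh per (structure, hemisphere) row of
#' the configuration, keeps each vertex's pre-deformation unit-sphere
#' position as its spherical registration, assigns structure-blocked global
#' vertex indices, and assembles the within-structure vertex adjacency from
#' shared face edges. Right-hemisphere meshes are mirrored across x with
#' face winding flipped to preserve orientation.
#'
#' @param config a configuration data frame (see [default_atlas_config()]).
#' @param seed integer seed for the per-structure jitter fields.
#' @return An object of class `mesh_atlas` with elements `structures` (named
#'   list of `list(mesh, sphere)` where `sphere` is the n x 3 unit-coordinate
#'   matrix), `offsets` (data frame with global `start`/`end` index per
#'   structure), `edges` (global undirected edge matrix, no cross-structure
#'   edges), and `n_vertices`.
#' @examples
#' atlas <- build_atlas(demo_atlas_config())
#' atlas$n_vertices
#' @export
build_atlas <- function(config = default_atlas_config(), seed = 2026L) {
  key <- paste(config$structure, config$hemisphere)
  if (anyDuplicated(key))
    stop("duplicate (structure, hemisphere) pair in atlas config: ",
         key[duplicated(key)][1L])
  structures <- vector("list", nrow(config))
  names(structures) <- key
  offsets <- data.frame(structure = config$structure,
                        hemisphere = config$hemisphere,
                        start = NA_integer_, end = NA_integer_)
  edge_list <- vector("list", nrow(config))
  off <- 0L
  for (i in seq_len(nrow(config))) {
    row <- config[i, ]
    sph <- build_sphere_mesh("uv", rings = row$rings, cols = row$cols,
                             structure_name = row$structure,
                             hemisphere = row$hemisphere)
    mesh <- deform_to_structure(
      sph, axes = c(row$axes1, row$axes2, row$axes3),
      taper = row$taper, bend = row$bend, jitter = row$jitter,
      seed = .child_seed(seed, key[i]))
    if (row$hemisphere == "right") {
      mesh$vertices[, 1L] <- -mesh$vertices[, 1L]
      mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]  # restore outward winding
    }
    nv <- nrow(mesh$vertices)
    structures[[i]] <- list(mesh = mesh, sphere = sph$vertices)
    offsets$start[i] <- off + 1L
    offsets$end[i] <- off + nv
    edge_list[[i]] <- mesh_edges(mesh) + off
    off <- off + nv
  }
  structure(
    list(structures = structures, offsets = offsets,
         edges = do.call(rbind, edge_list), n_vertices = off,
         config = config, seed = seed),
    class = "mesh_atlas")
}

#' @export
print.mesh_atlas <- function(x, ...) {
  cat(sprintf("<mesh_atlas> %d structures, %d vertices, %d edges\n",
              length(x$structures), x$n_vertices, nrow(x$edges)))
  invisible(x)
}

#' Global vertex indices of one structure
#'
#' @param atlas a `mesh_atlas`.
#' @param structure structure name.
#' @param hemisphere `"left"` or `"right"`.
#' @return Integer vector of global (1-based) vertex indices.
#' @export
atlas_vertex_range <- function(atlas, structure, hemisphere) {
  i <- which(atlas$offsets$structure == structure &
               atlas$offsets$hemisphere == hemisphere)
  if (length(i) != 1L)
    stop("structure '", structure, "' (", hemisphere, ") not in atlas")
  seq.int(atlas$offsets$start[i], atlas$offsets$end[i])
}

# adjacency list over global vertex indices (cached on first use)
.atlas_adjacency <- function(atlas) {
  .adjacency_list(atlas$edges, atlas$n_vertices)
}

#' Write an atlas to a directory
#'
#' One PLY mesh and one CSV of spherical coordinates
#' (`vertex`, `x`, `y`, `z`; `vertex` is the global 1-based index) per
#' structure, plus `offsets.csv` and `edges.csv`.
#'
#' @param atlas a `mesh_atlas`.
#' @param dir output directory (created if needed).
#' @param format PLY dialect passed to [write_ply()].
#' @return `dir` invisibly.
#' @export
write_atlas <- function(atlas, dir, format = "ascii") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(atlas$structures)) {
    s <- atlas$structures[[i]]
    stem <- gsub(" ", "_", names(atlas$structures)[i])
    write_ply(s$mesh, file.path(dir, paste0(stem, ".ply")), format = format)
    idx <- seq.int(atlas$offsets$start[i], atlas$offsets$end[i])
    utils::write.csv(
      data.frame(vertex = idx, x = s$sphere[, 1L], y = s$sphere[, 2L],
                 z = s$sphere[, 3L]),
      file.path(dir, paste0(stem, "_sphere.csv")), row.names = FALSE)
  }
  utils::write.csv(atlas$offsets, file.path(dir, "offsets.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(atlas$edges) |>
                     stats::setNames(c("i", "j")),
                   file.path(dir, "edges.csv"), row.names = FALSE)
  invisible(dir)
}
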