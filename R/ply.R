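#' Read a triangulated mesh from a PLY file
#'
#' Supports ascii and binary (little/big endian) PLY with a vertex element
#' carrying `x`, `y`, `z` properties and a face element with a
#' `vertex_indices`/`vertex_index` list property. Faces must be triangles.
#' Vertex indices are 0-based on disk (the PLY convention) and converted to
#' 1-based in the returned mesh.
#'
#' @param path path to a `.ply` file.
#' @param structure_name,hemisphere labels for the returned mesh; defaults
#'   are read from a `comment structure <name> <hemisphere>` header line
#'   when present.
#' @return A `surface_mesh`.
#' @export
read_ply <- function(path, structure_name = NULL, hemisphere = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  # ---- header (always ascii lines) ----
  read_hline <- function() {
    chars <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0L) stop("unexpected end of file in PLY header")
      if (b == as.raw(10L)) break
      chars <- c(chars, b)
    }
    sub("\r$", "", rawToChar(chars))
  }
  lineno <- 1L
  if (read_hline() != "ply") stop("malformed PLY header at line 1: missing 'ply' magic")
  fmt <- NULL; elements <- list(); cur <- NULL
  repeat {
    lineno <- lineno + 1L
    ln <- read_hline()
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0L) next
    if (tok[1] == "comment") {
      if (length(tok) >= 4L && tok[2] == "structure") {
        if (is.null(structure_name)) structure_name <- tok[3]
        if (is.null(hemisphere)) hemisphere <- tok[4]
      }
      next
    }
    if (tok[1] == "format") {
      if (!tok[2] %in% c("ascii", "binary_little_endian", "binary_big_endian"))
        stop("malformed PLY header at line ", lineno, ": unknown format '", tok[2], "'")
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(n = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("malformed PLY header at line ", lineno,
                             ": property before any element")
      if (tok[2] == "list") {
        elements[[cur]]$props[[tok[5]]] <-
          list(list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        elements[[cur]]$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") break
    else stop("malformed PLY header at line ", lineno, ": '", ln, "'")
  }
  if (is.null(fmt)) stop("malformed PLY header: no format line")
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY file must contain vertex and face elements")

  type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                 short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                 int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                 float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  read_scalar <- function(type, n, endian) {
    sz <- type_size[[type]]
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "double", n, size = sz, endian = endian)
    else
      readBin(con, "integer", n, size = sz, endian = endian,
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  }

  if (fmt == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    nv <- elements$vertex$n; nf <- elements$face$n
    if (length(txt) < nv + nf) stop("truncated PLY body")
    vprops <- names(elements$vertex$props)
    vmat <- do.call(rbind, lapply(txt[seq_len(nv)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    colnames(vmat) <- vprops[seq_len(ncol(vmat))]
    verts <- vmat[, c("x", "y", "z"), drop = FALSE]
    dimnames(verts) <- NULL
    faces <- t(vapply(txt[nv + seq_len(nf)], function(l) {
      a <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
      if (a[1L] != 3L) stop("non-triangle face (", a[1L], " vertices) in PLY body")
      a[2:4]
    }, integer(3L), USE.NAMES = FALSE))
  } else {
    endian <- if (fmt == "binary_little_endian") "little" else "big"
    vp <- elements$vertex$props
    nv <- elements$vertex$n
    pnames <- names(vp)
    types <- vapply(vp, function(p) p$type, character(1L))
    if (identical(pnames, c("x", "y", "z")) && length(unique(types)) == 1L) {
      flat <- read_scalar(types[[1L]], nv * 3L, endian)
      verts <- matrix(flat, nv, 3L, byrow = TRUE)
    } else {
      verts <- matrix(NA_real_, nv, 3L)
      for (i in seq_len(nv)) {
        for (p in pnames) {
          val <- read_scalar(vp[[p]]$type, 1L, endian)
          if (p == "x") verts[i, 1L] <- val
          else if (p == "y") verts[i, 2L] <- val
          else if (p == "z") verts[i, 3L] <- val
        }
      }
    }
    fp <- elements$face$props[["vertex_indices"]]
    if (is.null(fp)) fp <- elements$face$props[["vertex_index"]]
    if (is.null(fp)) stop("PLY face element lacks a vertex index list property")
    nf <- elements$face$n
    faces <- matrix(NA_integer_, nf, 3L)
    for (i in seq_len(nf)) {
      k <- read_scalar(fp$count_type, 1L, endian)
      if (k != 3L) stop("non-triangle face (", k, " vertices) in PLY body")
      faces[i, ] <- read_scalar(fp$type, 3L, endian)
    }
  }
  surface_mesh(verts, faces + 1L,
               structure_name %||% "mesh", hemisphere %||% "left")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a triangulated mesh to a PLY file
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param format `"ascii"` (default) or `"binary_little_endian"`.
#' @return `path` invisibly.
#' @export
write_ply <- function(mesh, path, format = c("ascii", "binary_little_endian")) {
  format <- match.arg(format)
  v <- mesh$vertices; f <- mesh$faces - 1L  # PLY is 0-based
  header <- c(
    "ply",
    paste("format", format, "1.0"),
    paste("comment structure", mesh$structure_name, mesh$hemisphere),
    paste("element vertex", nrow(v)),
    "property double x", "property double y", "property double z",
    paste("element face", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (format == "ascii") {
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  } else {
    writeBin(as.numeric(t(v)), con, size = 8L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ]), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}
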