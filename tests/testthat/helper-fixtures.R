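# shared fixtures, built in code at test time

# capped-cylinder phantom with uv-sphere topology: lateral wall of constant
# radius plus spherical-ish caps; the analytic centerline is the z axis
cylinder_phantom <- function(rings = 40L, cols = 24L, radius = 1,
                             height = 6) {
  m <- build_sphere_mesh("uv", rings = rings, cols = cols)
  v <- m$vertices
  theta <- acos(pmin(pmax(v[, 3L], -1), 1))     # polar angle
  phi <- atan2(v[, 2L], v[, 1L])
  cap <- pi / 6                                  # polar extent of each cap
  z <- numeric(nrow(v)); r <- numeric(nrow(v))
  lat <- theta >= cap & theta <= pi - cap        # lateral wall
  z[lat] <- height / 2 * (1 - 2 * (theta[lat] - cap) / (pi - 2 * cap))
  r[lat] <- radius
  top <- theta < cap
  r[top] <- radius * sin(theta[top]) / sin(cap)
  z[top] <- height / 2 + radius * (cos(theta[top]) - cos(cap)) / (1 - cos(cap)) * 0.3
  bot <- theta > pi - cap
  r[bot] <- radius * sin(theta[bot]) / sin(cap)
  z[bot] <- -height / 2 - radius * (cos(pi - theta[bot]) - cos(cap)) /
    (1 - cos(cap)) * 0.3
  surface_mesh(cbind(r * cos(phi), r * sin(phi), z), m$faces,
               "cylinder", "left")
}

# random connected graph on n nodes: a random spanning tree plus extra edges
random_connected_graph <- function(n, extra = n) {
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L),
                             integer(1L)))
  if (extra > 0L) {
    more <- cbind(sample.int(n, extra, TRUE), sample.int(n, extra, TRUE))
    more <- more[more[, 1L] != more[, 2L], , drop = FALSE]
    edges <- rbind(edges, more)
  }
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
  unique(edges)
}

# independent QP oracle for the TV prox: box-constrained dual solved by
# L-BFGS-B on the smooth quadratic
tv_prox_qp_oracle <- function(w, lambda, edges) {
  n <- length(w); E <- nrow(edges)
  ei <- edges[, 1L]; ej <- edges[, 2L]
  Dt <- function(z) {
    out <- numeric(n)
    for (e in seq_len(E)) {
      out[ei[e]] <- out[ei[e]] + z[e]
      out[ej[e]] <- out[ej[e]] - z[e]
    }
    out
  }
  obj <- function(z) 0.5 * sum((w - Dt(z))^2)
  grad <- function(z) { x <- w - Dt(z); -(x[ei] - x[ej]) }
  o <- stats::optim(numeric(E), obj, grad, method = "L-BFGS-B",
                    lower = -lambda, upper = lambda,
                    control = list(factr = 1, maxit = 10000L))
  w - Dt(o$par)
}

# smoothed Gaussian noise map on a mesh: k rounds of neighbour averaging
smoothed_noise_map <- function(n_vertices, adj, k = 4L) {
  x <- stats::rnorm(n_vertices)
  for (i in seq_len(k))
    x <- vapply(seq_len(n_vertices),
                function(v) mean(x[c(v, adj[[v]])]), numeric(1L))
  x
}

# textbook Benjamini-Hochberg rejection set at level q
bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) / m * q)
  rej <- logical(m)
  if (length(ok)) rej[ord[seq_len(max(ok))]] <- TRUE
  rej
}

adjacency_list_of <- function(edges, n) shapestage:::.adjacency_list(edges, n)

local_quiet_fit <- function(expr) suppressWarnings(suppressMessages(expr))
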