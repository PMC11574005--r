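# internal helpers shared across modules

# evaluate expr under a local RNG state; the caller's .Random.seed is
# restored afterwards, so package randomness never perturbs user code
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a child seed from a master seed and a label; stays below 2^31
.child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

# adjacency list (list of integer neighbour vectors) from an edge matrix
.adjacency_list <- function(edges, n_vertices) {
  adj <- vector("list", n_vertices)
  if (nrow(edges) == 0L) return(lapply(adj, function(x) integer(0)))
  both <- rbind(edges, edges[, 2:1, drop = FALSE])
  split(both[, 2L], factor(both[, 1L], levels = seq_len(n_vertices)))
}

# breadth-first hop distances from a source vertex; Inf if unreachable
.bfs_hops <- function(adj, from, max_hops = Inf) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[from] <- 0
  frontier <- from
  h <- 0
  while (length(frontier) > 0L && h < max_hops) {
    h <- h + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(d[nxt])]
    d[nxt] <- h
    frontier <- nxt
  }
  d
}

# all vertices within `hops` edge hops of `from` (including itself)
.bfs_ball <- function(adj, from, hops) {
  if (is.infinite(hops)) return(seq_along(adj))
  which(is.finite(.bfs_hops(adj, from, max_hops = hops)))
}
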