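# Independent oracles used to cross-check the package implementation.
# Everything here works from node coordinates alone and deliberately
# avoids the package's adjacency, walk and distance code paths.

# Brute-force face adjacency: O(n^2) pairwise comparison of coordinates.
brute_adjacency <- function(coords) {
  n <- nrow(coords)
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- abs(sweep(coords, 2L, coords[i, ]))
    A[i, ] <- rowSums(d) == 1L & apply(d, 1L, max) == 1L
  }
  diag(A) <- FALSE
  A
}

# Dense lazy-walk operator built directly from the brute-force
# adjacency (column-stochastic; isolated nodes keep their mass).
brute_operator <- function(coords) {
  A <- brute_adjacency(coords)
  deg <- colSums(A)
  n <- nrow(A)
  D <- matrix(0, n, n)
  for (j in seq_len(n)) {
    if (deg[j] == 0L) {
      D[j, j] <- 1
    } else {
      D[j, j] <- 0.5
      D[A[, j], j] <- 0.5 / deg[j]
    }
  }
  D
}

# All-pairs shortest hop counts through igraph (textbook BFS oracle).
igraph_distances <- function(surface, from = NULL) {
  A <- brute_adjacency(surface$coords)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  d <- igraph::distances(g, algorithm = "unweighted")
  if (is.null(from)) d else d[from, ]
}

# Unrolled 1D coordinate of every node of a phase-0 build_ridges()
# surface: walk the cross-section profile in order (gap floor, left
# wall up, top, right wall down) and number the nodes consecutively.
# On a folded surface the SWSD must equal |du| + |dy|.
unroll_ridges <- function(surface) {
  p <- surface$params
  period <- p$ridge_width + p$spacing
  h <- p$ridge_height
  w <- p$ridge_width
  nx <- surface$volume_shape[1L]
  key <- function(x, z) paste(x, z)
  u_of <- new.env()
  u <- 0L
  for (x in 0:(nx - 1L)) {
    r <- x %% period
    zs <- if (r >= w) 0L                       # gap floor
          else if (r == 0L) 0:h                # left wall, ascending
          else if (r == w - 1L) h:0            # right wall, descending
          else h                               # top interior
    for (z in zs) {
      assign(key(x, z), u, envir = u_of)
      u <- u + 1L
    }
  }
  cc <- surface$coords
  vapply(seq_len(nrow(cc)),
         function(i) get(key(cc[i, 1L], cc[i, 3L]), envir = u_of),
         integer(1))
}

# Small deformed surface (a 2-high block on a plate): contains 3-, 4-
# and 5-neighbour nodes but stays tiny.
small_deformed <- function() {
  H <- matrix(0L, 5, 5)
  H[2:3, 2:3] <- 2L
  build_from_height_map(H)
}

# Plus-shaped 5-node star: hub with 4 degree-1 leaves.
star5 <- function() {
  build_from_nodes(rbind(c(1, 1, 0), c(0, 1, 0), c(2, 1, 0),
                         c(1, 0, 0), c(1, 2, 0)))
}
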