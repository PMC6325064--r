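# Diffusion as a lazy random walk on the surface graph.
#
# Per iteration, half of the probability mass at each node stays put
# and the other half is redistributed equally among the node's surface
# neighbours: u[t+1] = D u[t] with D(j,j) = 0.5 and
# D(i,j) = 0.5/deg(j) for face-adjacent i, j.  The divisor is the
# degree of the *source* node, which is what conserves mass on graphs
# of irregular degree; isolated nodes keep all their mass so that D
# stays column-stochastic.

#' The lazy-walk transition operator of a surface
#'
#' @param surface a `surface_graph`.
#' @return A `walk_operator` object; use [operator_matrix()] to
#'   materialize it as a dense matrix on small graphs.
#' @export
walk_operator <- function(surface) {
  stopifnot(inherits(surface, "surface_graph"))
  structure(list(surface = surface, p_move = 0.5,
                 signature = surface_signature(surface)),
            class = "walk_operator")
}

#' @export
print.walk_operator <- function(x, ...) {
  cat("<walk_operator> lazy random walk on", n_nodes(x$surface),
      "nodes (p_move = 0.5, source-degree splitting)\n")
  invisible(x)
}

#' Dense transition matrix of a walk operator
#'
#' Materializes D as an n x n matrix (column j holds the distribution
#' of mass leaving node j).  Intended for small graphs and cross-checks;
#' refuses n > 4000.
#'
#' @param op a `walk_operator`.
#' @return A dense column-stochastic matrix.
#' @export
operator_matrix <- function(op) {
  stopifnot(inherits(op, "walk_operator"))
  s <- op$surface
  n <- n_nodes(s)
  if (n > 4000L) stop_contract("operator_matrix is meant for small graphs")
  D <- diag(ifelse(s$degree > 0L, 0.5, 1), n)
  for (j in seq_len(n)) {
    nb <- node_neighbors(s, j)
    D[nb, j] <- 0.5 / s$degree[j]
  }
  D
}

#' Initial probability field
#'
#' Places unit mass on the start node at iteration 0.
#'
#' @param surface a `surface_graph`.
#' @param start node index or coordinate triple.
#' @return A `prob_field`: per-node mass, iteration counter and origin.
#' @export
init_field <- function(surface, start) {
  i0 <- resolve_start(surface, start)
  mass <- numeric(n_nodes(surface))
  mass[i0] <- 1
  new_prob_field(mass, 0L, surface$coords[i0, ], i0,
                 surface_signature(surface))
}

new_prob_field <- function(mass, iteration, origin, start_index, signature) {
  structure(list(mass = mass, iteration = as.integer(iteration),
                 origin = origin, start_index = start_index,
                 surface_signature = signature),
            class = "prob_field")
}

#' @export
print.prob_field <- function(x, ...) {
  cat(sprintf("<prob_field> iteration %d | %d nodes | mass %.12f | support %d\n",
              x$iteration, length(x$mass), sum(x$mass), sum(x$mass > 0)))
  invisible(x)
}

#' Advance a probability field by one lazy-walk iteration
#'
#' On a flat interior node this sends 0.5 of the node's mass to itself
#' and 0.125 to each of its four neighbours.
#'
#' @param field a `prob_field`.
#' @param op the matching `walk_operator`.
#' @return The field after one iteration; total mass is conserved.
#' @export
walk_step <- function(field, op) {
  stopifnot(inherits(field, "prob_field"), inherits(op, "walk_operator"))
  s <- op$surface
  if (!same_surface(field$surface_signature, op$signature)) {
    stop_contract("field and operator belong to different surfaces")
  }
  deg <- s$degree
  w <- ifelse(deg > 0L, 0.5 * field$mass / deg, 0)
  contrib <- w[s$adj_idx]
  grp <- rep.int(seq_along(deg), deg)
  inflow <- numeric(length(deg))
  if (length(contrib)) {
    agg <- rowsum(contrib, grp)
    inflow[as.integer(rownames(agg))] <- agg[, 1L]
  }
  mass <- ifelse(deg > 0L, 0.5, 1) * field$mass + inflow
  new_prob_field(mass, field$iteration + 1L, field$origin, field$start_index,
                 field$surface_signature)
}

# ---------------------------------------------------------------------------
# Shared engine driver.

# Runs the compiled propagation kernel with nodes re-ordered by
# geodesic distance from the start.  With restrict = TRUE the update at
# iteration t only touches nodes within the graph ball of radius t
# (grown one shell per iteration) -- the expanding-region optimization.
# Results are bitwise independent of the flag because mass travels at
# most one hop per iteration.
run_engine <- function(surface, start, n_iterations, maps = NULL,
                       record = integer(0), restrict = TRUE,
                       occ_threshold = 0) {
  n_iterations <- check_count(n_iterations, "n_iterations")
  i0 <- resolve_start(surface, start)
  if (is.null(maps)) {
    maps <- distance_maps(surface, i0)
  } else {
    stopifnot(inherits(maps, "distance_maps"))
    if (!same_surface(maps$surface_signature, surface_signature(surface)) ||
        maps$start_index != i0) {
      stop_contract("distance maps were computed for a different surface ",
                    "or start node")
    }
  }
  n <- n_nodes(surface)
  gd <- maps$dswsd
  o <- order(gd, method = "radix", na.last = TRUE)   # Inf sorts last
  rank <- integer(n); rank[o] <- seq_len(n)

  # CSR restricted to the permuted order
  deg_p <- surface$degree[o]
  ptr_p <- c(0, cumsum(deg_p)); storage.mode(ptr_p) <- "integer"
  pos <- sequence(deg_p, from = surface$adj_ptr[o] + 1L)
  idx_p0 <- rank[surface$adj_idx[pos]] - 1L

  W <- cbind(maps$d2[o]^2, maps$d3[o]^2,
             ifelse(is.finite(gd[o]), gd[o], 0)^2)
  wcol <- ifelse(deg_p > 0L, 0.5 / deg_p, 0)
  selfw <- ifelse(deg_p > 0L, 0.5, 1)
  ball <- if (restrict) {
    fin <- gd[is.finite(gd)]
    cumsum(tabulate(pmin(fin, n_iterations + 1) + 1L,
                    nbins = n_iterations + 2L))
  } else numeric(0)

  res <- .propagate_csr(ptr_p, idx_p0, wcol, selfw, rank[i0] - 1L,
                        n_iterations, W, ball, as.integer(record),
                        occ_threshold)
  # snapshots back in canonical node order
  snaps <- lapply(seq_along(res$snapshots), function(k) {
    m <- numeric(n)
    m[o] <- res$snapshots[[k]]
    new_prob_field(m, res$snapshot_iterations[k], maps$start, i0,
                   surface_signature(surface))
  })
  colnames(res$msd) <- c("msd_2d", "msd_3d", "msd_swsd")
  list(msd = res$msd, mass = res$mass, occupied = res$occupied,
       snapshots = snaps, maps = maps, start_index = i0)
}

#' Propagate a probability field and record snapshots
#'
#' Deterministic time course of the lazy walk from a single start node.
#' The support of the field at iteration t is contained in the graph
#' ball of radius t around the start, which the engine exploits by only
#' updating an expanding region around the occupied support; switch
#' `restrict` off to force full-graph updates (the results are
#' identical to within floating-point reproducibility, and are compared
#' in the package tests).
#'
#' @param surface a `surface_graph`.
#' @param start node index or coordinate triple.
#' @param n_iterations number of iterations to run.
#' @param record_every snapshot cadence; the final iteration is always
#'   recorded.  Alternatively give explicit `record` iterations.
#' @param record integer vector of iterations to snapshot.
#' @param restrict use the expanding-region optimization (default TRUE).
#' @return A list of `prob_field` snapshots (iteration 0 included).
#' @export
propagate <- function(surface, start, n_iterations, record_every = NULL,
                      record = NULL, restrict = TRUE) {
  if (is.null(record)) {
    record <- if (is.null(record_every)) n_iterations
              else unique(c(seq.int(record_every, n_iterations,
                                    by = record_every), n_iterations))
  }
  res <- run_engine(surface, start, n_iterations, record = record,
                    restrict = restrict)
  c(list(init_field(surface, res$start_index)), res$snapshots)
}

#' Simulate diffusion and measure spread with all three metrics
#'
#' The package workhorse: builds the distance maps from the start node
#' (2D, 3D, SWSD), propagates the lazy walk for `n_iterations`, and
#' accumulates at every iteration the population mean squared
#' displacement for each metric (the summed probability times the
#' squared distance), the total mass and the number of occupied nodes.
#'
#' @inheritParams propagate
#' @param maps optional precomputed [distance_maps()] for this surface
#'   and start.
#' @param record iterations at which to keep full field snapshots.
#' @param occ_threshold mass threshold for the occupied-node count.
#' @return A `diffusion_course` object with elements `msd` (an
#'   [msd_series] data frame), `mass`, `occupied`, `snapshots`, `maps`
#'   and provenance fields.
#' @examples
#' flat <- build_flat(41, 41)
#' dc <- simulate_diffusion(flat, c(20, 20, 0), 50)
#' head(dc$msd)
#' @export
simulate_diffusion <- function(surface, start, n_iterations, maps = NULL,
                               record = integer(0), restrict = TRUE,
                               occ_threshold = 0) {
  res <- run_engine(surface, start, n_iterations, maps = maps,
                    record = record, restrict = restrict,
                    occ_threshold = occ_threshold)
  msd <- msd_series(iterations = 0:n_iterations,
                    msd_2d = res$msd[, 1L], msd_3d = res$msd[, 2L],
                    msd_swsd = res$msd[, 3L],
                    provenance = list(
                      surface = surface_signature(surface),
                      builder = surface$builder,
                      start = res$maps$start))
  structure(list(msd = msd, mass = res$mass, occupied = res$occupied,
                 snapshots = res$snapshots, maps = res$maps,
                 start = res$maps$start, start_index = res$start_index,
                 n_iterations = as.integer(n_iterations),
                 surface_signature = surface_signature(surface)),
            class = "diffusion_course")
}

#' @export
print.diffusion_course <- function(x, ...) {
  cat(sprintf("<diffusion_course> %d iterations from (%s) | mass drift %.2e\n",
              x$n_iterations, paste(x$start, collapse = ","),
              max(abs(x$mass - 1))))
  print(tail(x$msd, 3L))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Stochastic single-particle tracks.

#' Sample single-particle tracks of the lazy walk
#'
#' Generates stochastic trajectories: per iteration a particle stays
#' put with probability 0.5 and otherwise hops to a uniformly chosen
#' surface neighbour.  The ensemble occupancy converges to the
#' deterministic propagation of [simulate_diffusion()]; individual
#' tracks are highly variable even on a flat surface.
#'
#' @inheritParams propagate
#' @param n_tracks number of independent tracks.
#' @param seed RNG seed; a `track_set` is reproducible from
#'   (seed, n_tracks, n_iterations).
#' @param record_every record positions every this many iterations (the
#'   final iteration is always recorded).
#' @return A `track_set`: matrix of node indices (rows = recorded
#'   iterations, columns = tracks) plus metadata.
#' @export
sample_tracks <- function(surface, start, n_tracks, n_iterations, seed,
                          record_every = 1L) {
  stopifnot(inherits(surface, "surface_graph"))
  n_tracks <- check_count(n_tracks, "n_tracks")
  n_iterations <- check_count(n_iterations, "n_iterations")
  record_every <- check_count(record_every, "record_every")
  if (missing(seed) || is.null(seed)) {
    stop_invalid_spec("a seed is required for reproducible tracks")
  }
  i0 <- resolve_start(surface, start)
  set.seed(seed)
  nodes <- .sample_tracks_csr(surface$adj_ptr, surface$adj_idx - 1L,
                              i0 - 1L, n_tracks, n_iterations, record_every)
  structure(list(nodes = nodes,
                 iterations = attr(nodes, "iterations"),
                 seed = seed, start = surface$coords[i0, ], start_index = i0,
                 surface_signature = surface_signature(surface)),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks x %d iterations (seed %s)\n",
              ncol(x$nodes), max(x$iterations), format(x$seed)))
  invisible(x)
}

#' Coordinates of recorded track positions
#'
#' @param tracks a `track_set`.
#' @param surface the surface the tracks were sampled on.
#' @return A data frame with track, iteration, x, y, z.
#' @export
track_coords <- function(tracks, surface) {
  stopifnot(inherits(tracks, "track_set"))
  if (!same_surface(tracks$surface_signature, surface_signature(surface))) {
    stop_contract("tracks were sampled on a different surface")
  }
  idx <- as.vector(tracks$nodes)
  data.frame(track = rep(seq_len(ncol(tracks$nodes)),
                         each = nrow(tracks$nodes)),
             iteration = rep(tracks$iterations, ncol(tracks$nodes)),
             x = surface$coords[idx, 1L],
             y = surface$coords[idx, 2L],
             z = surface$coords[idx, 3L])
}

#' Empirical MSD of a track ensemble
#'
#' Mean squared distance from the start over tracks at every recorded
#' iteration, for the three metrics, using the same distance maps as
#' the deterministic analysis.
#'
#' @param tracks a `track_set`.
#' @param maps [distance_maps()] from the tracks' start node.
#' @return An [msd_series] with one row per recorded iteration, plus a
#'   `"se_2d"` attribute with the standard error of the 2D squared
#'   displacement at each recorded iteration.
#' @export
track_msd <- function(tracks, maps) {
  stopifnot(inherits(tracks, "track_set"), inherits(maps, "distance_maps"))
  if (!same_surface(tracks$surface_signature, maps$surface_signature) ||
      tracks$start_index != maps$start_index) {
    stop_contract("tracks and maps have different provenance")
  }
  nt <- ncol(tracks$nodes)
  sq_mean <- function(d) {
    m <- matrix(d[tracks$nodes]^2, nrow = nrow(tracks$nodes))
    list(mean = rowMeans(m),
         se = sqrt(pmax(0, rowMeans(m^2) - rowMeans(m)^2) / nt))
  }
  m2 <- sq_mean(maps$d2); m3 <- sq_mean(maps$d3); ms <- sq_mean(maps$dswsd)
  out <- msd_series(iterations = tracks$iterations, msd_2d = m2$mean,
                    msd_3d = m3$mean, msd_swsd = ms$mean,
                    provenance = list(kind = "track_ensemble",
                                      n_tracks = nt, seed = tracks$seed))
  attr(out, "se_2d") <- m2$se
  attr(out, "se_swsd") <- ms$se
  out
}
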