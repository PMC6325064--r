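# The three distance notions used to measure spread on a surface.
#
# 2D ignores height, 3D is the straight line through the volume, and
# the shortest within-surface distance (SWSD) is the geodesic distance
# along face-adjacent surface nodes.  The SWSD uses orthogonal
# (city-block) propagation with every hop costing one node unit, so on
# a flat surface it is systematically longer than the Euclidean
# distance (7 versus 5 on a 3-4-5 triangle); relative measures such as
# D_rel factor that difference out.

#' Planar Euclidean distance between nodes
#'
#' @param a,b numeric vectors of length 3 (or matrices with three
#'   columns) of node coordinates; z is ignored.
#' @return `sqrt(dx^2 + dy^2)`.
#' @export
euclidean_2d <- function(a, b) {
  a <- unname(rbind(a)); b <- unname(rbind(b))
  c(sqrt((a[, 1L] - b[, 1L])^2 + (a[, 2L] - b[, 2L])^2))
}

#' Volume Euclidean distance between nodes
#'
#' @inheritParams euclidean_2d
#' @return `sqrt(dx^2 + dy^2 + dz^2)`.
#' @export
euclidean_3d <- function(a, b) {
  a <- unname(rbind(a)); b <- unname(rbind(b))
  c(sqrt((a[, 1L] - b[, 1L])^2 + (a[, 2L] - b[, 2L])^2 +
           (a[, 3L] - b[, 3L])^2))
}

#' Geodesic (shortest within-surface) distance transform
#'
#' Computes the SWSD from a start node to every surface node by
#' wave-front propagation: breadth-first expansion of the frontier with
#' every hop between face-adjacent nodes costing one node unit, the
#' discrete city-block geodesic.  Unreachable nodes are reported as
#' `Inf`.
#'
#' @param surface a `surface_graph`.
#' @param start node index or coordinate triple (x, y, z).
#' @return Numeric vector of per-node distances in node units.
#' @export
geodesic_transform <- function(surface, start) {
  stopifnot(inherits(surface, "surface_graph"))
  i0 <- resolve_start(surface, start)
  d <- .bfs_csr(surface$adj_ptr, surface$adj_idx - 1L, i0 - 1L)
  d <- as.numeric(d)
  d[d < 0] <- Inf
  d
}

resolve_start <- function(surface, start) {
  if (length(start) == 1L) {
    i0 <- as.integer(start)
    if (is.na(i0) || i0 < 1L || i0 > n_nodes(surface)) {
      stop_invalid_spec("start node index out of range")
    }
    i0
  } else {
    node_index(surface, start)
  }
}

#' Distance maps from a start node
#'
#' Bundles the three per-node distance measures from one start node:
#' planar Euclidean (`d2`), volume Euclidean (`d3`) and the shortest
#' within-surface distance (`dswsd`).  For every node
#' `dswsd >= d3 >= d2`.
#'
#' @inheritParams geodesic_transform
#' @return A `distance_maps` object with fields `d2`, `d3`, `dswsd`,
#'   `start` (coordinates), `start_index` and a provenance signature of
#'   the surface.
#' @export
distance_maps <- function(surface, start) {
  stopifnot(inherits(surface, "surface_graph"))
  i0 <- resolve_start(surface, start)
  cc <- surface$coords
  s <- cc[i0, ]
  dx2 <- (cc[, 1L] - s[1L])^2 + (cc[, 2L] - s[2L])^2
  structure(list(
    d2 = sqrt(dx2),
    d3 = sqrt(dx2 + (cc[, 3L] - s[3L])^2),
    dswsd = geodesic_transform(surface, i0),
    start = s,
    start_index = i0,
    surface_signature = surface_signature(surface)
  ), class = "distance_maps")
}

#' @export
print.distance_maps <- function(x, ...) {
  fin <- is.finite(x$dswsd)
  cat("<distance_maps> from node (", paste(x$start, collapse = ","), "), ",
      length(x$d2), " nodes\n", sep = "")
  cat(sprintf("  max d2 %.1f | max d3 %.1f | max swsd %s | unreachable %d\n",
              max(x$d2), max(x$d3),
              format(max(x$dswsd[fin])), sum(!fin)))
  invisible(x)
}

# Cheap provenance fingerprint used by contract checks between
# surfaces, fields and maps produced in one analysis.
surface_signature <- function(surface) {
  list(n = n_nodes(surface), volume_shape = unname(surface$volume_shape),
       builder = surface$builder)
}

same_surface <- function(a, b) {
  identical(a$n, b$n) && identical(a$volume_shape, b$volume_shape)
}
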