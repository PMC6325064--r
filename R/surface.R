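# Voxel surfaces as graphs of 6-connected cubic nodes.
#
# Every builder in this file works through an integer height map: a
# matrix H with one height per pixel (rows = y, columns = x, origin
# top-left).  The surface places a node at (x, y, H[x, y]) for every
# pixel and, wherever 4-adjacent pixels differ in height, adds a
# vertical run of connector nodes at the higher pixel's (x, y) covering
# z = min(h) .. max(h)-1, which makes every height step face-connected
# (the run includes the lower endpoint height; excluding it would leave
# the two columns touching only diagonally).

#' Construct a surface graph from an integer height map
#'
#' Converts a height-coded 2D image into a voxel surface inside a 3D
#' volume: each pixel contributes a node at its height, and vertical
#' lines of connector nodes are inserted between 4-adjacent pixels of
#' differing height so that the result is a single face-connected
#' surface wherever the pixel grid is connected.
#'
#' @param heights integer matrix of non-negative heights; rows are y
#'   (top row is y = 0), columns are x.  Node coordinates are 0-based
#'   with z = height and a node spacing of one distance unit.
#' @param nz z-extent of the bounding volume; defaults to `max(heights) + 1`.
#' @param builder,params builder name and parameter list recorded as
#'   metadata.
#' @return A `surface_graph` object: a list with the node coordinate
#'   matrix `coords` (n x 3, columns x, y, z), the CSR face-adjacency
#'   (`adj_ptr`, `adj_idx`), per-node `degree`, `volume_shape`, the
#'   originating `heights` map and builder metadata.
#' @examples
#' s <- build_from_height_map(matrix(0L, 4, 4))
#' s$degree
#' @export
build_from_height_map <- function(heights, nz = NULL, builder = "height_map",
                                  params = list()) {
  if (!is.matrix(heights) || length(heights) == 0L) {
    stop_invalid_spec("heights must be a non-empty matrix")
  }
  if (anyNA(heights) || any(heights < 0) || any(heights != round(heights))) {
    stop_invalid_spec("heights must be non-negative integers")
  }
  H <- matrix(as.integer(round(heights)), nrow(heights), ncol(heights))
  ny <- nrow(H); nx <- ncol(H)
  if (is.null(nz)) nz <- max(H) + 1L
  nz <- check_count(nz, "nz")
  if (max(H) >= nz) stop_invalid_spec("heights must fit within the volume: ",
                                      "max height ", max(H), " >= nz ", nz)

  nxy <- as.double(nx) * ny
  # occupancy mask over the volume; linear index = x + nx*y + nx*ny*z
  mask <- logical(nxy * nz)
  x <- rep.int(0:(nx - 1L), rep.int(ny, nx))   # column-major traversal of H
  y <- rep.int(0:(ny - 1L), nx)
  z <- as.integer(H)
  mask[x + as.double(nx) * y + nxy * z + 1] <- TRUE

  add_conn <- function(h1, h2, xh, yh) {
    lo <- pmin(h1, h2); hi <- pmax(h1, h2)
    keep <- which(hi > lo)
    if (!length(keep)) return(double(0))
    cnt <- hi[keep] - lo[keep]
    xs <- rep(xh[keep], cnt)
    ys <- rep(yh[keep], cnt)
    zs <- sequence(cnt, from = lo[keep], by = 1L)
    xs + as.double(nx) * ys + nxy * zs
  }
  if (nx > 1L) {
    i1 <- which(x < nx - 1L)
    h1 <- z[i1]; h2 <- z[i1 + ny]            # pixel one step +x
    mask[add_conn(h1, h2, x[i1] + (h2 > h1), y[i1]) + 1] <- TRUE
  }
  if (ny > 1L) {
    i2 <- which(y < ny - 1L)
    h1 <- z[i2]; h2 <- z[i2 + 1L]            # pixel one step +y
    mask[add_conn(h1, h2, x[i2], y[i2] + (h2 > h1)) + 1] <- TRUE
  }

  surface_from_mask(mask, nx, ny, nz, heights = H, builder = builder,
                    params = params)
}

# Shared finish: occupancy mask -> surface_graph with CSR adjacency.
surface_from_mask <- function(mask, nx, ny, nz, heights = NULL,
                              builder = "node_set", params = list()) {
  nxy <- as.double(nx) * ny
  lin <- which(mask) - 1                      # sorted 0-based linear indices
  n <- length(lin)
  if (n == 0L) stop_invalid_spec("surface has no nodes")
  id <- integer(length(mask))
  id[lin + 1] <- seq_len(n)
  zc <- as.integer(lin %/% nxy)
  r <- lin - nxy * zc
  yc <- as.integer(r %/% nx)
  xc <- as.integer(r - as.double(nx) * yc)

  # neighbour ids in the six face directions (0 = absent)
  M <- matrix(0L, nrow = n, ncol = 6L)
  ok <- xc > 0L;      M[ok, 1L] <- id[lin[ok]]            # lin - 1 (+1 for R)
  ok <- xc < nx - 1L; M[ok, 2L] <- id[lin[ok] + 2]
  ok <- yc > 0L;      M[ok, 3L] <- id[lin[ok] - nx + 1]
  ok <- yc < ny - 1L; M[ok, 4L] <- id[lin[ok] + nx + 1]
  ok <- zc > 0L;      M[ok, 5L] <- id[lin[ok] - nxy + 1]
  ok <- zc < nz - 1L; M[ok, 6L] <- id[lin[ok] + nxy + 1]
  tM <- t(M)
  adj_idx <- tM[tM != 0L]
  degree <- as.integer(rowSums(M != 0L))
  adj_ptr <- c(0, cumsum(degree))
  storage.mode(adj_ptr) <- "integer"

  structure(list(
    coords = cbind(x = xc, y = yc, z = zc),
    adj_ptr = adj_ptr,
    adj_idx = adj_idx,
    degree = degree,
    volume_shape = c(nx = nx, ny = ny, nz = nz),
    heights = heights,
    builder = builder,
    params = params,
    connector_rule = "vertical run at higher pixel, z = min(h)..max(h)-1"
  ), class = "surface_graph")
}

#' Construct a surface graph from an explicit node set
#'
#' Builds the face-adjacency graph of an arbitrary set of voxel nodes.
#' Mostly useful for small hand-made graphs and for deserialization;
#' the height-map builders are the normal entry point.
#'
#' @param coords integer matrix with columns x, y, z (0-based).
#' @param volume_shape bounding volume; defaults to the coordinate
#'   ranges.
#' @inheritParams build_from_height_map
#' @return A `surface_graph` (without a height map).
#' @export
build_from_nodes <- function(coords, volume_shape = NULL,
                             builder = "node_set", params = list()) {
  coords <- rbind(coords)
  if (ncol(coords) != 3L || anyNA(coords) || any(coords < 0)) {
    stop_invalid_spec("coords must be non-negative (x, y, z) triples")
  }
  if (is.null(volume_shape)) volume_shape <- apply(coords, 2L, max) + 1L
  vs <- as.integer(volume_shape)
  if (any(coords >= matrix(vs, nrow(coords), 3L, byrow = TRUE))) {
    stop_invalid_spec("coords exceed volume_shape")
  }
  nxy <- as.double(vs[1L]) * vs[2L]
  mask <- logical(nxy * vs[3L])
  mask[coords[, 1L] + as.double(vs[1L]) * coords[, 2L] +
         nxy * coords[, 3L] + 1] <- TRUE
  surface_from_mask(mask, vs[1L], vs[2L], vs[3L], builder = builder,
                    params = params)
}

n_nodes <- function(surface) nrow(surface$coords)

#' Look up the node index of a coordinate triple
#'
#' @param surface a `surface_graph`.
#' @param xyz length-3 integer vector (x, y, z), 0-based.
#' @return The row index of the node in `surface$coords`, or an
#'   invalid-spec error if the coordinate is not on the surface.
#' @export
node_index <- function(surface, xyz) {
  stopifnot(inherits(surface, "surface_graph"))
  if (length(xyz) == 2L) xyz <- c(xyz, surface_height_at(surface, xyz))
  if (length(xyz) != 3L || anyNA(xyz)) {
    stop_invalid_spec("node coordinate must be (x, y, z)")
  }
  vs <- surface$volume_shape
  cc <- surface$coords
  i <- which(cc[, 1L] == xyz[1L] & cc[, 2L] == xyz[2L] & cc[, 3L] == xyz[3L])
  if (length(i) != 1L) {
    stop_invalid_spec("node (", paste(xyz, collapse = ","),
                      ") is not on the surface")
  }
  i
}

surface_height_at <- function(surface, xy) {
  H <- surface$heights
  if (is.null(H)) return(NA_integer_)
  H[xy[2L] + 1L, xy[1L] + 1L]
}

#' Neighbours of a node
#' @param surface a `surface_graph`.
#' @param i node index.
#' @return Integer vector of face-adjacent node indices.
#' @export
node_neighbors <- function(surface, i) {
  p <- surface$adj_ptr
  if (p[i + 1L] == p[i]) return(integer(0))
  surface$adj_idx[(p[i] + 1L):p[i + 1L]]
}

#' Classify surface nodes by neighbour count
#'
#' On a flat or folded surface every interior node has four
#' face-neighbours; deformed surfaces additionally contain external
#' corners (three neighbours) and internal corners (five neighbours),
#' which locally speed up or slow down the spread of a random walk.
#'
#' @param surface a `surface_graph`.
#' @return A list with `degree` (per-node neighbour count) and
#'   `histogram` (named counts over degrees 0..6).
#' @export
classify_nodes <- function(surface) {
  stopifnot(inherits(surface, "surface_graph"))
  h <- tabulate(surface$degree + 1L, nbins = 7L)
  names(h) <- 0:6
  list(degree = surface$degree, histogram = h)
}

#' @export
print.surface_graph <- function(x, ...) {
  vs <- x$volume_shape
  cat("<surface_graph> ", n_nodes(x), " nodes in a ",
      paste(vs, collapse = " x "), " volume\n", sep = "")
  cat("  builder: ", x$builder, "\n", sep = "")
  h <- classify_nodes(x)$histogram
  h <- h[h > 0]
  cat("  neighbour counts: ",
      paste(sprintf("%s:%d", names(h), h), collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.surface_graph <- function(object, ...) {
  cls <- classify_nodes(object)
  res <- list(
    n_nodes = n_nodes(object),
    n_edges = length(object$adj_idx) %/% 2L,
    volume_shape = object$volume_shape,
    builder = object$builder,
    params = object$params,
    degree_histogram = cls$histogram,
    connected = is_connected(object)
  )
  class(res) <- "summary.surface_graph"
  res
}

#' @export
print.summary.surface_graph <- function(x, ...) {
  cat("Surface:", x$builder, "|", x$n_nodes, "nodes,", x$n_edges, "edges,",
      if (x$connected) "connected" else "NOT connected", "\n")
  print(x$degree_histogram)
  invisible(x)
}

#' @export
plot.surface_graph <- function(x, ...) {
  H <- x$heights
  if (is.null(H)) stop("surface has no height map to display")
  # image() wants x along rows; flip y so the origin is top-left
  image(x = 0:(ncol(H)), y = 0:(nrow(H)), z = t(H)[, rev(seq_len(nrow(H))), drop = FALSE],
        col = hcl.colors(64, "viridis"), xlab = "x [nodes]", ylab = "y [nodes]",
        useRaster = TRUE, ...)
  invisible(x)
}

# Connectivity via the wave-front transform (single connected component
# iff every node is reachable from node 1).
is_connected <- function(surface) {
  d <- .bfs_csr(surface$adj_ptr, surface$adj_idx - 1L, 0L)
  all(d >= 0L)
}

# ---------------------------------------------------------------------------
# Height-map generators (internal).  All heights sit on a common
# `level` so generators can be composed into quadrant arenas.

heights_flat <- function(nx, ny, level = 0L) {
  matrix(as.integer(level), nrow = ny, ncol = nx)
}

heights_ridges <- function(nx, ny, ridge_height, ridge_width, spacing,
                           orientation = "y", level = 0L, phase = 0L) {
  period <- ridge_width + spacing
  if (orientation == "y") {
    H <- matrix(as.integer(level), ny, nx)
    ridge <- ((0:(nx - 1L) - phase) %% period) < ridge_width
    H[, ridge] <- level + ridge_height
  } else {
    H <- matrix(as.integer(level), ny, nx)
    ridge <- ((0:(ny - 1L) - phase) %% period) < ridge_width
    H[ridge, ] <- level + ridge_height
  }
  H
}

# Footprint of one pillar base: base x base square, optionally with the
# four corner pixels removed ("corners indented").
pillar_footprint <- function(base, indent_corners = TRUE) {
  fp <- matrix(TRUE, base, base)
  if (indent_corners && base >= 2L) {
    fp[c(1L, base), 1L] <- FALSE
    fp[c(1L, base), base] <- FALSE
  }
  fp
}

# Pillar/pit centres on a hexagonal-like grid embedded in the square
# lattice: rows spaced by round(spacing * sqrt(3)/2), odd rows shifted
# by half the spacing.
hex_centres <- function(nx, ny, spacing, margin) {
  ry <- max(1L, as.integer(round(spacing * sqrt(3) / 2)))
  ys <- seq.int(margin, ny - 1L - margin, by = ry)
  out <- NULL
  for (k in seq_along(ys)) {
    off <- if (k %% 2L == 0L) as.integer(round(spacing / 2)) else 0L
    xs <- seq.int(margin + off, nx - 1L - margin, by = spacing)
    out <- rbind(out, cbind(xs, ys[k]))
  }
  out
}

heights_pillars <- function(nx, ny, base, pillar_height, grid_spacing,
                            level = 0L, indent_corners = TRUE) {
  if (grid_spacing < base) {
    stop_invalid_spec("pillars overlap: grid_spacing ", grid_spacing,
                      " < base ", base)
  }
  H <- matrix(as.integer(level), ny, nx)
  fp <- pillar_footprint(base, indent_corners)
  half <- base %/% 2L
  ctr <- hex_centres(nx, ny, grid_spacing, margin = half)
  if (is.null(ctr) || nrow(ctr) == 0L) {
    stop_invalid_spec("no pillar fits within the volume")
  }
  for (k in seq_len(nrow(ctr))) {
    xs <- (ctr[k, 1L] - half) + 0:(base - 1L)
    ys <- (ctr[k, 2L] - half) + 0:(base - 1L)
    keep <- xs >= 0L & xs < nx
    keepy <- ys >= 0L & ys < ny
    sub <- fp[keepy, keep, drop = FALSE]
    blk <- H[ys[keepy] + 1L, xs[keep] + 1L, drop = FALSE]
    blk[sub] <- level + pillar_height
    H[ys[keepy] + 1L, xs[keep] + 1L] <- blk
  }
  H
}

heights_invaginations <- function(nx, ny, base, depth, grid_spacing,
                                  level = NULL, indent_corners = FALSE) {
  if (is.null(level)) level <- depth
  if (level < depth) {
    stop_invalid_spec("invagination depth ", depth,
                      " exceeds the surface level ", level)
  }
  H <- heights_pillars(nx, ny, base, -depth, grid_spacing, level = level,
                       indent_corners = indent_corners)
  H
}

heights_bumps <- function(nx, ny, bump_height = 2L, bump_width = 3L,
                          spacing = 3L, level = 0L) {
  period <- bump_width + spacing
  H <- matrix(as.integer(level), ny, nx)
  bx <- ((0:(nx - 1L)) %% period) < bump_width
  by <- ((0:(ny - 1L)) %% period) < bump_width
  H[by, bx] <- level + bump_height
  H
}

# ---------------------------------------------------------------------------
# Public builders.

#' Build a flat horizontal surface
#'
#' @param width,height extents in nodes along x and y.
#' @param level constant z of the sheet (default 0).
#' @return A `surface_graph`; all nodes lie at `z = level`, interior
#'   nodes have four neighbours.
#' @examples
#' build_flat(3, 3)
#' @export
build_flat <- function(width, height, level = 0L) {
  width <- check_count(width, "width")
  height <- check_count(height, "height")
  build_from_height_map(heights_flat(width, height, level),
                        nz = as.integer(level) + 1L, builder = "flat",
                        params = list(width = width, height = height,
                                      level = as.integer(level)))
}

#' Build a folded surface of parallel ridges
#'
#' Ridges of constant height and width separated by flat spacing,
#' running along the chosen axis.  The result is a *folded* surface:
#' it unrolls to a flat sheet and every interior node has exactly four
#' neighbours.  Ridge widths below 3 are rejected because the two wall
#' columns of a 1- or 2-node-wide ridge coincide or touch at the base,
#' which creates internal corners and destroys the folded property.
#'
#' @param volume_shape integer triple (nx, ny, nz).
#' @param ridge_height,ridge_width,spacing ridge geometry in nodes;
#'   `ridge_height = 0` degenerates to [build_flat()].
#' @param orientation `"y"` (ridges parallel to the y axis, default) or
#'   `"x"`.
#' @param phase offset of the first ridge along the folded axis.
#' @return A `surface_graph`.
#' @export
build_ridges <- function(volume_shape, ridge_height, ridge_width, spacing,
                         orientation = c("y", "x"), phase = 0L) {
  orientation <- match.arg(orientation)
  vs <- as.integer(volume_shape)
  if (length(vs) != 3L || any(vs < 1L)) {
    stop_invalid_spec("volume_shape must be three positive integers")
  }
  ridge_height <- check_count(ridge_height, "ridge_height", min = 0L)
  spacing <- check_count(spacing, "spacing", min = 0L)
  if (ridge_height == 0L) {
    return(build_flat(vs[1L], vs[2L]))
  }
  ridge_width <- check_count(ridge_width, "ridge_width", min = 3L)
  if (ridge_height >= vs[3L]) {
    stop_invalid_spec("ridge_height ", ridge_height,
                      " does not fit in volume z-extent ", vs[3L])
  }
  H <- heights_ridges(vs[1L], vs[2L], ridge_height, ridge_width, spacing,
                      orientation, phase = as.integer(phase))
  build_from_height_map(H, nz = vs[3L], builder = "ridges",
                        params = list(ridge_height = ridge_height,
                                      ridge_width = ridge_width,
                                      spacing = spacing,
                                      orientation = orientation,
                                      phase = as.integer(phase)))
}

#' Build a deformed surface of pillars on a hexagonal grid
#'
#' Flat-topped pillars with a square base (corner pixels indented by
#' default) rising from a horizontal floor.  Pillars are deformed
#' features: their top rims carry external corners (three neighbours);
#' with `indent_corners = FALSE` the square feet additionally carry
#' internal corners (five neighbours), which the indentation removes.
#'
#' @param volume_shape integer triple (nx, ny, nz).
#' @param base side of the square pillar base in nodes.
#' @param pillar_height rise above the floor in nodes.
#' @param grid_spacing centre-to-centre spacing of the hexagonal layout.
#' @param indent_corners drop the four corner pixels of each base.
#' @return A `surface_graph`.
#' @export
build_pillars <- function(volume_shape, base = 5L, pillar_height = 15L,
                          grid_spacing = 12L, indent_corners = TRUE) {
  vs <- as.integer(volume_shape)
  base <- check_count(base, "base")
  pillar_height <- check_count(pillar_height, "pillar_height")
  grid_spacing <- check_count(grid_spacing, "grid_spacing")
  if (pillar_height >= vs[3L]) {
    stop_invalid_spec("pillar_height ", pillar_height,
                      " does not fit in volume z-extent ", vs[3L])
  }
  H <- heights_pillars(vs[1L], vs[2L], base, pillar_height, grid_spacing,
                       indent_corners = indent_corners)
  build_from_height_map(H, nz = vs[3L], builder = "pillars",
                        params = list(base = base,
                                      pillar_height = pillar_height,
                                      grid_spacing = grid_spacing,
                                      indent_corners = indent_corners))
}

#' Build a deformed surface of square invaginations (pits)
#'
#' The inverse of [build_pillars()]: square pits of the given depth sunk
#' into a floor raised to `level` (default the pit depth, so pit floors
#' sit at z = 0).
#'
#' @inheritParams build_pillars
#' @param depth pit depth in nodes.
#' @param level z of the surrounding floor.
#' @export
build_invaginations <- function(volume_shape, base = 5L, depth = 4L,
                                grid_spacing = 12L, level = NULL,
                                indent_corners = FALSE) {
  vs <- as.integer(volume_shape)
  depth <- check_count(depth, "depth")
  H <- heights_invaginations(vs[1L], vs[2L], base, depth, grid_spacing,
                             level = level, indent_corners = indent_corners)
  if (max(H) >= vs[3L]) {
    stop_invalid_spec("floor level ", max(H),
                      " does not fit in volume z-extent ", vs[3L])
  }
  build_from_height_map(H, nz = vs[3L], builder = "invaginations",
                        params = list(base = base, depth = depth,
                                      grid_spacing = grid_spacing,
                                      level = max(H),
                                      indent_corners = indent_corners))
}

#' Build a densely bumped (highly deformed) surface
#'
#' Small square bumps on a dense regular grid.
#'
#' @inheritParams build_pillars
#' @param bump_height,bump_width,spacing bump geometry in nodes.
#' @export
build_bumps <- function(volume_shape, bump_height = 2L, bump_width = 3L,
                        spacing = 3L) {
  vs <- as.integer(volume_shape)
  H <- heights_bumps(vs[1L], vs[2L], bump_height, bump_width, spacing)
  if (max(H) >= vs[3L]) stop_invalid_spec("bumps do not fit in the volume")
  build_from_height_map(H, nz = vs[3L], builder = "bumps",
                        params = list(bump_height = bump_height,
                                      bump_width = bump_width,
                                      spacing = spacing))
}

#' Compose a surface from four quadrant topographies
#'
#' Builds one connected surface whose four quadrants (top-left,
#' top-right, bottom-left, bottom-right of the height map) carry
#' different topographies, e.g. flat / ridges / pillars / invaginations.
#' All quadrant generators must share the same floor level, otherwise
#' the quadrants would not join into a continuous surface at a common
#' boundary height.
#'
#' @param volume_shape integer triple (nx, ny, nz); nx and ny must be
#'   even.
#' @param quadrants list of four specs, in the order top-left,
#'   top-right, bottom-left, bottom-right.  Each spec is a list with
#'   `builder` (one of "flat", "ridges", "pillars", "invaginations",
#'   "bumps") and optional `params` passed to the height-map generator.
#' @param level common floor level of the four quadrants.
#' @return A `surface_graph`.
#' @export
build_quadrant_composite <- function(volume_shape, quadrants, level = NULL) {
  vs <- as.integer(volume_shape)
  if (length(quadrants) != 4L) {
    stop_invalid_spec("exactly four quadrant specs are required")
  }
  if (vs[1L] %% 2L || vs[2L] %% 2L) {
    stop_invalid_spec("volume x/y extents must be even")
  }
  qx <- vs[1L] %/% 2L
  qy <- vs[2L] %/% 2L
  if (is.null(level)) {
    depths <- vapply(quadrants, function(q) {
      if (identical(q$builder, "invaginations")) {
        as.integer(q$params$depth %||% 4L)
      } else 0L
    }, integer(1))
    level <- max(depths)
  }
  level <- as.integer(level)
  gen <- function(q) {
    p <- q$params %||% list()
    switch(q$builder,
      flat = heights_flat(qx, qy, level),
      ridges = do.call(heights_ridges,
                       c(list(nx = qx, ny = qy, level = level),
                         p[setdiff(names(p), c("nx", "ny", "level"))])),
      pillars = do.call(heights_pillars,
                        c(list(nx = qx, ny = qy, level = level),
                          p[setdiff(names(p), c("nx", "ny", "level"))])),
      invaginations = do.call(heights_invaginations,
                              c(list(nx = qx, ny = qy, level = level),
                                p[setdiff(names(p), c("nx", "ny", "level"))])),
      bumps = do.call(heights_bumps,
                      c(list(nx = qx, ny = qy, level = level),
                        p[setdiff(names(p), c("nx", "ny", "level"))])),
      stop_invalid_spec("unknown quadrant builder: ", q$builder)
    )
  }
  Hs <- lapply(quadrants, gen)
  for (H in Hs) {
    if (any(H < 0L)) stop_invalid_spec("quadrant heights fall below zero; ",
                                       "raise the common level")
  }
  H <- rbind(cbind(Hs[[1L]], Hs[[2L]]), cbind(Hs[[3L]], Hs[[4L]]))
  if (max(H) >= vs[3L]) {
    stop_invalid_spec("quadrant heights do not fit in volume z-extent ",
                      vs[3L])
  }
  build_from_height_map(H, nz = vs[3L], builder = "quadrant_composite",
                        params = list(quadrants = quadrants, level = level))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Insert a slot or notch defect into a ridged surface
#'
#' A *slot* is a one-node-wide full-height gap cut through a ridge down
#' to the floor, opening a passage at the ridge base; its base corners
#' become internal corners with five neighbours.  A *notch* is a
#' one-node-wide cut of the given `depth` taken from the ridge top.  The
#' exact notch depth is not constrained by the geometry; it defaults to
#' one node and is exposed as a parameter.
#'
#' @param surface a `surface_graph` built by [build_ridges()] (or any
#'   height-map surface whose ridges run along y or x).
#' @param kind `"slot"`, `"notch"`, or `"none"` (returns the surface
#'   unchanged).
#' @param position length-2 integer (x, y): a pixel on the ridge to cut.
#' @param depth notch depth in nodes (ignored for slots).
#' @return A new `surface_graph` with the defect inserted.
#' @export
insert_defect <- function(surface, kind = c("slot", "notch", "none"),
                          position, depth = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(surface, "surface_graph"))
  if (kind == "none") return(surface)
  H <- surface$heights
  if (is.null(H)) stop_invalid_spec("surface carries no height map")
  x <- as.integer(position[1L]); y <- as.integer(position[2L])
  nyH <- nrow(H); nxH <- ncol(H)
  if (x < 0L || x >= nxH || y < 0L || y >= nyH) {
    stop_invalid_spec("defect position out of bounds")
  }
  orientation <- surface$params$orientation %||% "y"
  if (orientation == "y") {
    row <- H[y + 1L, ]
    at <- x
  } else {
    row <- H[, x + 1L]
    at <- y
  }
  floor_level <- min(row)
  if (row[at + 1L] <= floor_level) {
    stop_invalid_spec("defect position (", x, ",", y, ") is not on a ridge")
  }
  # contiguous elevated run containing the position = the ridge footprint
  lo <- at
  while (lo > 0L && row[lo] > floor_level) lo <- lo - 1L
  hi <- at
  while (hi < length(row) - 1L && row[hi + 2L] > floor_level) hi <- hi + 1L
  ridge_top <- row[at + 1L]
  newh <- if (kind == "slot") floor_level else {
    depth <- check_count(depth, "depth")
    max(floor_level, ridge_top - depth)
  }
  if (orientation == "y") {
    H[y + 1L, (lo:hi) + 1L] <- newh
  } else {
    H[(lo:hi) + 1L, x + 1L] <- newh
  }
  params <- surface$params
  params$defect <- list(kind = kind, position = c(x = x, y = y),
                        depth = if (kind == "notch") depth else NA_integer_)
  build_from_height_map(H, nz = surface$volume_shape[3L],
                        builder = paste0(surface$builder, "+", kind),
                        params = params)
}
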