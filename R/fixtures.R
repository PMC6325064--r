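# Named, reproducible study surfaces with their canonical start nodes.
#
# Each fixture is rebuilt bit-exactly from its name plus parameters
# (plus seed where stochastic).  Sizes are chosen so that, at the
# iteration counts used in the package analyses, the probability mass
# near the volume rim is far below double precision and boundary
# effects cannot contaminate MSD curves.

fixture_defs <- function() {
  list(
    flat_1024 = list(
      description = "1024 x 1024 flat reference surface (D_rel baseline)",
      build = function(p) {
        s <- build_flat(p$width %||% 1024L, p$height %||% 1024L)
        list(surface = s,
             starts = list(centre = c(511L, 511L, 0L)))
      }),
    flat_256 = list(
      description = "256 x 256 flat surface for short runs",
      build = function(p) {
        s <- build_flat(p$width %||% 256L, p$height %||% 256L)
        list(surface = s, starts = list(centre = c(127L, 127L, 0L)))
      }),
    ridges_folded = list(
      description = paste("folded surface: parallel ridges 4 high, 4 wide,",
                          "2 spacing in a 512 x 1024 x 5 volume"),
      build = function(p) {
        vol <- p$volume_shape %||% c(512L, 1024L, 5L)
        h <- p$ridge_height %||% 4L
        w <- p$ridge_width %||% 4L
        sp <- p$spacing %||% 2L
        s <- build_ridges(vol, h, w, sp)
        # phase-0 pattern: ridges at x %% (w+sp) in 0..(w-1), gaps after;
        # start presets sit near the volume centre on a gap floor and on
        # the middle of the next ridge wall
        p_ <- w + sp
        ymid <- (vol[2L] - 1L) %/% 2L
        floor_x <- p_ * ((vol[1L] %/% 2L) %/% p_) + w + (sp - 1L) %/% 2L
        wall_x <- p_ * ((vol[1L] %/% 2L) %/% p_) + p_
        list(surface = s,
             starts = list(
               floor = c(floor_x, ymid, 0L),
               wall = c(wall_x, ymid, h %/% 2L)))
      }),
    pillars_hex = list(
      description = paste("deformed surface: 5 x 5 base pillars (corners",
                          "indented), 15 high, hexagonal 12-node spacing"),
      build = function(p) {
        vol <- p$volume_shape %||% c(256L, 256L, 16L)
        s <- build_pillars(vol, p$base %||% 5L, p$pillar_height %||% 15L,
                           p$grid_spacing %||% 12L)
        H <- s$heights
        top <- which(H == max(H), arr.ind = TRUE)[1L, ]
        floor_px <- which(H == min(H), arr.ind = TRUE)
        ctr <- floor_px[which.min((floor_px[, 1L] - nrow(H) / 2)^2 +
                                    (floor_px[, 2L] - ncol(H) / 2)^2), ]
        list(surface = s,
             starts = list(
               floor = c(ctr[2L] - 1L, ctr[1L] - 1L, 0L),
               pillar_top = c(top[2L] - 1L, top[1L] - 1L, max(H))))
      }),
    invaginations_hex = list(
      description = "deformed surface: square pits 4 deep on a hexagonal grid",
      build = function(p) {
        vol <- p$volume_shape %||% c(256L, 256L, 6L)
        s <- build_invaginations(vol, p$base %||% 5L, p$depth %||% 4L,
                                 p$grid_spacing %||% 12L)
        H <- s$heights
        floor_px <- which(H == max(H), arr.ind = TRUE)
        ctr <- floor_px[which.min((floor_px[, 1L] - nrow(H) / 2)^2 +
                                    (floor_px[, 2L] - ncol(H) / 2)^2), ]
        list(surface = s,
             starts = list(floor = c(ctr[2L] - 1L, ctr[1L] - 1L, max(H))))
      }),
    quadrant_demo = list(
      description = paste("four-quadrant arena: flat, ridges, pillars and",
                          "invaginations sharing one floor level"),
      build = function(p) {
        vol <- p$volume_shape %||% c(256L, 256L, 24L)
        lvl <- p$level %||% 4L
        s <- build_quadrant_composite(vol, list(
          list(builder = "flat"),
          list(builder = "ridges",
               params = list(ridge_height = 4L, ridge_width = 4L,
                             spacing = 2L)),
          list(builder = "invaginations",
               params = list(base = 5L, depth = lvl, grid_spacing = 12L)),
          list(builder = "pillars",
               params = list(base = 5L, pillar_height = 15L,
                             grid_spacing = 12L))), level = lvl)
        ctr <- c(vol[1L] %/% 2L - 1L, vol[2L] %/% 2L - 1L)
        list(surface = s,
             starts = list(centre = c(ctr[1L], ctr[2L],
                                      surface_height_at(s, ctr))))
      }),
    ridges_defect = list(
      description = paste("ridges 7 high, 3 wide at 12-node intervals in a",
                          "1023 x 1023 x 9 volume; variants control, slot,",
                          "notch with start midway between the defect and",
                          "the next ridge"),
      build = function(p) {
        vol <- p$volume_shape %||% c(1023L, 1023L, 9L)
        h <- p$ridge_height %||% 7L
        w <- p$ridge_width %||% 3L
        interval <- p$interval %||% 12L
        variant <- p$variant %||% "control"
        depth <- p$notch_depth %||% 1L
        s <- build_ridges(vol, h, w, interval - w)
        # phase-0 pattern: ridges occupy x %% 12 in 0..2, gap middles at
        # x %% 12 == 7; the volume centre (511, 511) is such a middle.
        xmid <- (vol[1L] - 1L) %/% 2L
        ymid <- (vol[2L] - 1L) %/% 2L
        defect_x <- xmid + (interval - w) %/% 2L + 1L  # first column of the
                                                       # ridge right of start
        if (variant != "control") {
          s <- insert_defect(s, variant, c(defect_x, ymid), depth = depth)
        }
        list(surface = s,
             starts = list(midgap = c(xmid, ymid, 0L)),
             defect = c(defect_x, ymid))
      }),
    bumps_dense = list(
      description = "highly deformed surface: dense grid of small bumps",
      build = function(p) {
        vol <- p$volume_shape %||% c(256L, 256L, 4L)
        s <- build_bumps(vol, p$bump_height %||% 2L, p$bump_width %||% 3L,
                         p$spacing %||% 3L)
        ctr <- c(vol[1L] %/% 2L, vol[2L] %/% 2L)
        list(surface = s,
             starts = list(centre = c(ctr[1L], ctr[2L],
                                      surface_height_at(s, ctr))))
      }),
    synthetic_cell = list(
      description = paste("synthetic cell-like height map: smooth crowns",
                          "with superimposed ridges and bumps (seeded)"),
      build = function(p) {
        H <- do.call(synthetic_cell_heights, p[names(p) %in%
          c("nx", "ny", "n_crowns", "amplitude", "sigma", "ridge_amplitude",
            "ridge_period", "bump_amplitude", "n_bumps", "seed")])
        s <- build_from_height_map(H, builder = "synthetic_cell", params = p)
        top <- which(H == max(H), arr.ind = TRUE)[1L, ]
        list(surface = s,
             starts = list(crown = c(top[2L] - 1L, top[1L] - 1L, max(H))))
      })
  )
}

#' List the built-in surface fixtures
#'
#' @return Data frame of fixture names and descriptions.
#' @export
fixture_catalog <- function() {
  defs <- fixture_defs()
  data.frame(name = names(defs),
             description = vapply(defs, `[[`, "", "description"),
             row.names = NULL)
}

#' Build a named fixture surface with its start-node presets
#'
#' @param name a fixture name from [fixture_catalog()].
#' @param overrides named list of parameter overrides (e.g.
#'   `list(variant = "slot")` for `ridges_defect`, or a smaller
#'   `volume_shape`).
#' @return A list with `name`, `surface`, `starts` (named list of
#'   coordinate triples; the first entry is the canonical start) and
#'   any extra fixture fields (e.g. `defect` position).
#' @export
generate_fixture <- function(name, overrides = list()) {
  defs <- fixture_defs()
  if (!name %in% names(defs)) {
    stop_invalid_spec("unknown fixture '", name, "'; see fixture_catalog()")
  }
  out <- defs[[name]]$build(overrides)
  out$name <- name
  out$overrides <- overrides
  out$start <- out$starts[[1L]]
  out
}

#' Generate a synthetic cell-like height map
#'
#' Emulates the apical topography of cultured epithelial cells as seen
#' by hopping-probe ion conductance microscopy: a few smooth cell
#' "crowns" (2D Gaussians) with superimposed ridge undulations and
#' small bumps, quantized to integer node heights.  The output is fully
#' determined by the parameters and seed.
#'
#' @param nx,ny map extent in pixels.
#' @param n_crowns number of Gaussian crowns.
#' @param amplitude crown height in nodes.
#' @param sigma crown standard deviation in pixels.
#' @param ridge_amplitude,ridge_period sinusoidal ridge field (nodes /
#'   pixels); set amplitude 0 to disable.
#' @param bump_amplitude,n_bumps small square protrusions.
#' @param seed RNG seed.
#' @return Integer height matrix (rows = y, columns = x).
#' @export
synthetic_cell_heights <- function(nx = 512L, ny = 512L, n_crowns = 3L,
                                   amplitude = 36, sigma = 90,
                                   ridge_amplitude = 4, ridge_period = 24,
                                   bump_amplitude = 2, n_bumps = 400L,
                                   seed = 1L) {
  set.seed(seed)
  xs <- matrix(0:(nx - 1L), ny, nx, byrow = TRUE)
  ys <- matrix(0:(ny - 1L), ny, nx)
  H <- matrix(0, ny, nx)
  cx <- runif(n_crowns, nx * 0.25, nx * 0.75)
  cy <- runif(n_crowns, ny * 0.25, ny * 0.75)
  for (k in seq_len(n_crowns)) {
    H <- H + amplitude * exp(-((xs - cx[k])^2 + (ys - cy[k])^2) /
                               (2 * sigma^2))
  }
  if (ridge_amplitude > 0) {
    theta <- runif(1, 0, pi)
    u <- xs * cos(theta) + ys * sin(theta)
    H <- H + ridge_amplitude * 0.5 * (1 + sin(2 * pi * u / ridge_period))
  }
  if (bump_amplitude > 0 && n_bumps > 0) {
    bx <- sample.int(nx - 1L, n_bumps, replace = TRUE)
    by <- sample.int(ny - 1L, n_bumps, replace = TRUE)
    for (k in seq_len(n_bumps)) {
      H[by[k] + 0:1, bx[k] + 0:1] <- H[by[k] + 0:1, bx[k] + 0:1] +
        bump_amplitude
    }
  }
  matrix(as.integer(round(pmax(H, 0))), ny, nx)
}
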