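# On-disk formats: a versioned plain-text surface serialization, height
# maps as CSV or 16-bit TIFF, numeric series as CSV, Z-projections as
# CSV plus TIFF display copies, and a manifest with checksums for
# pipeline runs.  Adjacency is never stored; it is recomputed from the
# node list on load.

SURFACE_FORMAT <- "memtopo-surface-v1"

#' Serialize a surface to a plain-text file
#'
#' Writes the format tag, a JSON metadata line (volume shape, builder,
#' parameters, connector rule) and the node list as sorted x,y,z
#' triples.  Adjacency is recomputed on load, never stored.
#'
#' @param surface a `surface_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "surface_graph"))
  meta <- list(format = SURFACE_FORMAT,
               volume_shape = unname(surface$volume_shape),
               builder = surface$builder,
               params = surface$params,
               connector_rule = surface$connector_rule)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ", SURFACE_FORMAT),
               paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE)),
               "x,y,z"), con)
  write.table(surface$coords, con, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Load a surface serialized by [write_surface()]
#'
#' @param path file written by [write_surface()].
#' @return A `surface_graph` with identical node set and metadata;
#'   the height map is reconstructed when every (x, y) pixel column
#'   carries at least one node.
#' @export
read_surface <- function(path) {
  head2 <- readLines(path, n = 2L)
  if (!startsWith(head2[1L], paste0("# ", SURFACE_FORMAT))) {
    stop_invalid_spec("not a ", SURFACE_FORMAT, " file: ", path)
  }
  meta <- jsonlite::fromJSON(sub("^# ", "", head2[2L]))
  cc <- as.matrix(read.csv(path, skip = 2L))
  vs <- as.integer(meta$volume_shape)
  nxy <- as.double(vs[1L]) * vs[2L]
  mask <- logical(nxy * vs[3L])
  mask[cc[, 1L] + as.double(vs[1L]) * cc[, 2L] + nxy * cc[, 3L] + 1] <- TRUE
  s <- surface_from_mask(mask, vs[1L], vs[2L], vs[3L],
                         builder = meta$builder,
                         params = as.list(meta$params))
  # recover the height map (top node per pixel) for columnar surfaces
  o <- order(cc[, 3L])
  H <- matrix(NA_integer_, vs[2L], vs[1L])
  H[cbind(cc[o, 2L] + 1L, cc[o, 1L] + 1L)] <- cc[o, 3L]
  if (!anyNA(H)) s$heights <- H
  s
}

#' Read a height map from CSV or TIFF
#'
#' CSV: a headerless integer grid, one row per image row (origin
#' top-left).  TIFF: single-channel; 8/16-bit integer data are read
#' as raw integer heights.
#'
#' @param path input file; format chosen by extension.
#' @return Integer matrix (rows = y, columns = x).
#' @export
read_height_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  H <- if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img
  } else {
    as.matrix(read.csv(path, header = FALSE))
  }
  H <- matrix(as.integer(round(H)), nrow(H), ncol(H))
  if (anyNA(H) || any(H < 0)) {
    stop_invalid_spec("height map must contain non-negative integers")
  }
  H
}

#' Write a height map as CSV or 16-bit TIFF
#'
#' @param heights integer matrix (rows = y, columns = x); TIFF output
#'   requires heights below 65536.
#' @param path output file; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_height_map <- function(heights, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (max(heights) > 65535) stop_invalid_spec("heights exceed 16-bit TIFF")
    tiff::writeTIFF(heights / 65535, path, bits.per.sample = 16L)
  } else {
    write.table(heights, path, sep = ",", row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Summed Z-projection of a probability field
#'
#' Collapses the 3D field onto the imaging plane:
#' `image(x, y) = sum over z of mass(x, y, z)`.  The linear projection
#' conserves total mass; `log` and `sqrt` rescalings are display
#' transforms of a copy (summed projections visually accumulate mass
#' at vertical structures such as pillar sides, which in a 2D analysis
#' can be mistaken for binding).
#'
#' @param field a `prob_field`.
#' @param surface the matching `surface_graph`.
#' @param scale `"linear"`, `"log"` (log10 of mass plus a tenth of the
#'   smallest positive mass) or `"sqrt"`.
#' @return Matrix (rows = y, columns = x) of class `zprojection` with
#'   attributes `scale` and `iteration`.
#' @export
zproject <- function(field, surface, scale = c("linear", "log", "sqrt")) {
  scale <- match.arg(scale)
  stopifnot(inherits(field, "prob_field"), inherits(surface, "surface_graph"))
  if (!same_surface(field$surface_signature, surface_signature(surface))) {
    stop_contract("field belongs to a different surface")
  }
  vs <- surface$volume_shape
  img <- matrix(0, vs[2L], vs[1L])
  cc <- surface$coords
  agg <- rowsum(field$mass, cc[, 1L] * as.double(vs[2L]) + cc[, 2L])
  key <- as.numeric(rownames(agg))
  img[cbind(key %% vs[2L] + 1L, key %/% vs[2L] + 1L)] <- agg[, 1L]
  img <- switch(scale,
                linear = img,
                log = {
                  eps <- min(img[img > 0]) / 10
                  log10(img + eps)
                },
                sqrt = sqrt(img))
  structure(img, class = c("zprojection", "matrix", "array"),
            scale = scale, iteration = field$iteration)
}

#' @export
plot.zprojection <- function(x, ...) {
  m <- t(unclass(x))[, rev(seq_len(nrow(x))), drop = FALSE]
  image(m, col = hcl.colors(64, "inferno"), useRaster = TRUE, axes = FALSE,
        ...)
  invisible(x)
}

#' Write a Z-projection
#'
#' CSV keeps exact values; TIFF output is a min-max normalized 32-bit
#' display copy.
#'
#' @param proj a `zprojection`.
#' @param path output file; format chosen by extension.
#' @export
write_projection <- function(proj, path) {
  ext <- tolower(tools::file_ext(path))
  m <- unclass(proj)
  if (ext %in% c("tif", "tiff")) {
    rng <- range(m)
    disp <- if (diff(rng) > 0) (m - rng[1L]) / diff(rng) else m * 0
    tiff::writeTIFF(disp, path, bits.per.sample = 32L)
  } else {
    write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a sparse per-node field table
#'
#' Columns x, y, z, mass; only nodes with positive mass are written.
#'
#' @param field a `prob_field`.
#' @param surface the matching surface.
#' @param path output CSV.
#' @export
write_field_csv <- function(field, surface, path) {
  keep <- field$mass > 0
  df <- data.frame(surface$coords[keep, , drop = FALSE],
                   mass = field$mass[keep])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write per-node distance maps
#'
#' Columns x, y, z, d2, d3, dswsd (unreachable nodes as `Inf`).
#'
#' @param maps a `distance_maps`.
#' @param surface the matching surface.
#' @param path output CSV.
#' @export
write_distance_csv <- function(maps, surface, path) {
  df <- data.frame(surface$coords, d2 = maps$d2, d3 = maps$d3,
                   dswsd = maps$dswsd)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an MSD series or D_rel curve as CSV
#' @param series an `msd_series` or `drel_curve`.
#' @param path output CSV.
#' @export
write_series_csv <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Write sampled tracks as CSV
#'
#' Columns track_id, iteration, x, y, z.
#'
#' @param tracks a `track_set`.
#' @param surface the surface the tracks live on.
#' @param path output CSV.
#' @export
write_tracks_csv <- function(tracks, surface, path) {
  df <- track_coords(tracks, surface)
  names(df)[1L] <- "track_id"
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Run configuration and pipeline.

#' Read a flat key=value run configuration
#'
#' Lines of `key = value`; blank lines and `#` comments are ignored.
#' Values that parse as numbers are converted; comma-separated values
#' become vectors.
#'
#' @param path configuration file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop_invalid_spec("bad config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}

#' Run the full build / propagate / measure / compare pipeline
#'
#' Builds (or takes) a surface, computes the three distance maps from
#' the start node, propagates the lazy walk, repeats the run on a flat
#' reference of the same planar extent, and writes MSD, D_rel,
#' distance-map and projection outputs plus a JSON manifest with MD5
#' checksums of every file.  Deterministic configurations therefore
#' reproduce their manifests exactly.
#'
#' @param config named list (or path to a key=value file readable by
#'   [read_run_config()]) with entries `fixture` (fixture name) or
#'   `builder` + builder parameters, optional `start`, `n_iterations`,
#'   `record_every`, `out_dir`.
#' @return A result bundle (surfaces, courses, D_rel curve, file list),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  out_dir <- config$out_dir %||% stop_invalid_spec("config needs out_dir")
  n_iter <- as.integer(config$n_iterations %||% 100L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$fixture)) {
    fx <- generate_fixture(config$fixture, config$overrides %||% list())
    surface <- fx$surface
    start <- config$start %||% fx$start
  } else if (!is.null(config$builder)) {
    surface <- switch(config$builder,
      flat = build_flat(config$width, config$height),
      ridges = build_ridges(config$volume_shape, config$ridge_height,
                            config$ridge_width, config$spacing),
      pillars = build_pillars(config$volume_shape, config$base %||% 5L,
                              config$pillar_height %||% 15L,
                              config$grid_spacing %||% 12L),
      height_map = build_from_height_map(read_height_map(config$height_map)),
      stop_invalid_spec("unknown builder in config: ", config$builder))
    start <- config$start %||%
      stop_invalid_spec("config needs a start node for builder runs")
  } else {
    stop_invalid_spec("config needs either fixture or builder")
  }
  start <- as.integer(start)

  rec <- config$record_every %||% max(1L, n_iter %/% 4L)
  snap_iters <- unique(c(seq.int(rec, n_iter, by = rec), n_iter))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(paste0("stage '", name, "' failed: ",
                                 conditionMessage(e)),
                          class = c("memtopo_stage_error", "memtopo_error")))
    })
  }
  course <- stage("simulate",
                  simulate_diffusion(surface, start, n_iter,
                                     record = snap_iters))
  vs <- surface$volume_shape
  flat <- stage("baseline", build_flat(vs[1L], vs[2L]))
  fstart <- c(start[1L], start[2L], 0L)
  fcourse <- stage("baseline", simulate_diffusion(flat, fstart, n_iter))
  dr <- stage("analyze", drel(course$msd, fcourse$msd))

  files <- character(0)
  wr <- function(fname, writer) {
    p <- file.path(out_dir, fname)
    writer(p)
    files <<- c(files, p)
    p
  }
  stage("report", {
    wr("surface.txt", function(p) write_surface(surface, p))
    wr("msd.csv", function(p) write_series_csv(course$msd, p))
    wr("msd_flat.csv", function(p) write_series_csv(fcourse$msd, p))
    wr("drel.csv", function(p) write_series_csv(dr, p))
    wr("distances.csv", function(p) write_distance_csv(course$maps, surface, p))
    last <- course$snapshots[[length(course$snapshots)]]
    wr("field_final.csv", function(p) write_field_csv(last, surface, p))
    wr("projection_final.csv", function(p)
      write_projection(zproject(last, surface), p))
  })

  manifest <- list(
    package = "memtopo",
    version = as.character(utils::packageVersion("memtopo")),
    config = config,
    start = start,
    n_iterations = n_iter,
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       row.names = NULL))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(surface = surface, course = course, baseline = fcourse,
                 drel = dr, files = c(files, manifest_path),
                 manifest = manifest))
}
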