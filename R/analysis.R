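# From probability fields and distance maps to MSD(t), diffusion
# coefficients and D_rel, the diffusion rate relative to a flat
# surface.  D_rel is a per-iteration MSD ratio (not a ratio of fitted
# slopes) so that its transient features -- the superdiffusive peak of
# a shortcut, the slow fall of confined 2D measurements -- stay
# visible as functions of time.

#' Construct an MSD series
#'
#' @param iterations integer vector of iteration indices.
#' @param msd_2d,msd_3d,msd_swsd population mean squared displacement
#'   per iteration (node^2) for each metric.
#' @param provenance free-form provenance list stored as an attribute.
#' @return A data frame of class `msd_series`.
#' @export
msd_series <- function(iterations, msd_2d, msd_3d, msd_swsd,
                       provenance = list()) {
  out <- data.frame(iteration = as.integer(iterations), msd_2d = msd_2d,
                    msd_3d = msd_3d, msd_swsd = msd_swsd)
  attr(out, "provenance") <- provenance
  class(out) <- c("msd_series", "data.frame")
  out
}

metric_col <- function(metric = c("2d", "3d", "swsd"), prefix) {
  metric <- match.arg(metric)
  paste0(prefix, metric)
}

#' Population MSD from field snapshots
#'
#' For every snapshot, the MSD under a metric is the probability-
#' weighted mean of the squared distance from the start node:
#' `sum(mass * d^2)` over all surface nodes.
#'
#' @param fields list of `prob_field` snapshots (as returned by
#'   [propagate()]).
#' @param maps [distance_maps()] computed from the same surface and
#'   start node.
#' @return An [msd_series] with one row per snapshot.
#' @export
population_msd <- function(fields, maps) {
  stopifnot(inherits(maps, "distance_maps"))
  if (inherits(fields, "prob_field")) fields <- list(fields)
  for (f in fields) {
    if (!same_surface(f$surface_signature, maps$surface_signature) ||
        f$start_index != maps$start_index) {
      stop_contract("fields and maps have different provenance")
    }
  }
  gsq <- ifelse(is.finite(maps$dswsd), maps$dswsd, 0)^2
  its <- vapply(fields, function(f) f$iteration, integer(1))
  o <- order(its)
  fields <- fields[o]
  msd_series(
    iterations = its[o],
    msd_2d = vapply(fields, function(f) sum(f$mass * maps$d2^2), 0),
    msd_3d = vapply(fields, function(f) sum(f$mass * maps$d3^2), 0),
    msd_swsd = vapply(fields, function(f) sum(f$mass * gsq), 0),
    provenance = list(surface = maps$surface_signature, start = maps$start))
}

#' Relative diffusion versus a flat baseline
#'
#' `D_rel(t) = MSD_metric(t) on the test surface / MSD of the same
#' metric at the same iteration on a flat reference surface`.  A value
#' of 1 indicates apparently Brownian spread; values above/below 1 are
#' apparent super-/subdiffusion.  Iteration 0 is excluded (the ratio is
#' undefined there).
#'
#' @param test,baseline_flat [msd_series] objects; the baseline grid
#'   must contain every iteration of the test grid, and the baseline
#'   must come from a flat surface large enough that boundary effects
#'   are negligible at the largest iteration compared.
#' @return A data frame of class `drel_curve` with columns `iteration`,
#'   `drel_2d`, `drel_3d`, `drel_swsd`.
#' @export
drel <- function(test, baseline_flat) {
  stopifnot(inherits(test, "msd_series"), inherits(baseline_flat, "msd_series"))
  tt <- test[test$iteration > 0L, ]
  bb <- baseline_flat[baseline_flat$iteration > 0L, ]
  at <- match(tt$iteration, bb$iteration)
  if (anyNA(at)) {
    stop_contract("baseline lacks iterations present in the test series")
  }
  bb <- bb[at, ]
  out <- data.frame(iteration = tt$iteration,
                    drel_2d = tt$msd_2d / bb$msd_2d,
                    drel_3d = tt$msd_3d / bb$msd_3d,
                    drel_swsd = tt$msd_swsd / bb$msd_swsd)
  attr(out, "provenance") <- list(test = attr(test, "provenance"),
                                  baseline = attr(baseline_flat, "provenance"))
  class(out) <- c("drel_curve", "data.frame")
  out
}

#' Long-time plateau of a D_rel curve
#'
#' D_rel curves on periodically structured surfaces approach their
#' asymptote like `a + b/t` (the residual variance of the periodic
#' height profile decays as 1/t relative to the linearly growing MSD).
#' The plateau is therefore estimated by an ordinary least-squares fit
#' of `drel ~ 1/t` over a late-time window and reported as the
#' intercept, i.e. the extrapolated t -> infinity limit.
#'
#' @param curve a `drel_curve`.
#' @param metric `"2d"`, `"3d"` or `"swsd"`.
#' @param window iteration range used for the fit; defaults to the last
#'   half of the curve.
#' @return The estimated plateau value (dimensionless).
#' @export
drel_plateau <- function(curve, metric = c("2d", "3d", "swsd"),
                         window = NULL) {
  stopifnot(inherits(curve, "drel_curve"))
  col <- metric_col(metric, "drel_")
  if (is.null(window)) {
    window <- c(ceiling(max(curve$iteration) / 2), max(curve$iteration))
  }
  sub <- curve[curve$iteration >= window[1L] & curve$iteration <= window[2L], ]
  if (nrow(sub) < 2L) stop_contract("plateau window holds fewer than 2 points")
  unname(coef(lm(sub[[col]] ~ I(1 / sub$iteration)))[1L])
}

#' Fit a diffusion coefficient to an MSD series
#'
#' Ordinary least squares of MSD versus iteration over a window (the
#' "least-squares tangent"), intercept free.  For Brownian spread on a
#' flat surface measured with the 2D metric the slope is 0.5 node^2 per
#' iteration (the lazy walk moves with probability 0.5 and every move
#' has squared length 1).
#'
#' @param series an [msd_series].
#' @param window iteration range `c(from, to)`; defaults to the last
#'   half of the series.
#' @param metric which MSD column to fit.
#' @return A `diffusion_fit` with the fitted `slope` (the diffusion
#'   coefficient in node^2/iteration), `intercept`, `r_squared`, the
#'   window and residual summary.
#' @export
fit_diffusion <- function(series, window = NULL,
                          metric = c("2d", "3d", "swsd")) {
  stopifnot(inherits(series, "msd_series"))
  col <- metric_col(metric, "msd_")
  if (is.null(window)) {
    window <- c(ceiling(max(series$iteration) / 2), max(series$iteration))
  }
  sub <- series[series$iteration >= window[1L] &
                  series$iteration <= window[2L], ]
  if (nrow(sub) < 2L) stop_contract("fit window holds fewer than 2 points")
  fit <- lm(sub[[col]] ~ sub$iteration)
  res <- residuals(fit)
  sst <- sum((sub[[col]] - mean(sub[[col]]))^2)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = if (sst > 0) 1 - sum(res^2) / sst else 1,
                 window = window, metric = col,
                 residual_summary = summary(res)),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> %s: slope %.6g node^2/iteration (R^2 %.6f) over t in [%d, %d]\n",
              x$metric, x$slope, x$r_squared, x$window[1L], x$window[2L]))
  invisible(x)
}

#' @export
coef.diffusion_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Label apparent super-, normal and subdiffusion along a D_rel curve
#'
#' Labels each iteration `super` where D_rel exceeds `1 + tolerance`,
#' `sub` where it falls below `1 - tolerance`, and `normal` otherwise,
#' and reports the landmarks of a shortcut-type curve: the iteration of
#' the maximum (peak apparent superdiffusion), of the minimum, and the
#' first iteration after the maximum at which the curve returns to or
#' below 1 (the crossing back to apparently Brownian spread).  Ties are
#' broken towards the earliest iteration.
#'
#' @param curve a `drel_curve`.
#' @param metric `"2d"`, `"3d"` or `"swsd"`.
#' @param tolerance half-width of the band around 1 treated as normal.
#' @return An `anomaly_classification` list with `labels` (data frame),
#'   `argmax`, `max`, `argmin`, `min` and `crossing`.
#' @export
classify_anomaly <- function(curve, metric = c("swsd", "2d", "3d"),
                             tolerance = 0.01) {
  stopifnot(inherits(curve, "drel_curve"))
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop_invalid_spec("tolerance must be positive")
  }
  col <- metric_col(match.arg(metric), "drel_")
  v <- curve[[col]]
  it <- curve$iteration
  labels <- ifelse(v > 1 + tolerance, "super",
                   ifelse(v < 1 - tolerance, "sub", "normal"))
  imax <- which.max(v)   # earliest maximum on ties
  imin <- which.min(v)
  after <- which(seq_along(v) > imax & v <= 1)
  crossing <- if (length(after)) it[after[1L]] else NA_integer_
  structure(list(labels = data.frame(iteration = it, drel = v,
                                     label = labels),
                 argmax = it[imax], max = v[imax],
                 argmin = it[imin], min = v[imin],
                 crossing = crossing, metric = col, tolerance = tolerance),
            class = "anomaly_classification")
}

#' @export
print.anomaly_classification <- function(x, ...) {
  cat(sprintf("<anomaly_classification> %s (tolerance %.3g)\n", x$metric,
              x$tolerance))
  cat(sprintf("  peak %.4f at iteration %d | min %.4f at iteration %d\n",
              x$max, x$argmax, x$min, x$argmin))
  if (!is.na(x$crossing)) {
    cat("  first return to <= 1 after the peak: iteration", x$crossing, "\n")
  }
  tb <- table(x$labels$label)
  cat("  labels:", paste(names(tb), tb, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Occupied-node count of field snapshots
#'
#' Number of nodes carrying more than `threshold` probability mass in
#' each snapshot.  On surfaces without absorbing boundaries the count
#' is non-decreasing with iteration; shortcut defects let it grow
#' faster than on the intact surface.
#'
#' @param fields list of `prob_field` snapshots.
#' @param threshold mass threshold (default 0: the support size).
#' @return Data frame with `iteration` and `occupied`.
#' @export
occupied_node_count <- function(fields, threshold = 0) {
  if (inherits(fields, "prob_field")) fields <- list(fields)
  if (threshold < 0) stop_invalid_spec("threshold must be >= 0")
  data.frame(
    iteration = vapply(fields, function(f) f$iteration, integer(1)),
    occupied = vapply(fields, function(f) sum(f$mass > threshold), 0))
}

#' Probability mass by distance shell
#'
#' Sums the probability mass of a field over integer distance shells
#' (`floor(d)` binning; SWSD distances are integers already).  The
#' shell masses add up to the total mass of the field.
#'
#' @param field a `prob_field`.
#' @param maps matching [distance_maps()].
#' @param metric `"2d"`, `"3d"` or `"swsd"`.
#' @return Data frame with `shell` (integer distance) and `mass`.
#' @export
probability_by_distance <- function(field, maps,
                                    metric = c("swsd", "2d", "3d")) {
  stopifnot(inherits(field, "prob_field"), inherits(maps, "distance_maps"))
  if (!same_surface(field$surface_signature, maps$surface_signature) ||
      field$start_index != maps$start_index) {
    stop_contract("field and maps have different provenance")
  }
  metric <- match.arg(metric)
  d <- switch(metric, "2d" = maps$d2, "3d" = maps$d3, "swsd" = maps$dswsd)
  keep <- is.finite(d)
  shell <- floor(d[keep])
  agg <- rowsum(field$mass[keep], shell)
  out <- data.frame(shell = as.integer(rownames(agg)), mass = agg[, 1L])
  # shells from 0 up to the outermost occupied one (empty shells kept)
  out <- out[out$shell <= max(out$shell[out$mass > 0]), ]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Plotting.

#' @export
plot.msd_series <- function(x, log = "", ...) {
  sub <- x[x$iteration > 0L, ]
  matplot(sub$iteration, as.matrix(sub[, c("msd_2d", "msd_3d", "msd_swsd")]),
          type = "l", lty = 1, col = c("#1b9e77", "#d95f02", "#7570b3"),
          xlab = "iteration", ylab = expression(MSD ~ (node^2)), log = log,
          ...)
  legend("topleft", legend = c("2D", "3D", "SWSD"), lty = 1, bty = "n",
         col = c("#1b9e77", "#d95f02", "#7570b3"))
  invisible(x)
}

#' @export
plot.drel_curve <- function(x, ...) {
  matplot(x$iteration, as.matrix(x[, c("drel_2d", "drel_3d", "drel_swsd")]),
          type = "l", lty = 1, col = c("#1b9e77", "#d95f02", "#7570b3"),
          xlab = "iteration", ylab = expression(D[rel]), ...)
  abline(h = 1, lty = 3)
  legend("bottomleft", legend = c("2D", "3D", "SWSD"), lty = 1, bty = "n",
         col = c("#1b9e77", "#d95f02", "#7570b3"))
  invisible(x)
}
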