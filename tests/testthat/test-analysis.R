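test_that("population MSD matches hand-evaluated one-step fields", {
  flat <- build_flat(41, 41)
  start <- c(20, 20, 0)
  maps <- distance_maps(flat, start)
  fields <- propagate(flat, start, 1)
  msd <- population_msd(fields, maps)
  expect_equal(msd$iteration, 0:1)
  expect_equal(msd$msd_2d, c(0, 0.5))     # 4 * 0.125 * 1^2
  expect_equal(msd$msd_3d, c(0, 0.5))
  expect_equal(msd$msd_swsd, c(0, 0.5))   # all one-step SWSDs are 1
  # the streaming course agrees with the snapshot route
  course <- simulate_diffusion(flat, start, 40, maps = maps, record = c(7, 40))
  again <- population_msd(course$snapshots, maps)
  expect_equal(again$msd_2d, course$msd$msd_2d[c(8, 41)])
  expect_equal(again$msd_swsd, course$msd$msd_swsd[c(8, 41)])
})

test_that("MSD series keep the metric ordering and start at zero", {
  s <- build_pillars(c(60, 60, 17), 5, 15, 12)
  course <- simulate_diffusion(s, c(30, 30, 0), 150)
  m <- course$msd
  expect_equal(m$msd_2d[1], 0)
  expect_true(all(m$msd_swsd >= m$msd_3d - 1e-12))
  expect_true(all(m$msd_3d >= m$msd_2d - 1e-12))
})

test_that("D_rel of a series against itself is identically one", {
  flat <- build_flat(41, 41)
  course <- simulate_diffusion(flat, c(20, 20, 0), 50)
  dr <- drel(course$msd, course$msd)
  expect_equal(dr$iteration, 1:50)
  expect_equal(dr$drel_2d, rep(1, 50))
  expect_equal(dr$drel_swsd, rep(1, 50))
  short <- course$msd[course$msd$iteration <= 20, ]
  class(short) <- class(course$msd)
  expect_error(drel(course$msd, short), class = "memtopo_contract_error")
})

test_that("diffusion fits recover exact slopes and flag saturation", {
  lin <- msd_series(0:100, 0.5 * (0:100), 0.5 * (0:100), 0.8 * (0:100))
  f <- fit_diffusion(lin, metric = "2d")
  expect_equal(unname(coef(f)["slope"]), 0.5)
  f2 <- fit_diffusion(lin, window = c(3, 17), metric = "swsd")
  expect_equal(f2$slope, 0.8)
  # concave (saturating) series: early slope exceeds late slope
  sat <- msd_series(0:100, 10 * (1 - exp(-(0:100) / 20)),
                    10 * (1 - exp(-(0:100) / 20)),
                    10 * (1 - exp(-(0:100) / 20)))
  early <- fit_diffusion(sat, window = c(0, 20))$slope
  late <- fit_diffusion(sat, window = c(80, 100))$slope
  expect_gt(early, late)
  expect_error(fit_diffusion(lin, window = c(40, 40)),
               class = "memtopo_contract_error")
})

test_that("anomaly classification labels bands and finds landmarks", {
  flatline <- structure(
    data.frame(iteration = 1:10, drel_2d = rep(1, 10),
               drel_3d = rep(1, 10), drel_swsd = rep(1, 10)),
    class = c("drel_curve", "data.frame"))
  cl <- classify_anomaly(flatline, "swsd")
  expect_true(all(cl$labels$label == "normal"))
  hump <- flatline
  hump$drel_swsd <- c(1, 1.02, 1.06, 1.08, 1.05, 1.01, 0.98, 0.95, 0.95, 0.96)
  cl2 <- classify_anomaly(hump, "swsd", tolerance = 0.01)
  expect_equal(cl2$argmax, 4L)
  expect_equal(cl2$crossing, 7L)   # first value <= 1 after the peak
  expect_equal(cl2$argmin, 8L)     # earliest of the tied minima
  expect_equal(cl2$labels$label[2:4], rep("super", 3))
  expect_error(classify_anomaly(hump, "swsd", tolerance = 0),
               class = "memtopo_invalid_spec")
})

test_that("occupied-node counts grow monotonically from one", {
  flat <- build_flat(41, 41)
  fields <- propagate(flat, c(20, 20, 0), 12, record = 1:12)
  occ <- occupied_node_count(fields)
  expect_equal(occ$occupied[occ$iteration == 0], 1)
  expect_equal(occ$occupied[occ$iteration == 1], 5)
  expect_true(all(diff(occ$occupied) >= 0))
})

test_that("probability-by-distance shells conserve mass", {
  flat <- build_flat(41, 41)
  maps <- distance_maps(flat, c(20, 20, 0))
  fields <- propagate(flat, c(20, 20, 0), 9, record = c(1, 9))
  h0 <- probability_by_distance(fields[[1]], maps, "swsd")
  expect_equal(h0, data.frame(shell = 0L, mass = 1))
  h1 <- probability_by_distance(fields[[2]], maps, "swsd")
  expect_equal(h1$mass, c(0.5, 0.5))
  h9 <- probability_by_distance(fields[[3]], maps, "2d")
  expect_equal(sum(h9$mass), 1)
  expect_error(probability_by_distance(fields[[2]],
                                       distance_maps(flat, c(0, 0, 0))),
               class = "memtopo_contract_error")
})

test_that("plateau extrapolation recovers a + b/t limits", {
  t <- 1:400
  curve <- structure(
    data.frame(iteration = t, drel_2d = 0.59 + 3 / t,
               drel_3d = 0.59 - 1 / t, drel_swsd = rep(1, 400)),
    class = c("drel_curve", "data.frame"))
  expect_equal(drel_plateau(curve, "2d"), 0.59, tolerance = 1e-10)
  expect_equal(drel_plateau(curve, "3d"), 0.59, tolerance = 1e-10)
  expect_equal(drel_plateau(curve, "swsd"), 1, tolerance = 1e-12)
})
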