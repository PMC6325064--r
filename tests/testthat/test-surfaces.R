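test_that("flat surfaces have the forced grid adjacency", {
  s <- build_flat(3, 3)
  expect_equal(nrow(s$coords), 9L)
  expect_equal(s$degree[node_index(s, c(1, 1, 0))], 4L)
  for (corner in list(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(2, 2, 0))) {
    expect_equal(s$degree[node_index(s, corner)], 2L)
  }
  s1 <- build_flat(1, 1)
  expect_equal(nrow(s1$coords), 1L)
  expect_equal(s1$degree, 0L)
})

test_that("large flat surface matches the closed-form edge count", {
  s <- build_flat(1024, 1024)
  expect_equal(nrow(s$coords), 1024L^2)
  # directed adjacencies of an n x n grid: 2 * 2 * n * (n-1)
  expect_equal(length(s$adj_idx), 4L * 1023L * 1024L)
  # and the same count from brute-force enumeration on a small grid
  b <- brute_adjacency(build_flat(5, 4)$coords)
  expect_equal(length(build_flat(5, 4)$adj_idx), sum(b))
})

test_that("every builder yields a symmetric, 6-connected, connected graph", {
  surfaces <- list(
    flat = build_flat(7, 5),
    ridges = build_ridges(c(26, 9, 6), 4, 4, 2),
    pillars = build_pillars(c(40, 40, 17), 5, 15, 12),
    invag = build_invaginations(c(40, 40, 6), 5, 4, 12),
    bumps = build_bumps(c(20, 20, 4), 2, 3, 3),
    hmap = build_from_height_map(matrix(c(0L, 3L, 1L, 2L, 0L, 5L), 2, 3)),
    deformed = small_deformed()
  )
  for (nm in names(surfaces)) {
    s <- surfaces[[nm]]
    A <- brute_adjacency(s$coords)
    # symmetry and 6-connectivity come from the brute-force definition;
    # the package adjacency must match it edge for edge
    for (i in seq_len(nrow(s$coords))) {
      expect_equal(sort(node_neighbors(s, i)), which(A[i, ]),
                   info = paste(nm, "node", i))
    }
    expect_true(all(s$degree >= 0L & s$degree <= 6L), info = nm)
    expect_true(memtopo:::is_connected(s), info = nm)
  }
})

test_that("ridges of height zero degenerate to the flat surface", {
  r0 <- build_ridges(c(8, 6, 3), 0, 4, 2)
  fl <- build_flat(8, 6)
  expect_identical(r0$coords, fl$coords)
  expect_identical(r0$adj_idx, fl$adj_idx)
})

test_that("folded ridges have only 4-neighbour interior nodes", {
  s <- build_ridges(c(24, 12, 6), 4, 4, 2)
  cls <- classify_nodes(s)
  # interior = nodes away from the lateral volume boundary
  cc <- s$coords
  interior <- cc[, 1L] > 0L & cc[, 1L] < 23L & cc[, 2L] > 0L & cc[, 2L] < 11L
  expect_true(all(cls$degree[interior] == 4L))
  expect_equal(unname(cls$histogram[c("5", "6")]), c(0L, 0L))
  # one period of the h4 w4 s2 pattern holds 14 nodes per row
  row0 <- cc[, 2L] == 5L & cc[, 1L] >= 4L & cc[, 1L] < 10L
  expect_equal(sum(row0), 14L)
})

test_that("deformed builders contain 3- and 5-neighbour corner nodes", {
  p <- build_pillars(c(40, 40, 17), 5, 15, 12)
  hp <- classify_nodes(p)$histogram
  expect_gt(hp[["3"]], 0L)           # external corners at the top rims
  # flat pillar tops exist at z = pillar_height
  expect_true(any(p$coords[, 3L] == 15L))
  # square (non-indented) feet carry internal five-neighbour corners
  psq <- build_pillars(c(40, 40, 17), 5, 15, 12, indent_corners = FALSE)
  expect_gt(classify_nodes(psq)$histogram[["5"]], 0L)
  # with connectors attached at the higher pixel, sunken features hang
  # their walls outside the hole: pits contribute 3-neighbour corners
  inv <- build_invaginations(c(40, 40, 6), 5, 4, 12)
  hi <- classify_nodes(inv)$histogram
  expect_gt(hi[["3"]], 4L)           # more than the volume corners alone
  expect_true(any(inv$coords[, 3L] == 0L))     # pit floors reach z = 0
  d <- small_deformed()
  hd <- classify_nodes(d)$histogram
  expect_true(all(hd[c("3", "4", "5")] > 0L))
})

test_that("a lone pillar matches the isolated-pillar degree signature", {
  # spacing so large that a single pillar fits: the degree histogram of
  # the raised part equals that of one isolated pillar on a larger plate
  hist_raised <- function(s) {
    raised <- s$coords[, 3L] > 0L
    tabulate(s$degree[raised] + 1L, nbins = 7L)
  }
  one <- build_pillars(c(24, 24, 17), 5, 15, 100)
  also_one <- build_pillars(c(36, 36, 17), 5, 15, 200)
  expect_equal(sum(one$heights == 15L), 21L)   # 5x5 base, corners indented
  expect_equal(hist_raised(one), hist_raised(also_one))
  # external corners at the pillar top rim have 3 neighbours
  top_rim <- one$coords[, 3L] == 15L
  expect_true(any(one$degree[top_rim] == 3L))
})

test_that("height-map conversion inserts face-connecting vertical runs", {
  # a 2 x 1 map with heights 0 and 3: pixel nodes plus a vertical run
  # at the higher pixel covering z = 0..2
  s <- build_from_height_map(matrix(c(0L, 3L), nrow = 1))
  expect_equal(nrow(s$coords), 5L)
  expect_true(all(c(node_index(s, c(0, 0, 0)), node_index(s, c(1, 0, 3)),
                    node_index(s, c(1, 0, 0)), node_index(s, c(1, 0, 1)),
                    node_index(s, c(1, 0, 2))) > 0L))
  expect_true(memtopo:::is_connected(s))
  # constant map equals the flat builder at that level
  c2 <- build_from_height_map(matrix(2L, 3, 4))
  expect_equal(c2$coords[, 3L], rep(2L, 12L))
  expect_equal(length(c2$adj_idx), length(build_flat(4, 3)$adj_idx))
  expect_error(build_from_height_map(matrix(-1L, 2, 2)),
               class = "memtopo_invalid_spec")
})

test_that("slot and notch defects reshape the ridge as described", {
  base <- build_ridges(c(63, 31, 9), 7, 3, 9)
  h0 <- classify_nodes(base)$histogram
  expect_equal(unname(h0[["5"]]), 0L)
  slot <- insert_defect(base, "slot", c(25, 15))   # 25 %% 12 == 1: on-ridge
  hs <- classify_nodes(slot)$histogram
  expect_equal(unname(hs[["5"]]), 4L)              # slot base corners
  expect_true(memtopo:::is_connected(slot))
  # the passage through the base exists
  d <- geodesic_transform(slot, c(20, 15, 0))
  expect_equal(d[node_index(slot, c(30, 15, 0))], 10)  # straight through
  notch <- insert_defect(base, "notch", c(25, 15), depth = 1)
  expect_equal(max(notch$heights[16, 25:27]), 6L)
  expect_identical(insert_defect(base, "none", c(25, 15))$coords, base$coords)
  expect_error(insert_defect(base, "slot", c(20, 15)),   # off-ridge
               class = "memtopo_invalid_spec")
})

test_that("quadrant composites join four topographies into one surface", {
  quads <- list(list(builder = "flat"),
                list(builder = "ridges",
                     params = list(ridge_height = 4L, ridge_width = 4L,
                                   spacing = 2L)),
                list(builder = "invaginations",
                     params = list(base = 5L, depth = 4L, grid_spacing = 12L)),
                list(builder = "pillars",
                     params = list(base = 5L, pillar_height = 8L,
                                   grid_spacing = 12L)))
  s <- build_quadrant_composite(c(64, 64, 14), quads, level = 4L)
  expect_true(memtopo:::is_connected(s))
  expect_gt(classify_nodes(s)$histogram[["5"]], 0L)  # invagination corners
  # all-flat composite equals one flat sheet
  allflat <- build_quadrant_composite(
    c(16, 16, 2), replicate(4, list(builder = "flat"), simplify = FALSE),
    level = 0L)
  expect_equal(nrow(allflat$coords), 256L)
  expect_equal(length(allflat$adj_idx), length(build_flat(16, 16)$adj_idx))
  # node count: quadrant node sums (shared boundary lives on the grid,
  # no duplication by construction)
  expect_error(build_quadrant_composite(c(15, 16, 2), quads),
               class = "memtopo_invalid_spec")
})

test_that("builder preconditions reject impossible geometry", {
  expect_error(build_flat(0, 3), class = "memtopo_invalid_spec")
  expect_error(build_ridges(c(20, 10, 4), 5, 4, 2),
               class = "memtopo_invalid_spec")   # height exceeds volume
  expect_error(build_ridges(c(20, 10, 6), 4, 2, 2),
               class = "memtopo_invalid_spec")   # degenerate thin ridge
  expect_error(build_pillars(c(40, 40, 17), 5, 15, 3),
               class = "memtopo_invalid_spec")   # overlapping pillars
  expect_error(build_invaginations(c(40, 40, 8), 5, 9, 12, level = 5),
               class = "memtopo_invalid_spec")   # pit deeper than floor
})
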