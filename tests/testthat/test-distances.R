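test_that("Euclidean distances follow the textbook formulas", {
  expect_equal(euclidean_2d(c(0, 0, 2), c(3, 4, 9)), 5)
  expect_equal(euclidean_2d(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(euclidean_2d(c(0, 0, 0), c(0, 0, 9)), 0)  # height invisible
  expect_equal(euclidean_3d(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(euclidean_3d(c(0, 0, 0), c(0, 0, 9)), 9)
  expect_equal(euclidean_3d(c(1, 2, 2), c(4, 6, 14)), 13)
})

test_that("the SWSD is the city-block geodesic on a flat surface", {
  flat <- build_flat(10, 10)
  d <- geodesic_transform(flat, c(0, 0, 0))
  expect_equal(d[node_index(flat, c(3, 4, 0))], 7)
  expect_equal(d[node_index(flat, c(1, 0, 0))], 1)
  cc <- flat$coords
  expect_equal(d, abs(cc[, 1L] - 0) + abs(cc[, 2L] - 0))
})

test_that("the SWSD climbs over ridges", {
  # nodes on opposite sides of a full-length ridge (width 3, height 4):
  # the only route is over the top, planar separation + 2 * height
  s <- build_ridges(c(13, 7, 6), 4, 3, 5, phase = 4L)  # ridge at x = 4..6
  d <- geodesic_transform(s, c(3, 3, 0))
  expect_equal(d[node_index(s, c(7, 3, 0))], 4 + 2 * 4)
  expect_equal(d[node_index(s, c(5, 3, 4))], 1 + 4 + 1)  # up and across
})

test_that("the wave-front transform agrees with a graph-search oracle", {
  surfaces <- list(
    build_flat(9, 9),
    build_ridges(c(15, 5, 6), 4, 3, 3),
    small_deformed(),
    insert_defect(build_ridges(c(9, 5, 5), 3, 3, 3), "slot", c(6, 2)),
    build_from_height_map(matrix(c(0L, 2L, 5L, 1L, 0L, 3L, 2L, 2L), 2, 4))
  )
  for (s in surfaces) {
    n <- nrow(s$coords)
    expect_lte(n, 200L)
    ref <- igraph_distances(s)
    for (i0 in unique(c(1L, n %/% 2L, n))) {
      expect_equal(geodesic_transform(s, i0), unname(ref[i0, ]))
    }
  }
})

test_that("per-node distances obey dswsd >= d3 >= d2 >= 0 with zero at start", {
  surfaces <- list(build_flat(12, 12),
                   build_ridges(c(26, 9, 6), 4, 4, 2),
                   build_pillars(c(40, 40, 17), 5, 15, 12),
                   small_deformed())
  for (s in surfaces) {
    i0 <- nrow(s$coords) %/% 2L
    m <- distance_maps(s, i0)
    expect_true(all(m$d2 >= 0))
    expect_true(all(m$d3 >= m$d2))
    expect_true(all(m$dswsd >= m$d3 - 1e-12))
    expect_equal(m$d2[i0], 0)
    expect_equal(m$d3[i0], 0)
    expect_equal(m$dswsd[i0], 0)
    # local Lipschitz bound along adjacency
    for (i in seq(1L, nrow(s$coords), by = 7L)) {
      nb <- node_neighbors(s, i)
      expect_true(all(abs(m$dswsd[nb] - m$dswsd[i]) <= 1))
    }
  }
})

test_that("the SWSD unfolds a folded ridge surface exactly", {
  s <- build_ridges(c(26, 9, 6), 4, 4, 2)
  u <- unroll_ridges(s)
  cc <- s$coords
  for (i0 in c(1L, 57L, 200L)) {
    d <- geodesic_transform(s, i0)
    expect_equal(d, abs(u - u[i0]) + abs(cc[, 2L] - cc[i0, 2L]))
  }
})

test_that("the transform is independent of neighbour visiting order", {
  s <- build_pillars(c(30, 30, 17), 5, 15, 12)
  ref <- geodesic_transform(s, 17L)
  # shuffle every adjacency list in place and re-run the wave front
  set.seed(1)
  idx <- s$adj_idx
  for (i in seq_len(nrow(s$coords))) {
    p <- s$adj_ptr
    if (p[i + 1L] > p[i]) {
      sl <- (p[i] + 1L):p[i + 1L]
      idx[sl] <- idx[sample(sl)]
    }
  }
  d2 <- memtopo:::.bfs_csr(s$adj_ptr, idx - 1L, 16L)
  expect_equal(as.numeric(d2), ref)
})

test_that("unreachable nodes carry an infinite sentinel", {
  s <- build_from_nodes(rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0)))
  d <- geodesic_transform(s, c(0, 0, 0))
  expect_equal(d, c(0, 1, Inf))
  expect_error(geodesic_transform(s, c(2, 0, 0)),
               class = "memtopo_invalid_spec")
})
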