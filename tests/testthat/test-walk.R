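test_that("single steps place mass exactly as the lazy walk dictates", {
  # two-node graph: (1, 0) -> (0.5, 0.5)
  two <- build_from_nodes(rbind(c(0, 0, 0), c(1, 0, 0)))
  f <- walk_step(init_field(two, 1L), walk_operator(two))
  expect_equal(f$mass, c(0.5, 0.5))
  # flat interior node: 0.5 self, 0.125 to each of four neighbours
  flat <- build_flat(9, 9)
  f1 <- walk_step(init_field(flat, c(4, 4, 0)), walk_operator(flat))
  expect_equal(f1$mass[node_index(flat, c(4, 4, 0))], 0.5)
  for (nb in list(c(3, 4, 0), c(5, 4, 0), c(4, 3, 0), c(4, 5, 0))) {
    expect_equal(f1$mass[node_index(flat, nb)], 0.125)
  }
  expect_equal(sum(f1$mass), 1)
  # 5-node star, mass on the hub: after two steps the hub holds
  # 0.5 * 0.5 + 4 * (0.125 * 0.5) = 0.5 (leaves have degree 1)
  st <- star5()
  op <- walk_operator(st)
  f2 <- walk_step(walk_step(init_field(st, c(1, 1, 0)), op), op)
  expect_equal(f2$mass[node_index(st, c(1, 1, 0))], 0.5)
  # isolated node keeps all mass (stochastic operator on degree 0)
  lone <- build_flat(1, 1)
  fl <- walk_step(init_field(lone, 1L), walk_operator(lone))
  expect_equal(fl$mass, 1)
})

test_that("mass is conserved and non-negative over long runs", {
  s <- small_deformed()
  course <- simulate_diffusion(s, c(2, 2, 2), 2000)
  expect_lt(max(abs(course$mass - 1)), 1e-9)
  expect_true(all(vapply(propagate(s, c(2, 2, 2), 100),
                         function(f) all(f$mass >= 0), TRUE)))
})

test_that("propagation equals the dense operator power on small graphs", {
  for (s in list(build_flat(7, 7), small_deformed(),
                 insert_defect(build_ridges(c(9, 4, 5), 3, 3, 3), "slot",
                               c(6, 2)))) {
    D <- brute_operator(s$coords)
    i0 <- which.min(abs(s$coords[, 1L] - 3) + abs(s$coords[, 2L] - 2) +
                      s$coords[, 3L])
    v <- numeric(nrow(s$coords)); v[i0] <- 1
    for (t in 1:25) v <- D %*% v
    got <- propagate(s, i0, 25)
    expect_lt(max(abs(got[[length(got)]]$mass - as.numeric(v))), 1e-10)
  }
})

test_that("one-step support and locality on a flat surface", {
  flat <- build_flat(61, 61)
  fs <- propagate(flat, c(30, 30, 0), 5, record = 1:5)
  # t = 1: exactly 5 nonzero nodes
  expect_equal(sum(fs[[2]]$mass > 0), 5L)
  # support within the graph ball of radius t
  maps <- distance_maps(flat, c(30, 30, 0))
  for (f in fs[-1]) {
    expect_true(all(maps$dswsd[f$mass > 0] <= f$iteration))
  }
})

test_that("expanding-region propagation matches the full-graph result", {
  s <- build_ridges(c(48, 301, 6), 4, 4, 2)
  start <- c(22, 150, 0)
  a <- propagate(s, start, 200, record = c(57, 200), restrict = TRUE)
  b <- propagate(s, start, 200, record = c(57, 200), restrict = FALSE)
  for (k in seq_along(a)) {
    expect_lt(max(abs(a[[k]]$mass - b[[k]]$mass)), 1e-12)
  }
})

test_that("fields inherit every mirror symmetry of the surface", {
  flat <- build_flat(41, 41)
  f <- propagate(flat, c(20, 20, 0), 60)[[2]]
  cc <- flat$coords
  m <- matrix(0, 41, 41)
  m[cbind(cc[, 1L] + 1L, cc[, 2L] + 1L)] <- f$mass
  expect_lt(max(abs(m - t(m))), 1e-12)                 # diagonal mirror
  expect_lt(max(abs(m - m[41:1, ])), 1e-12)            # x mirror
  expect_lt(max(abs(m - m[, 41:1])), 1e-12)            # y mirror
})

test_that("the field converges to the dominant eigenvector of the operator", {
  s <- small_deformed()   # irregular degrees: 3, 4 and 5 present
  D <- brute_operator(s$coords)
  ev <- eigen(D)
  v1 <- Re(ev$vectors[, which.max(Re(ev$values))])
  v1 <- v1 / sum(v1)
  long <- propagate(s, 1L, 4000)
  got <- long[[length(long)]]$mass
  expect_lt(max(abs(got - v1)), 1e-9)
  # for this operator the stationary mass is degree-proportional
  expect_lt(max(abs(v1 - s$degree / sum(s$degree))), 1e-12)
})

test_that("track sampling is reproducible and respects adjacency", {
  s <- build_ridges(c(26, 9, 6), 4, 4, 2)
  a <- sample_tracks(s, c(4, 4, 0), 40, 60, seed = 7)
  b <- sample_tracks(s, c(4, 4, 0), 40, 60, seed = 7)
  expect_identical(a$nodes, b$nodes)
  c_ <- sample_tracks(s, c(4, 4, 0), 40, 60, seed = 8)
  expect_false(identical(a$nodes, c_$nodes))
  # consecutive recorded positions (cadence 1) are identical or adjacent
  for (tr in 1:10) {
    path <- a$nodes[, tr]
    for (k in seq_len(length(path) - 1L)) {
      expect_true(path[k + 1L] == path[k] ||
                    path[k + 1L] %in% node_neighbors(s, path[k]))
    }
  }
})

test_that("single tracks are highly variable around the ensemble mean", {
  flat <- build_flat(101, 101)
  maps <- distance_maps(flat, c(50, 50, 0))
  ts <- sample_tracks(flat, c(50, 50, 0), 16, 400, seed = 3,
                      record_every = 400)
  d2 <- maps$d2[ts$nodes[nrow(ts$nodes), ]]^2
  # per-track squared displacements scatter widely (coefficient of
  # variation of order 1 for Brownian endpoints)
  expect_gt(stats::sd(d2) / mean(d2), 0.5)
})

test_that("field/operator provenance mismatches are contract errors", {
  flat <- build_flat(5, 5)
  other <- build_flat(6, 6)
  expect_error(walk_step(init_field(flat, 1L), walk_operator(other)),
               class = "memtopo_contract_error")
  expect_error(propagate(flat, c(9, 9, 0), 5),
               class = "memtopo_invalid_spec")
  expect_error(sample_tracks(flat, 1L, 5, 5),
               class = "memtopo_invalid_spec")  # missing seed
})
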