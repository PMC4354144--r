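test_that("dodecahedron direction set is exact and antipodally closed", {
  d <- dodecahedron_directions()
  expect_equal(nrow(d), 20)
  expect_true(all(d$weight == 0.05))
  expect_equal(sum(d$weight), 1)
  m <- direction_matrix(d)
  expect_lt(max(abs(rowSums(m^2) - 1)), 1e-9)
  # each -v also present
  for (i in seq_len(20)) {
    gap <- min(rowSums(sweep(m, 2, -m[i, ])^2))
    expect_lt(gap, 1e-18)
  }
})

test_that("spherical Voronoi weights form a probability vector", {
  tetra <- direction_set(rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)))
  expect_equal(tetra$weight, rep(0.25, 4), tolerance = 1e-12)

  u <- uniform_directions(100, seed = 3)
  expect_equal(sum(u$weight), 1, tolerance = 1e-9)
  expect_true(all(u$weight > 0))
  # regression bound for the Fibonacci lattice: cells stay within 3x of each
  # other (observed ratio ~1.1)
  expect_lt(max(u$weight) / min(u$weight), 3)
  # deterministic per seed
  expect_equal(uniform_directions(40, seed = 11)$x, uniform_directions(40, seed = 11)$x)
})

test_that("degenerate direction sets are rejected", {
  expect_error(direction_set(rbind(c(1, 0, 0), c(1, 1e-15, 0), c(0, 1, 0), c(0, 0, 1))),
               "coincident")
  expect_error(uniform_directions(3), "at least 4")
  expect_error(direction_set(rbind(c(1, 0, 0), c(0, 1, 0)), weights = c(-1, 2)),
               "positive")
})
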