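test_that("closures of very short chains are always unknots", {
  kt <- ktab()
  dod <- dodecahedron_directions()
  set.seed(8)
  for (nseg in c(1, 2, 4)) {
    v <- matrix(rnorm(3 * (nseg + 1)), ncol = 3)
    ch <- open_chain(v)
    sp <- closure_spectrum(ch, dod, table = kt)
    expect_equal(sp$type, "0_1")
    expect_equal(sp$weight, 1)
  }
  # a 1-segment chain closes to a quadrilateral
  cl <- close_chain(open_chain(rbind(c(0, 0, 0), c(1, 0, 0))), c(0, 0, 1))
  expect_equal(n_segments(cl), 4)
})

test_that("closure geometry: ray tips extremal along the direction, margin-independent type", {
  kt <- ktab()
  p <- torus_knot_polygon(2, 3, 47)
  ch <- make_subchain(p, 3, 40)
  d <- c(0.3, -0.5, 0.8) / sqrt(0.98)
  for (margin in c(0.1, 2)) {
    cl <- close_chain(ch, d, hull_margin = margin)
    expect_equal(n_segments(cl), 43)
    proj <- unclass(cl) %*% d
    expect_equal(sort(order(proj, decreasing = TRUE)[1:2]), c(42, 43))
  }
  # classified type independent of the margin, across random chains
  set.seed(99)
  for (case in 1:12) {
    ch <- open_chain(matrix(rnorm(3 * 9), ncol = 3))
    dirs <- dodecahedron_directions()[case %% 20 + 1, ]
    d1 <- as.character(classify(close_chain(ch, c(dirs$x, dirs$y, dirs$z), 0.1), table = kt))
    d2 <- as.character(classify(close_chain(ch, c(dirs$x, dirs$y, dirs$z), 2.0), table = kt))
    expect_equal(d1, d2)
  }
})

test_that("spectra conserve mass and long trefoil subchains close to the trefoil", {
  kt <- ktab()
  p <- torus_knot_polygon(2, 3, 47)
  tref <- as.character(classify(p, table = kt))
  sp <- closure_spectrum(make_subchain(p, 0, 46), table = kt)
  expect_equal(sum(sp$weight), 1, tolerance = 1e-9)
  expect_equal(attr(sp, "failures"), 0)
  d <- dominant(sp)
  expect_equal(d$type, tref)
  expect_gte(d$frequency, 0.95)
  # knot-core-sized subchain still majority trefoil
  core_sp <- closure_spectrum(make_subchain(p, 0, 40), table = kt)
  expect_true(tref %in% majority_types(core_sp))
})

test_that("dominant and majority rules implement the tie-breaks", {
  fake <- function(types, w) {
    out <- tibble::tibble(type = types, weight = w)
    class(out) <- c("knot_spectrum", class(out))
    out
  }
  expect_equal(dominant(fake(c("0_1", "3_1"), c(0.55, 0.45))),
               list(type = "0_1", frequency = 0.55))
  # exact tie: smaller crossing number wins
  expect_equal(dominant(fake(c("3_1", "0_1"), c(0.5, 0.5)))$type, "0_1")
  # crossing-number tie: lexicographic
  expect_equal(dominant(fake(c("6_2", "6_1"), c(0.5, 0.5)))$type, "6_1")
  expect_equal(majority_types(fake(c("0_1", "3_1"), c(0.55, 0.45))), "0_1")
  expect_equal(majority_types(fake(c("A", "B", "C"), c(0.4, 0.4, 0.2))), character(0))
  # two types at exactly one half: the dominance winner is the single majority
  expect_equal(majority_types(fake(c("3_1", "0_1"), c(0.5, 0.5))), "0_1")
  expect_error(dominant(fake(character(0), numeric(0))), "empty")
})

test_that("spectrum is stable under direction-set refinement on the trefoil core", {
  kt <- ktab()
  p <- torus_knot_polygon(2, 3, 47)
  ch <- make_subchain(p, 5, 42)
  d20 <- dominant(closure_spectrum(ch, dodecahedron_directions(), table = kt))
  d100 <- dominant(closure_spectrum(ch, uniform_directions(100, seed = 2), table = kt))
  expect_equal(d20$type, d100$type)
})
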