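test_that("projection of a convex planar polygon has no crossings", {
  t <- 2 * pi * (0:19) / 20
  p <- polygon3(cbind(cos(t), sin(t), 0))
  d <- project(p, view_direction = c(0.2, 0.1, 1))
  expect_equal(n_diagram_crossings(d), 0)
})

test_that("the torus-axis view of a (2,3) torus polygon is the standard trefoil diagram", {
  p <- torus_knot_polygon(2, 3, 47)
  d <- project(p, view_direction = c(0, 0, 1))
  expect_equal(n_diagram_crossings(d), 3)
  expect_equal(length(unique(d$sign[d$sign != 0])), 1)   # all crossings same sign
  # independent oracle: brute-force count of projected segment-pair intersections
  v <- unclass(p)
  n <- nrow(v)
  cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (abs(i - j) <= 1 || (i == 1 && j == n)) next
    a1 <- v[i, 1:2]; a2 <- v[i %% n + 1, 1:2]
    b1 <- v[j, 1:2]; b2 <- v[j %% n + 1, 1:2]
    d1 <- a2 - a1; d2 <- b2 - b1
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) next
    r <- b1 - a1
    s <- (r[1] * d2[2] - r[2] * d2[1]) / den
    u <- (r[1] * d1[2] - r[2] * d1[1]) / den
    if (s > 0 && s < 1 && u > 0 && u < 1) cnt <- cnt + 1
  }
  expect_equal(cnt, 3)
})

test_that("classification does not depend on the view direction", {
  kt <- ktab()
  p <- torus_knot_polygon(2, 5, 45)
  dirs <- rand_dirs(5)
  types <- vapply(seq_len(5), function(i) {
    d <- project(p, view_direction = dirs[i, ])
    as.character(classify(d, table = kt))
  }, character(1))
  expect_equal(length(unique(types)), 1)
})

test_that("simplification removes kinks and unravels wavy unknots", {
  kink <- crossing_diagram(list(rbind(c(1, 1), c(1, 0))), c(1L))
  s <- simplify_diagram(kink)
  expect_equal(n_diagram_crossings(s), 0)

  tref <- trefoil_diagram()
  expect_equal(n_diagram_crossings(simplify_diagram(tref)), 3)  # already minimal

  d <- project(wavy_circle(), view_direction = c(0.9, 0.4, 0.1), seed = 5)
  expect_gt(n_diagram_crossings(d), 0)    # the oblique view has spurious crossings
  expect_equal(n_diagram_crossings(simplify_diagram(d)), 0)
})

test_that("crossing change and mirror are involutions with the right action", {
  tref <- trefoil_diagram()
  once <- crossing_change(tref, 2)
  expect_equal(once$sign[2], -1L)
  expect_equal(crossing_change(once, 2), tref)
  expect_error(crossing_change(tref, 9), "no crossing")

  expect_equal(mirror_diagram(mirror_diagram(tref)), tref)
  kt <- ktab()
  expect_equal(as.character(classify(mirror_diagram(tref), table = kt)),
               mirror_name(as.character(classify(tref, table = kt)), kt))
  # every single crossing change in the minimal trefoil diagram unknots it
  for (id in 1:3)
    expect_equal(as.character(classify(crossing_change(tref, id), table = kt)), "0_1")
})

test_that("DT codes realize table knots and round-trip through diagrams", {
  kt <- ktab()
  d31 <- diagram_from_dt("4 6 2")
  expect_equal(n_diagram_crossings(d31), 3)
  expect_equal(unsigned(as.character(classify(d31, table = kt))), "3_1")
  d41 <- diagram_from_dt(c(4, 6, 8, 2))
  expect_equal(as.character(classify(d41, table = kt)), "4_1")
  expect_equal(n_diagram_crossings(diagram_from_dt(integer(0))), 0)
  expect_error(diagram_from_dt(c(4, 4, 2)), "invalid")
  # unrealizable pairing
  expect_error(diagram_from_dt(c(4, 6, 8, 10, 2)), "realizable")

  # emitted DT code realizes the same knot
  code <- dt_from_diagram(d31)
  expect_equal(sort(abs(code)), c(2, 4, 6))
  expect_equal(unsigned(as.character(classify(diagram_from_dt(code), table = kt))), "3_1")
})

test_that("connected-sum diagrams classify as composites", {
  kt <- ktab()
  granny <- connect_sum_diagram(trefoil_diagram(), trefoil_diagram())
  expect_equal(as.character(classify(granny, table = kt)), "3_1#3_1")
  square <- connect_sum_diagram(trefoil_diagram(), mirror_diagram(trefoil_diagram()))
  expect_equal(as.character(classify(square, table = kt)), "-3_1#3_1")
})
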