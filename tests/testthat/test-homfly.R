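test_that("skein axioms: unknot and kinked unknots give 1", {
  empty <- crossing_diagram(list(), integer(0))
  expect_equal(as.character(homfly(empty)), "0,0:1")
  kink <- crossing_diagram(list(rbind(c(1, 1), c(1, 0))), c(-1L))
  expect_equal(as.character(homfly(kink)), "0,0:1")
})

test_that("trefoil and figure-eight polynomials match their frozen values", {
  # frozen after dev-time verification against the standard two-variable
  # values under the substitution v = i/l, z = i m (and the determinant
  # |P(l=-i, m=2)| = 3 and 5 respectively)
  p3 <- homfly(trefoil_diagram())
  expect_equal(as.character(p3), "-4,0:-1|-2,0:-2|-2,2:1")
  expect_equal(homfly_det(p3), 3)
  p4 <- homfly(figure8_diagram())
  expect_equal(as.character(p4), "-2,0:-1|0,0:-1|0,2:1|2,0:-1")
  expect_equal(homfly_det(p4), 5)
})

test_that("mirror image corresponds to l-inversion", {
  p3 <- homfly(trefoil_diagram())
  pm <- homfly(mirror_diagram(trefoil_diagram()))
  expect_equal(as.character(pm), as.character(homfly_mirror(p3)))
  expect_false(identical(as.character(p3), as.character(pm)))  # trefoil is chiral
  p4 <- homfly(figure8_diagram())
  expect_equal(as.character(homfly_mirror(p4)), as.character(p4))  # 4_1 amphichiral
})

test_that("connected sums multiply polynomials", {
  p3 <- homfly(trefoil_diagram())
  granny <- homfly(connect_sum_diagram(trefoil_diagram(), trefoil_diagram()))
  expect_equal(as.character(granny), as.character(homfly_product(p3, p3)))
  square <- homfly(connect_sum_diagram(trefoil_diagram(),
                                       mirror_diagram(trefoil_diagram())))
  expect_equal(as.character(square),
               as.character(homfly_product(p3, homfly_mirror(p3))))
})

test_that("homfly is invariant under simplification and projection direction", {
  kt <- ktab()
  set.seed(31)
  for (case in 1:25) {
    n <- sample(c(6, 8, 10, 14), 1)
    p <- random_equilateral_polygon(n, seed = 1000 + case)
    d <- project(p, view_direction = rand_dirs(1, seed = case)[1, ], seed = case)
    ph <- as.character(homfly(d))
    expect_equal(as.character(homfly(simplify_diagram(d))), ph)
    d2 <- project(p, view_direction = rand_dirs(1, seed = 500 + case)[1, ],
                  seed = 500 + case)
    expect_equal(as.character(homfly(d2)), ph)
  }
})

test_that("the recursion budget error names the diagram size", {
  p <- torus_knot_polygon(2, 7, 60)
  d <- project(p, seed = 2)
  expect_error(homfly(d, max_nodes = 0), "budget")
})
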