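test_that("disk matrix has the exact brick-wall cell structure", {
  kt <- ktab()
  p <- torus_knot_polygon(2, 3, 18)
  dm <- disk_matrix(p, table = kt)
  n <- 18
  expect_equal(nrow(dm), n * (n - 1))
  expect_equal(sort(unique(dm$nseg)), 1:(n - 1))
  expect_equal(sort(unique(dm$start)), 0:(n - 1))
  expect_equal(dm$longitude, (dm$start + dm$nseg / 2) %% n)
  # every subchain of <= 4 segments closes trivially from every direction
  short <- dm[dm$nseg <= 4, ]
  expect_true(all(short$knot == "0_1"))
  expect_true(all(abs(short$freq - 1) < 1e-9))
  expect_equal(attr(dm, "failures"), 0)
})

test_that("relabelling the host rotates cell starts but not the content", {
  kt <- ktab()
  v <- unclass(torus_knot_polygon(2, 3, 15))
  r <- 4
  dm1 <- disk_matrix(polygon3(v), table = kt)
  dm2 <- disk_matrix(polygon3(v[c((r + 1):15, 1:r), ]), table = kt)
  # multiset of (nseg, dominant) pairs is label-invariant
  t1 <- table(dm1$nseg, dm1$knot)
  t2 <- table(dm2$nseg, dm2$knot)
  expect_equal(t1, t2)
  # cell (s, k) of the rotated host matches cell (s + r, k) of the original
  pos1 <- knotdissect:::cell_index(dm1)
  pos2 <- knotdissect:::cell_index(dm2)
  for (k in c(3, 8, 12)) {
    for (s in c(0, 5, 11)) {
      expect_equal(dm2$knot[pos2[(s %% 15) * 15 + k]],
                   dm1$knot[pos1[((s + r) %% 15) * 15 + k]])
    }
  }
})

test_that("the trefoil host shows only unknot and trefoil cells, with a symmetric core", {
  kt <- ktab()
  p <- torus_knot_polygon(2, 3, 47)
  dm <- disk_matrix(p, table = kt)
  tref <- attr(dm, "global_type")
  expect_setequal(unique(dm$knot), c("0_1", tref))
  core <- knot_core(dm)
  expect_gt(nrow(core), 0)
  expect_lt(max(core$nseg), 47)
  # three-fold symmetry of the host: core starts related by ~n/3 shifts
  if (nrow(core) >= 3) {
    gaps <- sort(diff(sort(core$start)))
    expect_true(any(abs(gaps - 47 / 3) < 3) || length(unique(core$start)) < 3)
  }
  expect_error(knot_core(disk_matrix(wavy_circle(18), table = kt)), "core")
})

test_that("trimming paths spiral from the global type to the unknot", {
  kt <- ktab()
  dm <- disk_matrix(torus_knot_polygon(2, 3, 24), table = kt)
  tref <- attr(dm, "global_type")
  tp <- trimming_paths(dm, scission = 5)
  for (path in tp) {
    expect_equal(nrow(path), 23)
    expect_equal(path$nseg, 23:1)
    expect_equal(path$knot[1], tref)            # start at the near-full subchain
    expect_equal(path$knot[nrow(path)], "0_1")  # end trivially
    # trefoil direct to unknot: no intermediate types
    expect_true(all(path$knot %in% c(tref, "0_1")))
  }
  # the green path advances its start as segments are trimmed from the head
  expect_equal(tp$green$start, (6 + 23 - tp$green$nseg) %% 24)
  expect_true(all(tp$blue$start == 6))
})

test_that("scission classes partition all scissions; trefoil is all both_direct", {
  kt <- ktab()
  dm <- disk_matrix(torus_knot_polygon(2, 3, 24), table = kt)
  sc <- scission_classes(dm)
  expect_equal(nrow(sc), 24)
  expect_true(all(sc$class %in% c("both_via_K", "both_direct", "mixed")))
  expect_true(all(sc$class == "both_direct"))
})

test_that("triangular matrices cover every subchain of an open chain", {
  kt <- ktab()
  set.seed(5)
  ch <- open_chain(matrix(rnorm(18), ncol = 3))   # 5 segments
  tm <- triangular_matrix(ch, table = kt)
  expect_equal(nrow(tm), 5 * 6 / 2)
  expect_true(all(tm$knot == "0_1"))              # too short to knot
  expect_equal(attr(tm, "m"), 5)
  # full-length cell of a scission of the trefoil carries the trefoil
  p <- torus_knot_polygon(2, 3, 30)
  chain <- make_subchain(p, 1, 29)
  tm2 <- triangular_matrix(chain, table = kt)
  full <- tm2[tm2$nseg == 29, ]
  expect_equal(unsigned(full$knot), "3_1")
})

test_that("a twist-knot host shows all three scission behaviours", {
  kt <- ktab()
  host <- lissajous_polygon(c(2, 3, 5), c(0.1, 1, 0), 50)
  expect_equal(unsigned(as.character(classify(host, table = kt))), "6_1")
  dm <- disk_matrix(host, table = kt, budget = 200L)
  expect_setequal(unsigned(unique(dm$knot)), c("0_1", "4_1", "6_1"))
  sc <- scission_classes(dm)
  expect_setequal(unique(sc$class), c("both_via_K", "both_direct", "mixed"))
  # mixed scissions: trimming one end passes through the figure-eight, the
  # other goes straight to the unknot
  mx <- sc[sc$class == "mixed", ]
  expect_true(all((unsigned(mx$first_blue) == "4_1" & mx$first_green == "0_1") |
                  (mx$first_blue == "0_1" & unsigned(mx$first_green) == "4_1")))
  # via-K scissions all pass through the figure-eight on both ends
  via <- sc[sc$class == "both_via_K", ]
  expect_true(all(unsigned(via$first_blue) == "4_1"))
  # classes form contiguous circular arcs: few boundaries around the circle
  cls <- sc$class[order(sc$scission)]
  changes <- sum(cls != c(cls[-1], cls[1]))
  expect_lte(changes, 8)
})
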