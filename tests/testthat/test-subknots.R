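test_that("subknot report separates all and majority subknots", {
  kt <- ktab()
  dm <- disk_matrix(torus_knot_polygon(2, 3, 47), table = kt)
  rep_ <- subknot_report(dm)
  tref <- rep_$global_type
  expect_setequal(rep_$all_subknots, c("0_1", tref))
  expect_true("0_1" %in% rep_$all_subknots)
  expect_true(all(rep_$majority_subknots %in% rep_$all_subknots))
  expect_equal(sum(rep_$areas$cells), nrow(dm))
  g <- glance(rep_)
  expect_equal(g$n_subknots, 2)
  td <- tidy(rep_)
  expect_true(all(c("type", "cells", "majority") %in% names(td)))
})

test_that("region generations reproduce the torus-knot nesting", {
  kt <- ktab()
  # trefoil: two regions, unknot one hop inside the global territory
  rg3 <- region_graph(disk_matrix(torus_knot_polygon(2, 3, 30), table = kt))
  g3 <- setNames(rg3$generations$generation, unsigned(rg3$generations$type))
  expect_equal(g3[["3_1"]], 0)
  expect_equal(g3[["0_1"]], 1)
  # 5_1: the unknot zone is reachable only through the trefoil zone
  rg5 <- region_graph(disk_matrix(torus_knot_polygon(2, 5, 40), table = kt))
  g5 <- setNames(rg5$generations$generation, unsigned(rg5$generations$type))
  expect_equal(g5[["5_1"]], 0)
  expect_equal(g5[["3_1"]], 1)
  expect_equal(g5[["0_1"]], 2)
  # every observed subknot type gets a finite generation
  expect_setequal(rg5$generations$type,
                  unique(disk_matrix(torus_knot_polygon(2, 5, 40), table = kt)$knot))
})

test_that("extract_subknot yields a standalone polygon of the cell's type", {
  kt <- ktab()
  p <- torus_knot_polygon(2, 3, 47)
  dm <- disk_matrix(p, table = kt)
  core <- knot_core(dm)
  cell <- core[1, ]
  ex <- extract_subknot(p, cell, table = kt)
  expect_s3_class(ex, "polygon3")
  expect_equal(as.character(classify(ex, table = kt)), attr(dm, "global_type"))
  # subdivision does not change the extracted type
  expect_equal(as.character(classify(refine(ex, 2), table = kt)),
               attr(dm, "global_type"))
  # recursive dissection of the extracted knot shows its own subknot structure
  rep2 <- subknot_report(disk_matrix(ex, table = kt))
  expect_true(attr(dm, "global_type") %in% rep2$all_subknots)
  expect_error(extract_subknot(p, list(start = 0, nseg = 2), table = kt), "trivial")
})

test_that("containment comparisons compute the four agreement flags", {
  kt <- ktab()
  dm <- disk_matrix(torus_knot_polygon(2, 3, 47), table = kt)
  rep_ <- subknot_report(dm)
  # the trefoil's full predecessor reference is just the unknot
  cmp <- compare_to_reference(rep_, reference = "0_1", first_generation = "0_1")
  expect_true(all(unlist(cmp)))
  # a reference the host cannot realize
  cmp2 <- compare_to_reference(rep_, reference = c("0_1", "4_1"))
  expect_true(cmp2$subknots_in_reference)
  expect_false(cmp2$reference_in_subknots)
  # synthetic report exercising the non-subset direction
  fake <- structure(list(global_type = "8_10", n = 50,
                         all_subknots = c("0_1", "3_1", "7_5"),
                         majority_subknots = c("0_1", "3_1")),
                    class = "subknot_report")
  cmp3 <- compare_to_reference(fake, reference = c("0_1", "3_1", "5_1"))
  expect_false(cmp3$subknots_in_reference)   # 7_5 is not a predecessor
  expect_true(cmp3$majority_in_reference)
})

test_that("early-exit containment agrees with the full matrix", {
  kt <- ktab()
  p <- torus_knot_polygon(2, 3, 30)
  tref <- as.character(classify(p, table = kt))
  r <- contains_subknots(p, c("0_1", tref), table = kt)
  expect_true(r$contains)
  expect_lt(r$cells_evaluated, 30 * 29)
  r2 <- contains_subknots(p, c("0_1", tref, "4_1"), table = kt)
  expect_false(r2$contains)
  expect_equal(r2$missing, "4_1")
})
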