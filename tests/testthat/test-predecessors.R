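test_that("first-generation predecessors of the small twist and torus knots", {
  kt <- ktab()
  expect_equal(first_generation("3_1", kt)$set, "0_1")
  expect_equal(first_generation("5_1", kt)$set, "3_1")
  expect_setequal(unsigned(first_generation("5_2", kt)$set), c("3_1", "0_1"))
  expect_setequal(unsigned(first_generation("4_1", kt)$set), "0_1")
  # signed consistency: torus predecessors inherit the host handedness
  fg91 <- first_generation("9_1", kt)
  expect_equal(fg91$set, "7_1")
  expect_equal(first_generation("-9_1", kt)$set, "-7_1")
})

test_that("predecessors are undefined for non-alternating knots", {
  kt <- ktab()
  expect_error(first_generation("8_19", kt), "non-alternating")
  expect_error(generational_closure("8_21", table = kt), "non-alternating")
  expect_error(first_generation("0_1", kt), "crossings")
  expect_error(first_generation("99_99", kt), "unknown knot")
})

test_that("mirror symmetry of predecessor sets", {
  kt <- ktab()
  for (nm in c("7_5", "7_7", "8_10")) {
    a <- first_generation(nm, kt)$set
    b <- first_generation(paste0("-", nm), kt)$set
    expect_setequal(mirror_name(a, kt), b)
  }
})

test_that("unknotting-number-one knots reach the unknot in one crossing change", {
  kt <- ktab()
  for (nm in c("3_1", "4_1", "5_2", "6_1", "7_2")) {
    expect_true("0_1" %in% first_generation(nm, kt)$set)
  }
  # unknotting number two: no direct unknot, trefoil intermediary
  expect_false("0_1" %in% first_generation("5_1", kt)$set)
})

test_that("generational closure assigns first-appearance generations", {
  kt <- ktab()
  pc <- generational_closure("7_1", table = kt)
  expect_equal(pc$generations, list("5_1", "3_1", "0_1"))
  expect_true(pc$defined)
  td <- tidy(pc)
  expect_equal(td$generation, 1:3)
  expect_equal(glance(pc)$n_types, 3)
  # composite predecessors: crossing changes on the plumbed square-knot diagram
  fgsq <- first_generation("-3_1#3_1", kt)
  expect_setequal(fgsq$set, c("-3_1", "3_1"))
})

test_that("the census over 7-crossing alternating knots is fully defined", {
  kt <- ktab()
  c7 <- defined_census(7, table = kt)
  expect_equal(nrow(c7), 7)
  expect_equal(sum(c7$defined), 7)
  c3 <- defined_census(3, table = kt)
  expect_equal(sum(c3$defined), 1)
})
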