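test_that("the generated table covers the full census with both chiralities", {
  kt <- ktab()
  e <- kt$entries[!kt$entries$composite, ]
  reps <- e[!startsWith(e$name, "-"), ]
  # census sizes per crossing number (two 10-crossing mutant pairs share a
  # HOMFLYPT polynomial with their partner and are merged: 244, not 249)
  expect_equal(as.integer(table(reps$crossings)),
               c(1L, 1L, 2L, 3L, 7L, 21L, 49L, 160L))
  expect_equal(sum(reps$alternating & reps$crossings == 8), 18)
  expect_equal(sum(reps$alternating & reps$crossings == 9), 41)
  # chiral knots appear twice, amphichiral once
  amphi <- reps$name[reps$amphichiral]
  expect_true(all(c("4_1", "6_3", "8_3", "8_9", "8_12", "8_17", "8_18") %in% amphi))
  expect_equal(nrow(e), 2 * nrow(reps) - sum(reps$amphichiral))
})

test_that("every table diagram classifies back to its own name", {
  kt <- ktab()
  dtab <- read_dt_table()
  idx <- c(which(dtab$crossings <= 7),
           which(dtab$name %in% c("8_1", "8_10", "8_19", "9_1", "9_19", "9_42")))
  for (i in idx) {
    d <- diagram_from_dt(dtab$dt[[i]])
    expect_equal(as.character(classify(d, table = kt)), dtab$name[i])
  }
})

test_that("trefoil polynomial lookup is unique below 10 crossings", {
  kt9 <- build_knot_table(9)
  p3 <- as.character(homfly(trefoil_diagram()))
  expect_equal(length(kt9$lookup[[p3]]), 1)
  expect_equal(unsigned(kt9$lookup[[p3]]), "3_1")
  # collision scan: the only ambiguity at <= 9 crossings pairs one prime with
  # a 4_1 composite (both alternating, so downstream calls are unaffected)
  expect_lte(length(kt9$collisions), 2)
})

test_that("composite entries multiply their factors", {
  kt <- ktab()
  e <- kt$entries
  sq <- e[e$name == "-3_1#3_1", ]
  expect_equal(nrow(sq), 1)
  p31 <- e$poly[e$name == "3_1"]
  p31m <- e$poly[e$name == "-3_1"]
  expect_equal(sq$poly, knotdissect:::.cpp_poly_product(c(p31, p31m)))
  expect_true(sq$amphichiral)
  expect_equal(sq$crossings, 6)
  expect_true(all(c("3_1#3_1", "3_1#4_1", "-3_1#3_1#3_1") %in% e$name))
})

test_that("name helpers: crossing numbers and mirrors", {
  kt <- ktab()
  expect_equal(knot_crossing_number(c("0_1", "3_1", "-7_5", "3_1#-3_1", "10_124")),
               c(0L, 3L, 7L, 6L, 10L))
  expect_true(is.na(knot_crossing_number("unknown:deadbeef")))
  expect_equal(mirror_name(c("3_1", "4_1", "0_1"), kt), c("-3_1", "4_1", "0_1"))
  expect_equal(mirror_name("3_1#-3_1", kt), "-3_1#3_1")
  expect_equal(mirror_name(mirror_name("-9_19", kt), kt), "-9_19")
})

test_that("unknown polynomials get stable hash names", {
  out <- knotdissect:::name_from_poly("2,0:7|4,4:1", 12, ktab())
  expect_match(as.character(out), "^unknown:[0-9a-f]{8}$")
  out2 <- knotdissect:::name_from_poly("2,0:7|4,4:1", 12, ktab())
  expect_equal(as.character(out), as.character(out2))
})
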