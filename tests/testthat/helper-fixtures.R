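# Shared fixtures, all built in code.

# the default table is memoized inside the package, so this is cheap after
# the first call of the session
ktab <- function() build_knot_table(10)

# standard positive trefoil as a signed Gauss code: O1 U2 O3 U1 O2 U3, all +1
trefoil_diagram <- function() {
  crossing_diagram(list(rbind(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 0, 1, 0))),
                   c(1L, 1L, 1L))
}

# figure-eight: O1 U2 O3 U4 O2 U1 O4 U3, signs +,+,-,-
figure8_diagram <- function() {
  crossing_diagram(list(rbind(c(1, 2, 3, 4, 2, 1, 4, 3),
                              c(1, 0, 1, 0, 1, 0, 1, 0))),
                   c(1L, 1L, -1L, -1L))
}

# planar circle with radial waviness: an unknot whose generic projections
# carry many removable crossings once tilted
wavy_circle <- function(n = 40, wobble = 0.4) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  r <- 1 + wobble * sin(7 * t)
  polygon3(cbind(r * cos(t), r * sin(t), 0.05 * cos(11 * t)))
}

# deterministic jumble of unit-sphere directions
rand_dirs <- function(k, seed = 99) {
  set.seed(seed)
  m <- matrix(rnorm(3 * k), k, 3)
  m / sqrt(rowSums(m^2))
}

expect_knot <- function(x, name, table = ktab()) {
  expect_equal(as.character(classify(x, table = table)), name)
}

# chirality-blind comparison helpers (table chirality labels are an internal
# convention; mirror-paired sets are the convention-free content)
unsigned <- function(x) sub("^-", "", x)
setequal_upto_mirror <- function(a, b, table = ktab()) {
  setequal(a, b) || setequal(mirror_name(a, table), b)
}
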