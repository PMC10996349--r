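# Shared fixtures: small problem sizes keep the unit tests fast; the
# default-resolution checks live in test-acceptance.R.

small_grid <- c(12L, 12L, 32L)

small_network <- function(seed = 11L) {
  generate_network(seed = seed)
}

# Hand-built single-vessel graph: one straight axial segment spanning the
# voxel depth, entirely interior in x/y.
single_vessel_graph <- function(voxel = c(0.15e-3, 0.16e-3, 0.43e-3),
                                outer_d = 9e-6) {
  nodes <- rbind(c(voxel[1] / 2, voxel[2] / 2, 0),
                 c(voxel[1] / 2, voxel[2] / 2, voxel[3]))
  segs <- data.frame(from = 1L, to = 2L, outer_diameter = outer_d,
                     wall_thickness = 1e-6)
  vessel_graph(nodes, segs, voxel)
}

empty_graph <- function(voxel = c(0.15e-3, 0.16e-3, 0.43e-3)) {
  vessel_graph(matrix(numeric(0), 0, 3),
               data.frame(from = integer(0), to = integer(0),
                          outer_diameter = numeric(0),
                          wall_thickness = numeric(0)),
               voxel)
}

# Relative comparison that stays meaningful at any magnitude (expect_equal
# falls back to absolute tolerance for values below sqrt(.Machine$double.eps),
# which would make checks on 1e-9-scale coefficients vacuous).
expect_rel <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol * max(abs(expected)))
}

# Independent closed-form evaluation of the two-wall equilibrium potential,
# written out directly so it does not share code with the package internals.
psi_closed_form <- function(y, zeta = -0.0211, debye = 9.04855e-10, h = 1e-9,
                            temp = 310, z = 1) {
  k <- 1.38064852e-23
  e <- 1.60217662e-19
  pref <- 4 * k * temp / (z * e)
  g <- tanh(z * e * zeta / (4 * k * temp))
  pref * (atanh(g * exp(-y / debye)) + atanh(g * exp(-(2 * h - y) / debye)))
}
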