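D <- 80e-6
Q <- 251.32e-14
mu <- 1e-3

test_that("the stadium family preserves perimeter and reproduces the width limits", {
  circ <- cross_section(D, D)
  expect_equal(circ$width, D)
  expect_equal(circ$perimeter, pi * D)
  flat <- cross_section(D, D / 4)
  expect_equal(flat$perimeter, pi * D, tolerance = 1e-3)
  expect_equal(flat$width / D, 3 * pi / 8 + 0.25, tolerance = 1e-12)
  squeezed <- cross_section(D, 1e-9 * D)
  expect_equal(squeezed$width, pi * D / 2, tolerance = 1e-6)
  expect_error(cross_section(D, 0), "gap")
  expect_error(cross_section(D, 1.1 * D), "gap")
})

test_that("the circular section reproduces Poiseuille flow to better than 1%", {
  sol <- solve_axial_flow(cross_section(D, D), Q, mu)
  expect_equal(sol$dpdz, -128 * mu * Q / (pi * D^4), tolerance = 0.01)
  expect_equal(median(sol$shear$gamma), 32 * Q / (pi * D^3), tolerance = 0.01)
  expect_equal(sol$w_max, 2 * Q / (pi * (D / 2)^2), tolerance = 0.01)
  expect_equal(sol$area, pi * (D / 2)^2, tolerance = 0.005)
  expect_error(solve_axial_flow(cross_section(D, D), Q, mu,
                                grid_resolution = 6), "coarse")
})

test_that("the solve is linear in viscosity and flow rate", {
  s1 <- solve_axial_flow(cross_section(D, D / 2), Q, mu, grid_resolution = 16)
  s2 <- solve_axial_flow(cross_section(D, D / 2), Q, mu / 2,
                         grid_resolution = 16)
  expect_equal(s2$dpdz, s1$dpdz / 2, tolerance = 1e-12)
  s3 <- solve_axial_flow(cross_section(D, D / 2), 2 * Q, mu,
                         grid_resolution = 16)
  expect_equal(s3$dpdz, 2 * s1$dpdz, tolerance = 1e-12)
})

test_that("resistance rises monotonically as the gap closes", {
  dp <- vapply(c(0.8, 0.5, 0.25), function(g)
    abs(solve_axial_flow(cross_section(D, g * D), Q, mu,
                         grid_resolution = 16)$dpdz), numeric(1))
  expect_true(all(diff(dp) > 0))
})

test_that("the pressure gradient is grid-converged at the default resolution", {
  lo <- solve_axial_flow(cross_section(D, D / 4), Q, mu, grid_resolution = 16)
  hi <- solve_axial_flow(cross_section(D, D / 4), Q, mu, grid_resolution = 32)
  expect_lt(abs(hi$dpdz - lo$dpdz) / abs(hi$dpdz), 0.01)
})

test_that("narrow gaps approach the rectangular-slit series solution", {
  for (g in c(0.1, 0.05)) {
    sec <- cross_section(D, g * D)
    sol <- solve_axial_flow(sec, Q, mu, grid_resolution = 16)
    oracle <- rect_duct_pressure_gradient(sec$width, sec$gap, Q, mu)
    expect_equal(sol$dpdz, oracle, tolerance = 0.10)
  }
})

test_that("the rectangular-duct series matches the square-duct literature constant", {
  a <- 50e-6
  G <- rect_duct_pressure_gradient(a, a, Q, mu)
  expect_equal(abs(G), 28.45 * mu * Q / a^4, tolerance = 0.001)
})

test_that("flattening to a D/4 gap amplifies resistance about seventeenfold", {
  circ <- solve_axial_flow(cross_section(D, D), Q, mu)
  flat <- solve_axial_flow(cross_section(D, D / 4), Q, mu, grid_resolution = 24)
  ratio <- resistance_ratio(flat, circ)
  expect_gt(ratio, 17 * 0.8)
  expect_lt(ratio, 17 * 1.2)
  # independent analytic bracket: the rectangle of the same width and gap
  # conducts slightly better than the stadium, the reported upper bound is 18
  rect_ratio <- abs(rect_duct_pressure_gradient(flat$section$width,
                                                flat$section$gap, Q, mu)) /
    abs(circ$dpdz)
  expect_equal(rect_ratio, 15, tolerance = 0.07)
  expect_gt(ratio, rect_ratio * 0.97)
  expect_lt(ratio, 18 * 1.05)
  expect_equal(resistance_ratio(circ, circ), 1)
  other <- solve_axial_flow(cross_section(D, D), 2 * Q, mu,
                            grid_resolution = 16)
  expect_error(resistance_ratio(flat, other), "flow rates")
})

test_that("wall shear splits into ~8x on flat walls and ~4x on the caps", {
  circ <- solve_axial_flow(cross_section(D, D), Q, mu)
  flat <- solve_axial_flow(cross_section(D, D / 4), Q, mu, grid_resolution = 24)
  gains <- shear_partition(flat, circ)
  expect_equal(gains$gain_flat, 8, tolerance = 0.25)
  expect_equal(gains$gain_curved, 4, tolerance = 0.25)
  expect_gt(gains$gain_flat, gains$gain_curved)
  self <- shear_partition(circ, circ)
  expect_equal(self$gain_curved, 1, tolerance = 1e-9)
  expect_equal(self$gain_flat, 1, tolerance = 1e-9)
  expect_error(shear_partition(flat, 0), "zero")
})

test_that("flat walls out-shear the caps across the whole gap sweep", {
  circ <- solve_axial_flow(cross_section(D, D), Q, mu, grid_resolution = 24)
  for (g in c(0.3, 0.5, 0.7, 0.9)) {
    sol <- solve_axial_flow(cross_section(D, g * D), Q, mu,
                            grid_resolution = 16)
    gains <- shear_partition(sol, circ)
    expect_gt(gains$gain_flat, gains$gain_curved)
  }
})
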