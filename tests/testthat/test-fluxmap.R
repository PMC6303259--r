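test_that("the standard scenario carries exactly the four conductivity classes", {
  sc <- flux_scenario()
  expect_identical(dim(sc$sigma), c(26L, 41L))
  expect_setequal(unique(as.vector(sc$sigma)), c(0.4, 1, 4, 10))
  sv <- sc$sigma_values
  expect_equal(sv[["cylindrical_capillary"]] / sv[["flattened_capillary"]], 2.5)
  expect_equal(sv[["cylindrical_arteriole"]] / sv[["flat_arteriole"]], 2.5)
  # the proximal half of the path is cylindrical, the distal half flat
  path <- sc$sigma[sc$arteriole_row, seq_len(sc$tip_col)]
  expect_true(all(path %in% c(4, 10)))
  expect_equal(sum(path == 4), round(sc$tip_col / 2))
  # flat-free arteriole
  sc0 <- flux_scenario(flat_fraction = 0)
  expect_setequal(unique(as.vector(sc0$sigma)), c(1, 10))
  expect_error(flux_scenario(tip_col = 41), "short circuit")
})

test_that("flux follows the one-sided difference definition exactly", {
  V <- matrix(as.numeric(row(matrix(0, 5, 6))), 5, 6)   # V = i
  sig <- matrix(1, 5, 6)
  fl <- compute_flux(V, sig)
  expect_equal(fl$jx[2:5, ], matrix(1, 4, 6))
  expect_equal(fl$jx[1, ], rep(0, 6))
  expect_equal(fl$jy, matrix(0, 5, 6))
  expect_equal(compute_flux(matrix(2, 5, 6), sig)$magnitude, matrix(0, 5, 6))
  sig2 <- matrix(3, 5, 6)
  expect_equal(compute_flux(V, sig2)$jx[3, 2], 3)       # jx = sigma * dV
})

test_that("relaxation solves the uniform-conductivity Laplace problem", {
  nr <- 10; nc <- 15
  dir <- matrix(FALSE, nr, nc); dir[, 1] <- TRUE; dir[, nc] <- TRUE
  val <- matrix(0, nr, nc); val[, 1] <- 1
  sc <- lattice_scenario(matrix(1, nr, nc), dir, val)
  pot <- relax_potential(sc, tol = 1e-12)
  expect_true(pot$converged)
  lin <- matrix(seq(1, 0, length.out = nc), nr, nc, byrow = TRUE)
  expect_lt(max(abs(pot$V - lin)), 1e-6)
})

test_that("relaxation agrees with the direct sparse solve and conserves flux", {
  sc <- flux_scenario(n_rows = 13, n_cols = 21, flat_halo = 3)
  pot <- relax_potential(sc)
  expect_true(pot$converged)
  direct <- solve_potential_direct(sc)
  expect_lt(max(abs(pot$V - direct$V)), 1e-6)
  # discrete conservation at free cells
  fl <- compute_flux(pot)
  expect_lt(max(abs(fl$divergence[!sc$dirichlet])), 1e-6)
  # maximum principle
  expect_gte(min(pot$V), 0)
  expect_lte(max(pot$V), 1)
})

test_that("the flattened tip carries less flux than the swerving path around it", {
  sc <- flux_scenario()
  pot <- solve_potential_direct(sc)
  means <- flux_region_means(compute_flux(pot), sc)
  expect_lt(means[["tip"]], means[["swerve"]])
})

test_that("softening the tip conductivity monotonically starves the tip", {
  tip_flux <- vapply(c(0.2, 0.4, 0.7, 1.0), function(sf) {
    sc <- flux_scenario(sigma_values = c(flattened_capillary = sf,
                                         cylindrical_capillary = 1,
                                         flat_arteriole = 4,
                                         cylindrical_arteriole = 10))
    means <- flux_region_means(compute_flux(solve_potential_direct(sc)), sc)
    means[["tip"]]
  }, numeric(1))
  expect_true(all(diff(tip_flux) > 0))
})
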