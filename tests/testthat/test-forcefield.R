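# Pairwise energetics: mixing rules, A/C conversion, pair energies and
# the state energy decomposition, checked against independent brute-force
# oracles.

test_that("Lorentz-Berthelot mixing", {
  expect_equal(combine_lj(0.453, 3.380, 0.453, 3.380),
               list(epsilon = 0.453, sigma = 3.380))
  m <- combine_lj(0.453, 3.380, 0.1521, 3.1507)
  expect_equal(m$epsilon, 0.262490571259, tolerance = 1e-10)
  expect_equal(m$sigma, 3.26535)
  expect_equal(combine_lj(0, 1, 0.5, 3)$epsilon, 0)
})

test_that("A/C coefficients are algebraically consistent", {
  expect_equal(ac_from_epsilon_sigma(0, 2.5), list(A = 0, C = 0))
  ac <- ac_from_epsilon_sigma(0.1521, 3.1507)
  expect_equal(ac$A, 582202.198, tolerance = 1e-6)
  expect_equal(ac$C, 595.156969, tolerance = 1e-6)
  back <- epsilon_sigma_from_ac(ac$A, ac$C)
  expect_equal(back$epsilon, 0.1521, tolerance = 1e-10)
  expect_equal(back$sigma, 3.1507, tolerance = 1e-10)
})

test_that("pair energy has the LJ zero crossing, minimum and Coulomb term", {
  expect_equal(pair_energy(3.1507, 0.1521, 3.1507), 0)
  expect_equal(pair_energy(2^(1 / 6) * 3.1507, 0.1521, 3.1507), -0.1521)
  expect_equal(pair_energy(3, 0, 1, qi = 0.4, qj = 0.4), 17.7098666667,
               tolerance = 1e-10)
  expect_error(pair_energy(0, 0.1, 3), "positive")
})

test_that("two-molecule interaction energy matches a 9-term hand sum", {
  ff <- forcefield()
  a <- water_structure(c(0, 0, 0), "a")
  b <- water_structure(c(2.8, 0, 0), "b")
  # independent oracle: loop over the 3 x 3 site pairs directly
  pa <- as.matrix(a$atoms[, c("x", "y", "z")])
  pb <- as.matrix(b$atoms[, c("x", "y", "z")])
  q <- a$atoms$charge
  e_oracle <- 0
  for (i in 1:3) {
    for (j in 1:3) {
      r <- sqrt(sum((pa[i, ] - pb[j, ])^2))
      e_oracle <- e_oracle + 332.06 * q[i] * q[j] / r
    }
  }
  rOO <- sqrt(sum((pa[1, ] - pb[1, ])^2))
  sr6 <- (ff$water$sigma / rOO)^6
  e_oracle <- e_oracle + 4 * ff$water$epsilon * (sr6^2 - sr6)

  ie <- interaction_energy(a, b, box_edge = Inf, ff = ff)
  expect_equal(ie$total, e_oracle, tolerance = 1e-12)
  expect_equal(ie$total, ie$electrostatic + ie$vdw, tolerance = 1e-10)

  # symmetry
  ie2 <- interaction_energy(b, a, box_edge = Inf, ff = ff)
  expect_equal(ie$total, ie2$total, tolerance = 1e-12)

  # dummy molecules with no charge and no LJ interact not at all
  d1 <- nanostructure("X", matrix(0, 1, 3), lj_label = "GHOST", name = "d1")
  d2 <- nanostructure("X", matrix(c(3, 0, 0), 1, 3), lj_label = "GHOST",
                      name = "d2")
  ffg <- forcefield(sites = data.frame(label = "GHOST", epsilon = 0,
                                       sigma = 1))
  expect_equal(interaction_energy(d1, d2, Inf, ffg),
               list(total = 0, electrostatic = 0, vdw = 0))

  # centre-centre cutoff skips far pairs entirely
  far <- water_structure(c(11, 0, 0), "far")
  expect_equal(interaction_energy(a, far, Inf, ff)$total, 0)
  expect_error(interaction_energy(a, b, box_edge = 10, ff = ff), "cutoff")
  bad <- nanostructure("Q", matrix(c(5, 0, 0), 1, 3), lj_label = "NOPE")
  expect_error(interaction_energy(a, bad, Inf, ff), "unresolvable")
})

test_that("state energy equals the all-pairs brute-force oracle", {
  # three waters, then five molecules incl. a charged LJ solute; cutoff
  # beyond the box diagonal so no convention can differ
  st <- tiny_water_state()
  st$waters <- st$waters[c(2, 9, 33), , drop = FALSE]
  ff <- nocut_ff(12.4)
  e <- total_energy(st, ff)
  o <- brute_force_energy(st, ff)
  expect_equal(e$total, o$total, tolerance = 1e-9)
  expect_equal(e$water_water, o$water_water, tolerance = 1e-9)

  dimer <- nanostructure(c("Xa", "Xb"),
                         rbind(c(0, 0, 0), c(0, 0, 1.5)),
                         charge = c(0.25, -0.25),
                         lj_label = c("LJA", "LJB"), name = "dimer")
  ff2 <- nocut_ff(12.4, sites = data.frame(label = c("LJA", "LJB"),
                                           epsilon = c(0.2, 0.05),
                                           sigma = c(3.2, 2.4)))
  st2 <- tiny_water_state(seed = 3)
  st2$waters <- st2$waters[c(5, 17, 28, 51), , drop = FALSE]
  st2$solute <- dimer
  e2 <- total_energy(st2, ff2)
  o2 <- brute_force_energy(st2, ff2)
  expect_equal(e2$total, o2$total, tolerance = 1e-9)
  expect_equal(e2$solute_water, o2$solute_water, tolerance = 1e-9)
  expect_equal(e2$electrostatic_in_soln, o2$elec, tolerance = 1e-9)
  expect_equal(e2$vdw_in_soln, o2$vdw, tolerance = 1e-9)
})

test_that("energy decomposition closes and degenerates correctly", {
  st <- tiny_water_state()
  st$solute <- build_ssz_fixture("keto")
  ff <- tiny_ff()
  e <- total_energy(st, ff)
  expect_equal(e$electrostatic_in_soln + e$vdw_in_soln, e$solute_water,
               tolerance = 1e-6)
  expect_equal(e$solute_water + e$water_water, e$total, tolerance = 1e-6)

  empty <- st
  empty$waters <- st$waters[0, , drop = FALSE]
  e0 <- total_energy(empty, ff)
  expect_equal(unlist(e0, use.names = FALSE), rep(0, 5))

  pure <- st
  pure$solute <- NULL
  expect_equal(total_energy(pure, ff)$solute_water, 0)
})

test_that("total energy is invariant under box-lattice translations", {
  st <- tiny_water_state()
  ff <- tiny_ff()
  e1 <- total_energy(st, ff)$total
  st2 <- st
  st2$waters <- st2$waters + matrix(rep(c(12.4, 0, -24.8), 3),
                                    nrow(st2$waters), 9, byrow = TRUE)
  expect_equal(total_energy(st2, ff)$total, e1, tolerance = 1e-8)
})
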