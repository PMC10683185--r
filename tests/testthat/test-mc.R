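# Metropolis sampler: proposal symmetry and rigidity, local energy
# differences against full recomputation, the acceptance rule against a
# Bernoulli oracle, and trajectory-level contracts.

test_that("zero-amplitude proposals are identities; moves keep rigidity", {
  st <- tiny_water_state()
  set.seed(1)
  mv <- propose_move(st, mc_move_spec(d_translate = 1e-12, d_rotate = 1e-9))
  old <- matrix(st$waters[mv$index, ], 3, 3, byrow = TRUE)
  expect_equal(unname(mv$coords), unname(old), tolerance = 1e-9)

  set.seed(2)
  spec <- mc_move_spec(d_translate = 0.13, d_rotate = 10)
  for (k in 1:50) {
    mv <- propose_move(st, spec)
    old <- matrix(st$waters[mv$index, ], 3, 3, byrow = TRUE)
    # O displacement bounded by sqrt(3) * d (modulo box wrapping)
    dO <- mv$coords[1, ] - old[1, ]
    dO <- dO - 12.4 * round(dO / 12.4)
    expect_lte(sqrt(sum(dO^2)), sqrt(3) * 0.13 + 1e-12)
    # intramolecular geometry unchanged
    for (a in 2:3) {
      expect_equal(sqrt(sum((mv$coords[a, ] - mv$coords[1, ])^2)),
                   sqrt(sum((old[a, ] - old[1, ])^2)), tolerance = 1e-10)
    }
  }
})

test_that("translation components are uniform on [-d, +d]", {
  st <- tiny_water_state()
  spec <- mc_move_spec(d_translate = 0.13, d_rotate = 10)
  set.seed(42)
  n <- 10000
  dx <- numeric(3 * n)
  for (k in seq_len(n)) {
    mv <- propose_move(st, spec)
    old <- st$waters[mv$index, 1:3]
    d <- mv$coords[1, ] - old
    d <- d - 12.4 * round(d / 12.4)
    dx[(3 * k - 2):(3 * k)] <- d
  }
  ks <- suppressWarnings(stats::ks.test(dx, "punif", -0.13, 0.13))
  expect_gt(ks$p.value, 0.01)
  expect_gt(max(dx), 0.12)
  expect_lt(min(dx), -0.12)
})

test_that("local energy difference equals full recomputation", {
  st <- tiny_water_state()
  st$waters <- st$waters[1:5, , drop = FALSE]
  st$solute <- build_ssz_fixture("keto")
  ff <- tiny_ff()
  set.seed(11)
  for (k in 1:20) {
    mv <- propose_move(st, mc_move_spec(d_translate = 0.5, d_rotate = 45))
    de <- delta_energy_local(st, mv$index, mv$coords, ff)
    st2 <- st
    st2$waters[mv$index, ] <- as.vector(t(mv$coords))
    de_full <- total_energy(st2, ff)$total - total_energy(st, ff)$total
    expect_equal(de, de_full, tolerance = 1e-9)
  }
  # identical coordinates give exactly zero
  old <- matrix(st$waters[2, ], 3, 3, byrow = TRUE)
  expect_identical(delta_energy_local(st, 2, old, ff), 0)
})

test_that("a molecule beyond every cutoff contributes nothing", {
  st <- tiny_water_state()
  st$solute <- NULL
  st$waters <- st$waters[1:3, , drop = FALSE]
  st$box_edge <- 40
  st$waters[1, ] <- st$waters[1, ] + rep(c(18, 18, 18), 3)
  ff <- tiny_ff() # cutoff 6 << separations
  old <- matrix(st$waters[1, ], 3, 3, byrow = TRUE)
  expect_equal(delta_energy_local(st, 1, old + 0.05, ff), 0)
})

test_that("Metropolis acceptance matches the Bernoulli oracle", {
  set.seed(5)
  expect_true(all(replicate(50, metropolis_accept(-3, 298))))
  expect_true(all(replicate(50, metropolis_accept(0, 298))))
  rt <- 1.98720425e-3 * 298
  acc <- mean(replicate(10000, metropolis_accept(rt * log(2), 298)))
  expect_equal(acc, 0.5, tolerance = 0.02)
  expect_false(any(replicate(200, metropolis_accept(100, 298))))
  expect_error(metropolis_accept(1, -5), "positive")
})

test_that("trajectories are seeded, reproducible, and drift-free", {
  st <- tiny_water_state()
  ff <- tiny_ff()
  cfg <- mc_config(n_prod = 5000, n_equil = 1000, seed = 99,
                   sample_every = 50, refresh_every = 1000)
  t1 <- run_mc(st, cfg, ff = ff)
  t2 <- run_mc(st, cfg, ff = ff)
  expect_identical(t1$energies, t2$energies)
  expect_identical(t1$final_state$waters, t2$final_state$waters)
  expect_equal(nrow(t1$energies), 100) # floor(n_prod / sample_every)
  expect_lt(t1$max_drift, 1e-6)
  expect_true(t1$acceptance >= 0 && t1$acceptance <= 1)

  # n_prod = 0: empty series, state changed only by equilibration
  t0 <- run_mc(st, mc_config(n_prod = 0, n_equil = 100, seed = 1), ff = ff)
  expect_equal(nrow(t0$energies), 0)

  # running-sum bookkeeping agrees with a fresh total at the end
  ef <- total_energy(t1$final_state, ff)$total
  expect_equal(tail(t1$energies$total, 1), ef, tolerance = 1e-6)
})

test_that("equilibrated pure water is physically sane at 298 K", {
  st <- tiny_water_state()
  ff <- tiny_ff()
  tr <- run_mc(st, mc_config(n_prod = 40000, n_equil = 40000, seed = 3,
                             sample_every = 50), ff = ff)
  # acceptance with the reference +/-0.13 A, +/-10 deg amplitudes
  expect_gt(tr$acceptance, 0.35)
  expect_lt(tr$acceptance, 0.65)
  # condensed-phase water-water energy per molecule is negative
  per <- mean(tr$energies$e_ww) / n_waters(st)
  expect_lt(per, -5)
  # stable over production: halves agree (no monotone drift)
  half <- nrow(tr$energies) %/% 2
  m1 <- mean(tr$energies$e_ww[seq_len(half)])
  m2 <- mean(tr$energies$e_ww[-seq_len(half)])
  expect_lt(abs(m1 - m2), 0.1 * abs(m1))
})
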