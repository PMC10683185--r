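# Synthetic-structure generator: tube lattice, charge assignment, the
# sulfasalazine fixture, complex placement and solvation.

test_that("capped (9,0) tube has the published composition and dimensions", {
  s <- build_bnnt(n = 9, rows = 22, bond_length = 1.45, cap = TRUE)
  tab <- table(s$atoms$element)
  expect_equal(unname(tab[["B"]]), 99)
  expect_equal(unname(tab[["N"]]), 99)
  expect_equal(unname(tab[["H"]]), 18)

  bn <- s$atoms$element %in% c("B", "N")
  r <- sqrt(s$atoms$x[bn]^2 + s$atoms$y[bn]^2)
  expect_true(all(r > 3.5 & r < 3.8))
  len <- diff(range(s$atoms$z[bn]))
  expect_gt(len, 21.6)
  expect_lt(len, 23.6)
  expect_equal(s$axis, c(0, 0, 1))
})

test_that("ideal rolled lattice: every B-N bond equals the bond length", {
  s <- build_bnnt(n = 9, rows = 12, bond_length = 1.47, cap = FALSE)
  p <- as.matrix(s$atoms[, c("x", "y", "z")])
  el <- s$atoms$element
  d <- as.matrix(dist(p))
  diag(d) <- Inf
  bonds <- d[el == "B", el == "N"]
  bonded <- bonds[bonds < 1.6]
  expect_true(length(bonded) > 0)
  expect_equal(max(abs(bonded - 1.47)), 0, tolerance = 1e-6)
})

test_that("lattice topology: interior B atoms have exactly 3 N neighbours", {
  s <- build_bnnt(n = 9, rows = 12)
  p <- as.matrix(s$atoms[, c("x", "y", "z")])
  el <- s$atoms$element
  d <- as.matrix(dist(p))
  zr <- range(s$atoms$z[el %in% c("B", "N")])
  for (i in which(el == "B")) {
    nn <- sum(d[i, el == "N"] < 1.6)
    rim <- abs(p[i, 3] - zr[1]) < 0.1 || abs(p[i, 3] - zr[2]) < 0.1
    expect_equal(nn, if (rim) 2L else 3L)
  }
  # every rim atom carries exactly one capping hydrogen
  for (i in which(el %in% c("B", "N"))) {
    rim <- abs(p[i, 3] - zr[1]) < 0.1 || abs(p[i, 3] - zr[2]) < 0.1
    nH <- sum(d[i, el == "H"] < 1.3)
    expect_equal(nH, if (rim) 1L else 0L)
  }
})

test_that("degenerate tube requests are rejected", {
  expect_error(build_bnnt(n = 2), "at least 3")
  expect_error(build_bnnt(rows = 0), "at least 2")
  expect_error(build_bnnt(rows = 11), "even")
  expect_error(build_bnnt(bond_length = 1.0), "1.3")
})

test_that("tube charge assignment neutralizes exactly", {
  s <- build_bnnt(n = 9, rows = 22)
  expect_equal(net_charge(s), 0, tolerance = 1e-9)
  expect_true(all(s$atoms$charge[s$atoms$element == "H"] == 0))

  s2 <- assign_bnnt_charges(s, qB = 0.92, qN = -0.92)
  expect_equal(net_charge(s2), 0, tolerance = 1e-9)
  expect_true(all(s2$atoms$charge[s2$atoms$element == "B"] == 0.92))

  # asymmetric charges: 99 * 0.03 residual spread over 18 cap hydrogens
  s3 <- assign_bnnt_charges(s, qB = 0.83, qN = -0.80)
  hq <- s3$atoms$charge[s3$atoms$element == "H"]
  expect_equal(unique(round(hq, 10)), -0.165)
  expect_equal(net_charge(s3), 0, tolerance = 1e-9)

  expect_error(assign_bnnt_charges(build_ssz_fixture("keto")), "other than")
})

test_that("sulfasalazine fixture has the published inventory and charges", {
  for (tt in c("keto", "enol")) {
    z <- build_ssz_fixture(tt)
    expect_equal(nrow(z$atoms), 42)
    tab <- table(z$atoms$element)
    expect_equal(as.integer(tab[c("C", "O", "N", "S", "H")]), c(18L, 5L, 4L, 1L, 14L))
    expect_equal(net_charge(z), 0, tolerance = 1e-6)
    p <- as.matrix(z$atoms[, c("x", "y", "z")])
    expect_gt(min(dist(p)), 0.5)
  }
  k <- build_ssz_fixture("keto")
  expect_equal(k$atoms$charge[k$atoms$role %in% "S"], 0.90)
  expect_equal(unique(k$atoms$charge[k$atoms$role %in% "O_S"]), -0.47)
  expect_equal(k$atoms$charge[k$atoms$role %in% "O1"], -0.28)
  expect_error(build_ssz_fixture("imine"))
})

test_that("complex placement honours the requested closest contact", {
  tube <- build_bnnt()
  drug <- build_ssz_fixture("keto")
  cpx <- place_complex(tube, drug, "carbonyl_v2", gap = 2.55)
  nt <- nrow(tube$atoms)
  tp <- as.matrix(cpx$atoms[1:nt, c("x", "y", "z")])
  dp <- as.matrix(cpx$atoms[-(1:nt), c("x", "y", "z")])
  d <- nanosolv:::.cross_min_dist(tp, dp)
  # the carbonyl O sits over a B atom at the published 2.55 A contact
  o1 <- which(cpx$atoms$role[-(1:nt)] %in% "O1")
  expect_equal(min(d[cpx$atoms$element[1:nt] == "B", o1]), 2.55,
               tolerance = 0.01)
  expect_equal(min(d), 2.55, tolerance = 0.01)

  for (site in c("carbonyl_v1", "sulfonamide", "pyridine")) {
    cx <- place_complex(tube, drug, site, gap = 3.5)
    dd <- nanosolv:::.cross_min_dist(
      as.matrix(cx$atoms[1:nt, c("x", "y", "z")]),
      as.matrix(cx$atoms[-(1:nt), c("x", "y", "z")]))
    expect_equal(min(dd), 3.5, tolerance = 0.05)
  }

  # placement is deterministic: no RNG involved
  expect_identical(place_complex(tube, drug, "sulfonamide", gap = 3.0),
                   place_complex(tube, drug, "sulfonamide", gap = 3.0))
  expect_error(place_complex(tube, drug, "pyridine", gap = 1.5), "2, 5")
  expect_error(place_complex(drug, drug, "pyridine", gap = 3), "axis")
})

test_that("solvation reaches the requested density", {
  # 0.993 g/cm^3 -> 0.0332 molecules/A^3
  st <- solvate(NULL, box_spec(12.4), seed = 1)
  expect_true(abs(n_waters(st) - 63) <= 1)
  st2 <- solvate(NULL, box_spec(20), seed = 2)
  rho <- n_waters(st2) * 18.0153 / 6.02214076e23 / (20e-8)^3
  expect_lt(abs(rho - 0.993) / 0.993, 0.02)
})

test_that("solvation carves out the solute and stays reproducible", {
  z <- build_ssz_fixture("keto")
  st <- solvate(z, box_spec(28), seed = 5)
  st_empty <- solvate(NULL, box_spec(28), seed = 5)
  expect_lt(n_waters(st), n_waters(st_empty))
  sp <- as.matrix(z$atoms[, c("x", "y", "z")])
  dmin <- min(nanosolv:::.cross_min_dist(st$waters[, 1:3], sp))
  expect_gte(dmin, 2.6)

  # water geometry is the rigid three-site one
  w <- st$waters[1, ]
  oh1 <- sqrt(sum((w[4:6] - w[1:3])^2))
  oh2 <- sqrt(sum((w[7:9] - w[1:3])^2))
  expect_equal(oh1, 0.9572, tolerance = 1e-10)
  expect_equal(oh2, 0.9572, tolerance = 1e-10)
  ang <- acos(sum((w[4:6] - w[1:3]) * (w[7:9] - w[1:3])) / oh1 / oh2) * 180 / pi
  expect_equal(ang, 104.52, tolerance = 1e-8)

  # identical seeds give bit-identical states
  expect_identical(solvate(z, box_spec(28), seed = 9)$waters,
                   solvate(z, box_spec(28), seed = 9)$waters)
  expect_false(identical(solvate(z, box_spec(28), seed = 9)$waters,
                         solvate(z, box_spec(28), seed = 10)$waters))
  expect_error(solvate(build_bnnt(), box_spec(20), seed = 1), "too small")
})
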