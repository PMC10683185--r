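# Shared fixtures and independent oracles for the test suite.

# small pure-water state (63 molecules, 12.4 Angstrom box)
tiny_water_state <- function(seed = 7) {
  solvate(NULL, box_spec(12.4), seed = seed)
}

# forcefield with a cutoff that fits the tiny box (r_c < L/2)
tiny_ff <- function(...) forcefield(cutoff = 6, ...)

# a forcefield whose cutoff exceeds any distance in the given box, so
# that cutoff conventions cannot differ between implementations
nocut_ff <- function(edge, ...) forcefield(cutoff = edge * 2, ...)

# build a nanostructure holding one rigid water
water_structure <- function(origin = c(0, 0, 0), name = "w") {
  wm <- water_model()
  tmpl <- rbind(c(0, 0, 0),
                wm$r_oh * c(sin(wm$angle_hoh / 2 * pi / 180), 0,
                            cos(wm$angle_hoh / 2 * pi / 180)),
                wm$r_oh * c(-sin(wm$angle_hoh / 2 * pi / 180), 0,
                            cos(wm$angle_hoh / 2 * pi / 180)))
  nanostructure(c("O", "H", "H"), sweep(tmpl, 2, -origin),
                charge = c(wm$qO, wm$qH, wm$qH),
                lj_label = c("O_W", "H_W", "H_W"), name = name)
}

# Independent all-pairs brute-force energy oracle for a simulation
# state: plain R double loops, no cutoff, minimum image on every
# site pair anchored at the water O (and per solute atom), exactly the
# published pair potential.  Used to check the compiled kernels.
brute_force_energy <- function(state, ff) {
  L <- state$box_edge
  k <- ff$coulomb_constant
  wm <- ff$water
  qs <- c(wm$qO, wm$qH, wm$qH)
  W <- state$waters
  n <- nrow(W)
  mi <- function(d) d - L * round(d / L)
  ww <- 0
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        sh <- (W[i, 1:3] - W[j, 1:3]) - mi(W[i, 1:3] - W[j, 1:3])
        rOO <- sqrt(sum((W[i, 1:3] - W[j, 1:3] - sh)^2))
        sr6 <- (wm$sigma / rOO)^6
        ww <- ww + 4 * wm$epsilon * (sr6^2 - sr6)
        for (a in 1:3) {
          for (b in 1:3) {
            dv <- W[i, (3 * a - 2):(3 * a)] - W[j, (3 * b - 2):(3 * b)] - sh
            ww <- ww + k * qs[a] * qs[b] / sqrt(sum(dv^2))
          }
        }
      }
    }
  }
  sw_elec <- 0; sw_vdw <- 0
  if (!is.null(state$solute)) {
    at <- state$solute$atoms
    lj <- nanosolv:::ff_lookup(ff, at$lj_label)
    for (s in seq_len(nrow(at))) {
      ps <- c(at$x[s], at$y[s], at$z[s])
      for (i in seq_len(n)) {
        d0 <- W[i, 1:3] - ps
        sh <- d0 - mi(d0)
        r <- sqrt(sum((d0 - sh)^2))
        em <- sqrt(lj$epsilon[s] * wm$epsilon)
        sm <- (lj$sigma[s] + wm$sigma) / 2
        sr6 <- (sm / r)^6
        sw_vdw <- sw_vdw + 4 * em * (sr6^2 - sr6)
        for (a in 1:3) {
          dv <- W[i, (3 * a - 2):(3 * a)] - ps - sh
          sw_elec <- sw_elec + k * at$charge[s] * qs[a] / sqrt(sum(dv^2))
        }
      }
    }
  }
  list(total = ww + sw_elec + sw_vdw, water_water = ww,
       solute_water = sw_elec + sw_vdw, elec = sw_elec, vdw = sw_vdw)
}

# Annihilation of a weak neutral LJ particle (epsilon 0.02, sigma 1.5;
# sigma_mix with water O is still 2.33 A) in the 63-water box, plus an
# independent Widom-insertion estimate of the same excess chemical
# potential computed in plain R from an unrelated pure-water trajectory.
# The particle's local environment decorrelates over thousands of moves,
# so windows are long and weak coupling keeps the exponential averages
# in their statistically honest regime.
lj_particle_mu <- function(n_prod = 1e6, n_equil = 2e5, seed = 5,
                           windows = c(1, 0.7, 0.45, 0.25, 0.1, 0)) {
  lj <- nanostructure("X", matrix(0, 1, 3), lj_label = "LJX", name = "lj")
  ff <- tiny_ff(sites = data.frame(label = "LJX", epsilon = 0.02,
                                   sigma = 1.5))
  st <- solvate(lj, box_spec(12.4), seed = 22, carve = 1.2)
  res <- suppressWarnings(
    run_annihilation(st, lambda_schedule(windows),
                     mc_config(n_prod = n_prod, n_equil = n_equil,
                               seed = seed, sample_every = 200),
                     spec = mc_move_spec(0.35, 25), ff = ff))
  list(state = st, ff = ff, mu = -res$dg_sol, se = res$se, result = res)
}

widom_mu <- function(state, n_ins = 1000, eps = 0.02, sig = 1.5,
                     widom_seed = 77) {
  stw <- state
  stw$solute <- NULL
  tr <- run_mc(stw, mc_config(n_prod = 2e5, n_equil = 2e4, seed = 8,
                              sample_every = 100, coord_every = 200),
               mc_move_spec(0.35, 25), ff = tiny_ff())
  rt <- 1.98720425e-3 * 298
  L <- state$box_edge
  wm <- water_model()
  me <- sqrt(eps * wm$epsilon)
  ms <- (sig + wm$sigma) / 2
  set.seed(widom_seed)
  block <- numeric(dim(tr$coords)[1])
  for (s in seq_len(dim(tr$coords)[1])) {
    O <- tr$coords[s, , ]
    ins <- matrix(runif(3 * n_ins, -L / 2, L / 2), n_ins, 3)
    acc <- 0
    for (k in seq_len(n_ins)) {
      d <- sweep(O, 2, ins[k, ])
      d <- d - L * round(d / L)
      sr6 <- (ms^2 / rowSums(d^2))^3
      acc <- acc + exp(-sum(4 * me * (sr6^2 - sr6)) / rt)
    }
    block[s] <- acc / n_ins
  }
  nb <- 10
  bm <- colMeans(matrix(block[seq_len(nb * (length(block) %/% nb))],
                        ncol = nb))
  list(mu = -rt * log(mean(block)),
       se = rt * sd(bm) / sqrt(nb) / mean(block))
}
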