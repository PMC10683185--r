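# Canonical-ensemble Metropolis sampling over rigid waters around a fixed
# solute.  The production loop lives in compiled code (src/engine.cpp) and
# draws from R's RNG stream, so runs are bit-identical for a given seed.
# The R-level propose_move / delta_energy_local / metropolis_accept
# functions implement the identical conventions and exist so the engine's
# ingredients can be tested against independent recomputation.

#' Monte Carlo move amplitudes
#'
#' @param d_translate maximum per-axis displacement in Angstrom.  The
#'   reference protocol translates a randomly selected water within
#'   +/- 0.13 Angstrom per Cartesian axis.
#' @param d_rotate maximum rotation in degrees (about a uniformly random
#'   axis through the molecule's O atom).
#' @param target_acceptance nominal acceptance fraction these amplitudes
#'   were tuned for (recorded, not enforced).
#' @export
mc_move_spec <- function(d_translate = 0.13, d_rotate = 10,
                         target_acceptance = 0.5) {
  if (d_translate <= 0) stop("'d_translate' must be positive")
  if (d_rotate <= 0 || d_rotate > 180)
    stop("'d_rotate' must lie in (0, 180] degrees")
  structure(list(d_translate = d_translate, d_rotate = d_rotate,
                 target_acceptance = target_acceptance),
            class = "mc_move_spec")
}

#' Monte Carlo run configuration
#'
#' @param n_prod number of production configurations (attempted moves).
#' @param n_equil number of equilibration configurations discarded before
#'   sampling; defaults to 10% of production.
#' @param temperature Kelvin.
#' @param seed integer seed (required; all randomness derives from it).
#' @param sample_every record the energy breakdown every this many
#'   production configurations.
#' @param coord_every record water coordinates every this many production
#'   configurations (0 = never).
#' @param coord_full record all nine water site coordinates instead of
#'   the oxygen only?
#' @param refresh_every recompute the total energy from scratch every this
#'   many moves to bound floating-point drift of the running sum.
#' @export
mc_config <- function(n_prod, n_equil = ceiling(n_prod / 10),
                      temperature = 298, seed, sample_every = 100,
                      coord_every = 0, coord_full = FALSE,
                      refresh_every = 1e5) {
  if (missing(seed)) stop("'seed' is required for reproducibility")
  if (n_prod < 0 || n_equil < 0) stop("configuration counts must be >= 0")
  if (temperature <= 0) stop("'temperature' must be positive")
  structure(list(n_prod = n_prod, n_equil = n_equil,
                 temperature = temperature, seed = as.integer(seed),
                 sample_every = as.integer(sample_every),
                 coord_every = as.integer(coord_every),
                 coord_full = isTRUE(coord_full),
                 refresh_every = refresh_every),
            class = "mc_config")
}

#' Propose a rigid-body water move
#'
#' Selects one water uniformly, translates it by independent uniform
#' per-axis displacements in \[-d, +d\] and rotates it by a uniform angle
#' in \[-theta, +theta\] about a uniformly random axis through its O
#' atom, then wraps the molecule into the box.  The proposal is symmetric
#' (sign-symmetric translation and rotation), as Metropolis sampling
#' requires.  Draw order: molecule index, tx, ty, tz, axis z, axis phi,
#' angle.  Uses the current R RNG stream.
#'
#' @param state a `simulation_state` with at least one water.
#' @param spec an [mc_move_spec()].
#' @return list with `index` and `coords` (3 x 3 matrix: O, H1, H2 rows).
#' @export
propose_move <- function(state, spec = mc_move_spec()) {
  n <- nrow(state$waters)
  if (n < 1) stop("state has no waters")
  i <- floor(runif(1) * n) + 1
  if (i > n) i <- n
  tr <- (2 * runif(3) - 1) * spec$d_translate
  z <- 2 * runif(1) - 1
  phi <- 2 * pi * runif(1)
  ang <- (2 * runif(1) - 1) * spec$d_rotate * pi / 180
  s <- sqrt(max(0, 1 - z^2))
  axis <- c(s * cos(phi), s * sin(phi), z)
  w <- matrix(state$waters[i, ], 3, 3, byrow = TRUE)
  o <- w[1, ] + tr
  R <- .axis_angle(axis, ang)
  h <- sweep(w[2:3, , drop = FALSE], 2, w[1, ]) %*% t(R)
  new <- rbind(o, o + h[1, ], o + h[2, ])
  L <- state$box_edge
  sh <- L * floor(new[1, ] / L + 0.5)
  new <- sweep(new, 2, sh)
  dimnames(new) <- list(c("O", "H1", "H2"), c("x", "y", "z"))
  list(index = i, coords = new)
}

# energy of water i with the solute and all other waters, same
# conventions as the compiled engine (R reference implementation)
.water_env_energy <- function(state, i, coords, ff, lambda = 1,
                              softcore_alpha = 0.5) {
  L <- state$box_edge
  k <- ff$coulomb_constant
  wm <- ff$water
  e <- 0
  # solute term (full sum, minimum image per solute atom vs water O)
  if (!is.null(state$solute)) {
    sa <- solute_arrays(state$solute, ff)
    dO <- matrix(coords[1, ], nrow(sa$pos), 3, byrow = TRUE) - sa$pos
    sh <- .mi_shift(dO, L)
    qs <- c(wm$qO, wm$qH, wm$qH)
    for (a in 1:3) {
      dv <- matrix(coords[a, ], nrow(sa$pos), 3, byrow = TRUE) - sa$pos - sh
      r <- sqrt(rowSums(dv^2))
      e <- e + lambda * sum(k * sa$q * qs[a] / r)
    }
    rO6 <- rowSums((dO - sh)^2)^3
    mix <- combine_lj(sa$eps, sa$sig, wm$epsilon, wm$sigma)
    s6 <- mix$sigma^6
    denom <- softcore_alpha * (1 - lambda) * s6 + rO6
    e <- e + lambda * sum(4 * mix$epsilon * ((s6 / denom)^2 - s6 / denom))
  }
  # water-water term with O-O centre cutoff
  others <- setdiff(seq_len(nrow(state$waters)), i)
  if (length(others)) {
    W <- state$waters[others, , drop = FALSE]
    dO <- matrix(coords[1, ], length(others), 3, byrow = TRUE) -
      W[, 1:3, drop = FALSE]
    sh <- .mi_shift(dO, L)
    rOO <- sqrt(rowSums((dO - sh)^2))
    inc <- rOO <= ff$cutoff
    if (any(inc)) {
      sr6 <- (wm$sigma / rOO[inc])^6
      e <- e + sum(4 * wm$epsilon * (sr6^2 - sr6))
      qs <- c(wm$qO, wm$qH, wm$qH)
      for (a in 1:3) {
        for (b in 1:3) {
          dv <- matrix(coords[a, ], sum(inc), 3, byrow = TRUE) -
            W[inc, (3 * b - 2):(3 * b), drop = FALSE] - sh[inc, , drop = FALSE]
          r <- sqrt(rowSums(dv^2))
          e <- e + sum(k * qs[a] * qs[b] / r)
        }
      }
    }
  }
  e
}

#' Local energy change of a proposed move
#'
#' Energy difference E(after) - E(before) computed from only the moved
#' molecule's interactions with the solute and all other waters.  By
#' construction this equals the difference of [total_energy()] between
#' the two configurations (only the moved molecule's pair terms change).
#'
#' @param state a `simulation_state`.
#' @param index water index.
#' @param new_coords 3 x 3 matrix of proposed O, H1, H2 coordinates.
#' @param ff a [forcefield()].
#' @param lambda,softcore_alpha solute-water coupling (see
#'   [total_energy()]).
#' @return kcal/mol.
#' @export
delta_energy_local <- function(state, index, new_coords, ff = forcefield(),
                               lambda = 1, softcore_alpha = 0.5) {
  old <- matrix(state$waters[index, ], 3, 3, byrow = TRUE)
  e_old <- .water_env_energy(state, index, old, ff, lambda, softcore_alpha)
  e_new <- .water_env_energy(state, index, new_coords, ff, lambda,
                             softcore_alpha)
  e_new - e_old
}

#' Metropolis acceptance rule
#'
#' Accepts with probability `min(1, exp(-delta_e / RT))`,
#' R = 1.98720425e-3 kcal/(mol K).  One uniform variate is drawn from the
#' current R RNG stream per call.
#'
#' @param delta_e energy change in kcal/mol.
#' @param temperature Kelvin.
#' @return logical.
#' @export
metropolis_accept <- function(delta_e, temperature = 298) {
  if (temperature <= 0) stop("'temperature' must be positive")
  u <- runif(1)
  delta_e <= 0 || u < exp(-delta_e / (.RGAS * temperature))
}

#' Run a Metropolis Monte Carlo simulation
#'
#' Samples the canonical ensemble of rigid waters around the (fixed)
#' solute of `state`.  `config$n_equil` configurations are discarded,
#' then `config$n_prod` are generated with the energy breakdown recorded
#' every `sample_every` moves.  The energy is tracked as a running sum of
#' local differences with a periodic full refresh; the maximum observed
#' drift is reported.  A fixed seed gives a bit-identical trajectory.
#'
#' @param state a solvated `simulation_state` (see [solvate()]).
#' @param config an [mc_config()].
#' @param spec an [mc_move_spec()].
#' @param ff a [forcefield()].
#' @param lambda solute-water coupling (1 = fully interacting).
#' @param lambda_neighbors optional vector of coupling values at which
#'   the solute-water energy gap is recorded at every sample (used by
#'   [run_annihilation()] for perturbation estimates).
#' @param softcore_alpha soft-core LJ parameter.
#' @return An `mc_trajectory`: sampled energies (data frame with columns
#'   step, total, e_soln, elec, vdw, e_ww), acceptance ratios, optional
#'   thinned coordinates, perturbation gaps, the final state, and the
#'   maximum running-energy drift.
#' @export
run_mc <- function(state, config, spec = mc_move_spec(), ff = forcefield(),
                   lambda = 1, lambda_neighbors = NULL,
                   softcore_alpha = 0.5) {
  stopifnot(inherits(state, "simulation_state"), inherits(config, "mc_config"))
  sa <- solute_arrays(state$solute, ff)
  res <- with_seed(config$seed,
    cpp_run_mc(state$waters, sa$pos, sa$q, sa$eps, sa$sig, ff$water,
               state$box_edge, ff$cutoff, ff$coulomb_constant,
               config$temperature, spec$d_translate, spec$d_rotate,
               config$n_equil, config$n_prod, config$sample_every,
               config$coord_every, config$coord_full, config$refresh_every,
               lambda, softcore_alpha,
               if (is.null(lambda_neighbors)) numeric(0) else lambda_neighbors))
  en <- as.data.frame(res$energies)
  names(en) <- c("step", "total", "e_soln", "elec", "vdw", "e_ww")
  coords <- NULL
  if (res$n_coord_samples > 0) {
    nw <- nrow(state$waters)
    coords <- array(NA_real_, c(res$n_coord_samples, nw, ncol(res$coords)))
    for (s in seq_len(res$n_coord_samples))
      coords[s, , ] <- res$coords[((s - 1) * nw + 1):(s * nw), , drop = FALSE]
  }
  final <- state
  final$waters[] <- res$waters_final
  gaps <- if (length(res$gaps)) res$gaps else NULL
  if (!is.null(gaps)) colnames(gaps) <- format(lambda_neighbors)
  structure(list(energies = en, acceptance = res$acceptance,
                 acceptance_equil = res$acceptance_equil,
                 coords = coords, gaps = gaps, lambda = lambda,
                 lambda_neighbors = lambda_neighbors,
                 final_state = final, max_drift = res$max_drift,
                 config = config, spec = spec),
            class = "mc_trajectory")
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat(sprintf("<mc_trajectory> %g equil + %g prod moves, %d energy samples\n",
              x$config$n_equil, x$config$n_prod, nrow(x$energies)))
  cat(sprintf("  acceptance: %.3f (equil %.3f); max running-energy drift %.2e kcal/mol\n",
              x$acceptance, x$acceptance_equil, x$max_drift))
  if (nrow(x$energies))
    cat(sprintf("  mean total energy: %.3f kcal/mol\n", mean(x$energies$total)))
  invisible(x)
}

#' @export
summary.mc_trajectory <- function(object, nblocks = 10, ...) {
  en <- object$energies
  if (!nrow(en)) return(invisible(NULL))
  stat <- function(v) c(mean = mean(v), se = block_se(v, nblocks))
  out <- t(vapply(en[, c("total", "e_soln", "elec", "vdw", "e_ww")], stat,
                  numeric(2)))
  res <- list(stats = out, acceptance = object$acceptance,
              n_samples = nrow(en))
  class(res) <- "summary.mc_trajectory"
  res
}

#' @export
print.summary.mc_trajectory <- function(x, ...) {
  cat(sprintf("Monte Carlo summary (%d samples, acceptance %.3f)\n",
              x$n_samples, x$acceptance))
  cat("means with block-averaged standard errors (kcal/mol):\n")
  for (nm in rownames(x$stats))
    cat(sprintf("  %-6s %12.4f +/- %.4f\n", nm, x$stats[nm, "mean"],
                x$stats[nm, "se"]))
  invisible(x)
}

#' @export
plot.mc_trajectory <- function(x, which = "total", ...) {
  en <- x$energies
  plot(en$step, en[[which]], type = "l", xlab = "production move",
       ylab = sprintf("%s energy (kcal/mol)", which), ...)
  invisible(x)
}
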