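# Pairwise nonbonded energetics: three-site water, solute-water
# Lennard-Jones + Coulomb with Lorentz-Berthelot mixing, minimum image,
# cutoffs and the energy decomposition used throughout.

#' Three-site water model parameters
#'
#' Rigid three-site water: a single Lennard-Jones site on oxygen, point
#' charges on all three sites, O-H 0.9572 Angstrom and H-O-H 104.52
#' degrees.  These are the standard values for the transferable
#' three-site intermolecular potential.
#'
#' @param epsilon,sigma oxygen LJ parameters (kcal/mol, Angstrom).
#' @param qO,qH site charges in e; they must sum to zero per molecule.
#' @param r_oh,angle_hoh rigid geometry (Angstrom, degrees).
#' @export
water_model <- function(epsilon = 0.1521, sigma = 3.1507, qO = -0.834,
                        qH = 0.417, r_oh = 0.9572, angle_hoh = 104.52) {
  if (abs(qO + 2 * qH) > 1e-9)
    stop("water charges must sum to zero per molecule")
  list(epsilon = epsilon, sigma = sigma, qO = qO, qH = qH, r_oh = r_oh,
       angle_hoh = angle_hoh)
}

#' Construct the nonbonded force-field registry
#'
#' Holds the per-site Lennard-Jones registry (shipped with the package as
#' a CSV of reference parameters for nanotube B/N, solute C/N/S/H sites
#' and the water model), the Coulomb constant and the cutoff convention.
#' Any entry can be overridden via `sites`.  Note that the reference "H"
#' site carries the sigma value exactly as published (0.094 Angstrom,
#' probably a misprint); override it here if desired.
#'
#' @param cutoff molecule-centre spherical cutoff in Angstrom for
#'   water-water (and generic molecule-molecule) interactions.
#'   Solute-water interactions are always summed in full under minimum
#'   image, because an extended solute has no meaningful single centre.
#' @param coulomb_constant electrostatic prefactor in
#'   kcal Angstrom / (mol e^2).
#' @param sites optional data frame with columns label/epsilon/sigma that
#'   replaces or extends the shipped registry.
#' @param water a [water_model()] parameter block.
#' @return An object of class `forcefield`.
#' @export
forcefield <- function(cutoff = 9.5, coulomb_constant = 332.06,
                       sites = NULL, water = water_model()) {
  if (cutoff <= 0) stop("'cutoff' must be positive")
  reg <- load_reference_table("lj")[, c("label", "epsilon", "sigma")]
  if (!is.null(sites)) {
    sites <- as.data.frame(sites)
    for (i in seq_len(nrow(sites))) {
      j <- match(sites$label[i], reg$label)
      if (is.na(j)) reg <- rbind(reg, sites[i, c("label", "epsilon", "sigma")])
      else reg[j, c("epsilon", "sigma")] <- sites[i, c("epsilon", "sigma")]
    }
  }
  if (anyDuplicated(reg$label)) stop("duplicate site labels")
  if (any(reg$epsilon < 0) || any(reg$sigma < 0))
    stop("epsilon and sigma must be non-negative")
  # keep the water LJ site in sync with the water model block
  reg[reg$label == "O_W", c("epsilon", "sigma")] <-
    list(water$epsilon, water$sigma)
  structure(list(sites = reg, coulomb_constant = coulomb_constant,
                 cutoff = cutoff, water = water),
            class = "forcefield")
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf("<forcefield> %d LJ sites, k_coulomb = %.2f, cutoff = %.1f A\n",
              nrow(x$sites), x$coulomb_constant, x$cutoff))
  print(x$sites, row.names = FALSE)
  invisible(x)
}

ff_lookup <- function(ff, labels) {
  i <- match(labels, ff$sites$label)
  if (anyNA(i))
    stop("unresolvable LJ label(s): ",
         paste(unique(labels[is.na(i)]), collapse = ", "))
  list(epsilon = ff$sites$epsilon[i], sigma = ff$sites$sigma[i])
}

#' Lorentz-Berthelot combining rule
#'
#' Cross-interaction parameters: geometric mean of epsilon, arithmetic
#' mean of sigma.
#'
#' @param epsilon_i,sigma_i,epsilon_j,sigma_j site parameters.
#' @return A list with `epsilon` and `sigma` (vectorized).
#' @export
combine_lj <- function(epsilon_i, sigma_i, epsilon_j, sigma_j) {
  list(epsilon = sqrt(epsilon_i * epsilon_j),
       sigma = (sigma_i + sigma_j) / 2)
}

#' Convert epsilon/sigma to A/C Lennard-Jones coefficients
#'
#' `A = 4 eps sigma^12`, `C = 4 eps sigma^6`, so that
#' `A/r^12 - C/r^6 = 4 eps [(sigma/r)^12 - (sigma/r)^6]`.
#'
#' @param epsilon,sigma LJ parameters.
#' @return list with components `A` (kcal A^12/mol) and `C` (kcal A^6/mol).
#' @export
ac_from_epsilon_sigma <- function(epsilon, sigma) {
  list(A = 4 * epsilon * sigma^12, C = 4 * epsilon * sigma^6)
}

#' @rdname ac_from_epsilon_sigma
#' @param A,C repulsive and attractive coefficients.
#' @export
epsilon_sigma_from_ac <- function(A, C) {
  eps <- ifelse(A > 0, C^2 / (4 * A), 0)
  sig <- ifelse(C > 0, (A / C)^(1 / 6), 0)
  list(epsilon = eps, sigma = sig)
}

#' Lennard-Jones + Coulomb pair energy
#'
#' `4 eps [(sigma/r)^12 - (sigma/r)^6] + k q_i q_j / r` in kcal/mol.
#'
#' @param r site-site distance in Angstrom (must be positive).
#' @param epsilon,sigma mixed LJ parameters for the pair.
#' @param qi,qj site charges in e.
#' @param k_coulomb electrostatic prefactor.
#' @export
pair_energy <- function(r, epsilon, sigma, qi = 0, qj = 0,
                        k_coulomb = 332.06) {
  if (any(r <= 0)) stop("'r' must be positive")
  sr6 <- (sigma / r)^6
  4 * epsilon * (sr6^2 - sr6) + k_coulomb * qi * qj / r
}

# minimum-image lattice shift for a displacement vector
.mi_shift <- function(d, L) L * round(d / L)

#' Interaction energy between two rigid molecules
#'
#' Sums [pair_energy()] over all cross pairs of two structures under the
#' minimum-image convention, treating each structure as one molecule: if
#' the centre-centre (centroid) minimum-image distance exceeds the
#' cutoff the pair is skipped entirely, otherwise all site pairs are
#' included with the molecule image shift applied to the second body.
#'
#' @param group_a,group_b `nanostructure` objects with resolvable LJ
#'   labels.
#' @param box_edge cubic box edge in Angstrom; `Inf` for no periodicity.
#' @param ff a [forcefield()].
#' @return list with `total`, `electrostatic` and `vdw` (kcal/mol).
#' @export
interaction_energy <- function(group_a, group_b, box_edge = Inf,
                               ff = forcefield()) {
  if (is.finite(box_edge) && box_edge < 2 * ff$cutoff)
    stop("box smaller than twice the cutoff")
  pa <- atom_positions(group_a); pb <- atom_positions(group_b)
  ca <- colMeans(pa); cb <- colMeans(pb)
  d <- ca - cb
  sh <- if (is.finite(box_edge)) .mi_shift(d, box_edge) else c(0, 0, 0)
  if (sqrt(sum((d - sh)^2)) > ff$cutoff)
    return(list(total = 0, electrostatic = 0, vdw = 0))
  pb <- sweep(pb, 2, -sh) # bring b's image next to a
  la <- ff_lookup(ff, group_a$atoms$lj_label)
  lb <- ff_lookup(ff, group_b$atoms$lj_label)
  eps <- sqrt(outer(la$epsilon, lb$epsilon))
  sig <- outer(la$sigma, lb$sigma, "+") / 2
  qq <- outer(group_a$atoms$charge, group_b$atoms$charge)
  r <- .cross_min_dist(pa, pb)
  sr6 <- (sig / r)^6
  vdw <- sum(4 * eps * (sr6^2 - sr6))
  elec <- sum(ff$coulomb_constant * qq / r)
  list(total = vdw + elec, electrostatic = elec, vdw = vdw)
}

# flatten a solute into the arrays the C++ kernels expect
solute_arrays <- function(solute, ff) {
  if (is.null(solute)) {
    return(list(pos = matrix(0, 0, 3), q = numeric(0), eps = numeric(0),
                sig = numeric(0)))
  }
  lj <- ff_lookup(ff, solute$atoms$lj_label)
  list(pos = atom_positions(solute), q = solute$atoms$charge,
       eps = lj$epsilon, sig = lj$sigma)
}

#' Total potential energy of a simulation state
#'
#' Decomposes the configurational energy of a rigid-body state into the
#' solute-water term (with its electrostatic and van der Waals parts) and
#' the water-water term.  There is no intramolecular term: all bodies are
#' rigid.  Water-water pairs use the molecule-centre (O-O) spherical
#' cutoff; solute-water interactions are summed in full under minimum
#' image.
#'
#' @param state a `simulation_state`.
#' @param ff a [forcefield()].
#' @param lambda solute-water coupling in \[0, 1\] (1 = fully coupled);
#'   charges scale linearly, the LJ term uses soft-core coupling.
#' @param softcore_alpha soft-core parameter.
#' @return An `energy_breakdown`: list with `total`, `solute_water`,
#'   `water_water`, `electrostatic_in_soln`, `vdw_in_soln` (kcal/mol).
#' @export
total_energy <- function(state, ff = forcefield(), lambda = 1,
                         softcore_alpha = 0.5) {
  sa <- solute_arrays(state$solute, ff)
  e <- cpp_state_energy(state$waters, sa$pos, sa$q, sa$eps, sa$sig,
                        ff$water, state$box_edge, ff$cutoff,
                        ff$coulomb_constant, lambda, softcore_alpha)
  energy_breakdown(e[["sw_elec"]], e[["sw_vdw"]], e[["ww"]])
}

energy_breakdown <- function(sw_elec, sw_vdw, ww) {
  structure(list(total = sw_elec + sw_vdw + ww,
                 solute_water = sw_elec + sw_vdw,
                 water_water = ww,
                 electrostatic_in_soln = sw_elec,
                 vdw_in_soln = sw_vdw),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0("<energy_breakdown> (kcal/mol)\n",
                     "  total        %12.4f\n",
                     "  solute-water %12.4f (elec %.4f, vdW %.4f)\n",
                     "  water-water  %12.4f\n"),
              x$total, x$solute_water, x$electrostatic_in_soln,
              x$vdw_in_soln, x$water_water))
  invisible(x)
}
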