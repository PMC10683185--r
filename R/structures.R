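#' Create a rigid molecular structure
#'
#' The basic container for a rigid body: an ordered set of atoms with
#' Cartesian coordinates (Angstrom), partial charges (elementary charge)
#' and a Lennard-Jones site label that must resolve in a [forcefield()]
#' registry.  Generated structures are charge-neutral by construction.
#'
#' @param element character vector of chemical symbols.
#' @param position numeric matrix (n x 3) of coordinates in Angstrom.
#' @param charge numeric vector of partial charges in units of e.
#' @param lj_label character vector of force-field site labels.
#' @param role optional character vector tagging chemically meaningful
#'   atoms (e.g. `"O1"` for the carbonyl oxygen); `NA` elsewhere.
#' @param name identifier for the structure.
#' @param axis optional unit 3-vector giving the body axis (set for
#'   nanotubes, used by [cylindrical_rdf()] and [place_complex()]).
#' @param rigid logical flag; all structures handled here are rigid.
#' @param total_charge declared net charge; construction fails if the
#'   atomic charges do not sum to it within 1e-6 e.
#' @return An object of class `nanostructure`: a list with elements
#'   `atoms` (data frame with columns element, x, y, z, charge, lj_label,
#'   role), `name`, `axis`, `rigid`.
#' @export
nanostructure <- function(element, position, charge = 0, lj_label = element,
                          role = NA_character_, name = "structure",
                          axis = NULL, rigid = TRUE, total_charge = 0) {
  position <- as.matrix(position)
  if (ncol(position) != 3L)
    stop("'position' must be an n x 3 matrix")
  n <- nrow(position)
  if (length(element) != n)
    stop("'element' length does not match number of positions")
  if (!all(is.finite(position)))
    stop("all position components must be finite")
  atoms <- data.frame(element = as.character(element),
                      x = position[, 1], y = position[, 2], z = position[, 3],
                      charge = rep_len(as.numeric(charge), n),
                      lj_label = rep_len(as.character(lj_label), n),
                      role = rep_len(as.character(role), n),
                      stringsAsFactors = FALSE)
  s <- structure(list(atoms = atoms, name = name, axis = axis, rigid = rigid),
                 class = "nanostructure")
  validate_nanostructure(s, total_charge = total_charge)
  s
}

validate_nanostructure <- function(s, total_charge = 0, min_dist = 0.5) {
  q <- sum(s$atoms$charge)
  if (abs(q - total_charge) > 1e-6)
    stop(sprintf("net charge %.8f differs from declared total %.8f", q,
                 total_charge))
  p <- as.matrix(s$atoms[, c("x", "y", "z")])
  if (nrow(p) > 1L) {
    d <- stats::dist(p)
    if (min(d) < min_dist) {
      ij <- which(as.matrix(d) == min(d) & upper.tri(as.matrix(d)),
                  arr.ind = TRUE)[1, ]
      stop(sprintf("atoms %d and %d are %.3f Angstrom apart (< %.1f)",
                   ij[1], ij[2], min(d), min_dist))
    }
  }
  if (!is.null(s$axis)) {
    if (length(s$axis) != 3L || abs(sqrt(sum(s$axis^2)) - 1) > 1e-8)
      stop("'axis' must be a unit 3-vector")
  }
  invisible(s)
}

#' @export
print.nanostructure <- function(x, ...) {
  cat(sprintf("<nanostructure> %s: %d atoms, net charge %+.4f e\n",
              x$name, nrow(x$atoms), sum(x$atoms$charge)))
  tab <- table(x$atoms$element)
  cat("  formula:", paste0(names(tab), as.integer(tab), collapse = " "), "\n")
  if (!is.null(x$axis))
    cat(sprintf("  axis: (%.3f, %.3f, %.3f)\n", x$axis[1], x$axis[2],
                x$axis[3]))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `nanostructure`.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Net charge of a structure
#' @param s a `nanostructure`.
#' @export
net_charge <- function(s) sum(s$atoms$charge)

atom_positions <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

translate_structure <- function(s, shift) {
  s$atoms$x <- s$atoms$x + shift[1]
  s$atoms$y <- s$atoms$y + shift[2]
  s$atoms$z <- s$atoms$z + shift[3]
  s
}

rotate_structure <- function(s, R) {
  p <- atom_positions(s) %*% t(R)
  s$atoms$x <- p[, 1]; s$atoms$y <- p[, 2]; s$atoms$z <- p[, 3]
  if (!is.null(s$axis)) s$axis <- as.numeric(R %*% s$axis)
  s
}

#' Specify a cubic simulation box
#'
#' @param edge box edge length in Angstrom.
#' @param density target water density in g/cm^3.
#' @param temperature temperature in Kelvin.
#' @return An object of class `box_spec`.
#' @export
box_spec <- function(edge = 50, density = 0.993, temperature = 298) {
  if (edge <= 0) stop("'edge' must be positive")
  if (density <= 0) stop("'density' must be positive")
  if (temperature <= 0) stop("'temperature' must be positive")
  structure(list(edge = edge, density = density, temperature = temperature),
            class = "box_spec")
}

new_simulation_state <- function(solute, waters, box_edge, temperature) {
  structure(list(solute = solute, waters = waters, box_edge = box_edge,
                 temperature = temperature),
            class = "simulation_state")
}

#' @export
print.simulation_state <- function(x, ...) {
  cat(sprintf("<simulation_state> %d waters in a %.1f Angstrom box at %.0f K\n",
              nrow(x$waters), x$box_edge, x$temperature))
  if (!is.null(x$solute))
    cat(sprintf("  solute: %s (%d atoms)\n", x$solute$name,
                nrow(x$solute$atoms)))
  invisible(x)
}

#' Number of water molecules in a simulation state
#' @param state a `simulation_state`.
#' @export
n_waters <- function(state) nrow(state$waters)
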