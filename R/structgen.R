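# Synthetic-structure generators: hydrogen-capped zigzag BN nanotube, an
# idealized sulfasalazine fixture, drug-tube complex placement, and water
# box solvation.  These make every downstream stage testable without any
# deposited coordinates.

#' Build a hydrogen-capped zigzag boron-nitride nanotube
#'
#' Constructs a zigzag (n,0) BN tube by rolling an ideal honeycomb lattice
#' onto a cylinder.  Atom rings alternate N and B along the tube axis (z);
#' the radius is chosen as \eqn{R = \sqrt{3}\,b / (4 \sin(\pi/2n))} so that
#' *every* nearest-neighbour B-N distance equals `bond_length` exactly
#' (pure arc-length rolling would shorten the circumferential bonds to
#' chords).  For n = 9 and b = 1.45 this gives R = 3.616 Angstrom, close
#' to the 3.67 Angstrom of the DFT-relaxed tube this generator emulates.
#' With `rows = 22` rings the tube has 99 B + 99 N atoms and a B/N length
#' of 22.5 Angstrom.  Both rims are zigzag edges whose single dangling
#' bond per atom is saturated with hydrogen when `cap = TRUE` (B-H 1.19,
#' N-H 1.01 Angstrom, along the severed axial bond).
#'
#' @param n chirality index (number of atoms per ring), at least 3.
#' @param rows number of B/N rings along the axis; must be even so that
#'   both rims are clean zigzag edges and B and N counts are equal.
#' @param bond_length B-N bond length in Angstrom, in \[1.3, 1.6\].
#' @param cap saturate the rims with hydrogen?
#' @param qB,qN partial charges placed on B and N (see
#'   [assign_bnnt_charges()]); defaults are the average Mulliken charges
#'   of the pristine tube.
#' @return A `nanostructure` with `axis = c(0, 0, 1)`, centred at the
#'   origin.
#' @export
build_bnnt <- function(n = 9, rows = 22, bond_length = 1.45, cap = TRUE,
                       qB = 0.83, qN = -0.83) {
  if (n < 3) stop("'n' must be at least 3")
  if (bond_length < 1.3 || bond_length > 1.6)
    stop("'bond_length' must lie in [1.3, 1.6] Angstrom")
  if (rows < 2) stop("'rows' must be at least 2 (one full B and N ring)")
  if (rows %% 2 != 0)
    stop("'rows' must be even: odd counts leave a bearded (non-zigzag) rim")
  b <- bond_length
  radius <- sqrt(3) * b / (4 * sin(pi / (2 * n)))

  # ring k (k = 0 .. rows-1): z spacing to ring k+1 is b/2 for even k and
  # b for odd k; angular offset pattern has period 4 (offset, base, base,
  # offset); elements alternate starting with N at the bottom rim.
  z <- cumsum(c(0, ifelse(seq_len(rows - 1) %% 2 == 1, b / 2, b)))
  z <- z - mean(range(z))
  offset <- (seq_len(rows) - 1) %% 4 %in% c(0, 3)
  elem_ring <- ifelse((seq_len(rows) - 1) %% 2 == 0, "N", "B")

  ang0 <- 2 * pi * (seq_len(n) - 1) / n
  el <- character(0); px <- py <- pz <- numeric(0)
  for (k in seq_len(rows)) {
    a <- ang0 + if (offset[k]) pi / n else 0
    px <- c(px, radius * cos(a)); py <- c(py, radius * sin(a))
    pz <- c(pz, rep(z[k], n))
    el <- c(el, rep(elem_ring[k], n))
  }
  if (cap) {
    # bottom rim (ring 1) misses its axial neighbour below, top rim above
    for (rim in c(1L, rows)) {
      a <- ang0 + if (offset[rim]) pi / n else 0
      dH <- if (elem_ring[rim] == "B") 1.19 else 1.01
      dz <- if (rim == 1L) -dH else dH
      px <- c(px, radius * cos(a)); py <- c(py, radius * sin(a))
      pz <- c(pz, rep(z[rim] + dz, n))
      el <- c(el, rep("H", n))
    }
  }
  lj <- c(B = "B_NT", N = "N_NT", H = "H")[el]
  s <- nanostructure(el, cbind(px, py, pz), charge = 0, lj_label = lj,
                     name = sprintf("BNNT_%d_0_r%d", n, rows),
                     axis = c(0, 0, 1))
  assign_bnnt_charges(s, qB = qB, qN = qN)
}

#' Assign partial charges to a BN nanotube
#'
#' Every B atom receives `qB`, every N atom `qN`; the cap hydrogens share
#' the residual \eqn{-(\sum q_B + \sum q_N)/n_H} equally so the total is
#' exactly zero.
#'
#' @param s a `nanostructure` containing only B, N and H atoms.
#' @param qB,qN charges in units of e.
#' @return The structure with charges replaced.
#' @export
assign_bnnt_charges <- function(s, qB = 0.83, qN = -0.83) {
  el <- s$atoms$element
  if (!all(el %in% c("B", "N", "H")))
    stop("not a BN nanotube: contains elements other than B, N, H")
  q <- ifelse(el == "B", qB, ifelse(el == "N", qN, 0))
  nh <- sum(el == "H")
  res <- sum(q)
  if (nh > 0) {
    q[el == "H"] <- -res / nh
  } else if (abs(res) > 1e-9) {
    stop("uncapped tube with unbalanced B/N charges cannot be neutralized")
  }
  s$atoms$charge <- q
  validate_nanostructure(s)
  s
}

# regular ring vertices in the xy plane
.hexagon <- function(center, start_deg = 0, radius = 1.39, nv = 6L) {
  a <- (start_deg + seq(0, by = 60, length.out = nv)) * pi / 180
  cbind(center[1] + radius * cos(a), center[2] + radius * sin(a), 0)
}

#' Build an idealized sulfasalazine fixture
#'
#' Returns a rigid 42-atom sulfasalazine molecule (C18 O5 N4 S H14) in the
#' requested tautomer with an idealized planar-backbone geometry assembled
#' from standard bond lengths (no deposited coordinates exist for the
#' system this emulates; the geometry is synthetic by design and the
#' solvation machinery is insensitive to its fine details).  Atoms with a
#' published Mulliken charge carry a `role` tag (C1, C2, O1, O2, O3,
#' N1-N4, S, O_S, H2, H3) and receive the tabulated value for the chosen
#' tautomer; both sulfonyl oxygens share the single published `O_S`
#' value.  The residual charge is spread uniformly over the twelve
#' untabulated hydrogens so the net charge is exactly zero (untabulated C
#' atoms are left at zero); the scheme is recorded in
#' `attr(, "charge_scheme")`.
#'
#' @param tautomer `"keto"` or `"enol"`.  In the enol form the phenolic
#'   proton (role H2) sits on O1; in the keto form O1 is a carbonyl and H2
#'   moves to the azo nitrogen N1.
#' @return A `nanostructure` centred at the origin.
#' @export
build_ssz_fixture <- function(tautomer = c("keto", "enol")) {
  tautomer <- match.arg(tautomer)

  el <- character(0); pos <- matrix(numeric(0), 0, 3); role <- character(0)
  add <- function(e, p, r = NA_character_) {
    el <<- c(el, e)
    pos <<- rbind(pos, matrix(p, ncol = 3, byrow = FALSE))
    role <<- c(role, rep_len(r, length(e)))
  }

  # pyridine ring centred at the origin; attachment carbon at angle 0,
  # ring nitrogen (N4) adjacent to it
  py <- .hexagon(c(0, 0))
  add(c("C", "N", "C", "C", "C", "C"), py,
      c(NA, "N4", NA, NA, NA, NA))
  ph_idx <- c(3, 4, 5, 6) # carbons bearing H (all but attachment and N4)
  hpos <- .hexagon(c(0, 0), radius = 1.39 + 1.08)[ph_idx, ]
  add(rep("H", 4), hpos)

  # sulfonamide bridge: pyridine-C(1) - N3(H) - S(=O)2 - phenyl
  n3 <- c(2.82, 0, 0)
  add("N", n3, "N3")
  add("H", c(2.315, -0.875, 0)) # H on N3 (untabulated)
  sS <- c(4.45, 0, 0)
  add("S", sS, "S")
  add("O", sS + 1.44 * c(0, 0.55, 0.835), "O_S")
  add("O", sS + 1.44 * c(0, 0.55, -0.835), "O_S")

  # para-disubstituted phenyl ring
  phc <- c(7.61, 0)
  phv <- .hexagon(phc, start_deg = 0)
  # vertices: 1 at angle 0 = para (azo side), 4 at angle 180 bonded to S
  add(rep("C", 6), phv)
  hph <- .hexagon(phc, start_deg = 0, radius = 1.39 + 1.08)[c(2, 3, 5, 6), ]
  add(rep("H", 4), hph)

  # azo bridge N1=N2 with a 30 degree kink
  n1 <- c(phc[1] + 1.39 + 1.43, 0, 0)
  n2 <- n1 + c(1.25 * cos(pi / 6), 1.25 * sin(pi / 6), 0)
  add("N", n1, "N1")
  add("N", n2, "N2")

  # salicylate ring: attachment at angle 180 of a hexagon east of N2
  sc <- c(n2[1] + 1.43 + 1.39, n2[2])
  sv <- .hexagon(sc, start_deg = 0)
  # vertex 4 (angle 180) bonds N2; vertex 3 (120) is C1 (bears O1);
  # vertex 2 (60) bears the carboxyl carbon C2; H on vertices 1, 5, 6
  add(rep("C", 6), sv, c(NA, NA, "C1", NA, NA, NA))
  hsal <- .hexagon(sc, start_deg = 0, radius = 1.39 + 1.08)[c(1, 5, 6), ]
  add(rep("H", 3), hsal)

  dir120 <- c(cos(2 * pi / 3), sin(2 * pi / 3), 0)
  dir60 <- c(cos(pi / 3), sin(pi / 3), 0)
  o1_len <- if (tautomer == "keto") 1.22 else 1.36
  o1 <- c(sv[3, 1], sv[3, 2], 0) + o1_len * dir120
  add("O", o1, "O1")
  c2 <- c(sc, 0) + (1.39 + 1.48) * dir60
  add("C", c2, "C2")
  o2 <- c2 + 1.22 * c(cos(5 * pi / 6), sin(5 * pi / 6), 0)
  add("O", o2, "O2")
  o3 <- c2 + 1.36 * c(cos(pi / 6), sin(pi / 6), 0)
  add("O", o3, "O3")
  add("H", o3 + 0.97 * c(0, 1, 0), "H3")
  if (tautomer == "enol") {
    add("H", o1 + 0.97 * c(cos(5 * pi / 6), sin(5 * pi / 6), 0), "H2")
  } else {
    add("H", n1 + 1.01 * c(0, -1, 0), "H2")
  }

  # charges: tabulated roles get their published value, residual spread
  # over untabulated hydrogens
  charges <- .ssz_role_charges(if (tautomer == "keto") "SSZ_keto" else "SSZ_enol")
  q <- rep(0, length(el))
  for (r in names(charges)) q[!is.na(role) & role == r] <- charges[[r]]
  free_h <- el == "H" & is.na(role)
  q[free_h] <- -sum(q) / sum(free_h)

  pos <- sweep(pos, 2, colMeans(pos)) # centre at origin
  lj <- ifelse(el == "C", "C",
        ifelse(el == "S", "S",
        ifelse(el == "N", "N",
        ifelse(el == "O", "O", "H"))))
  # hydrogens on carbon get the aromatic-H site; heteroatom H keep "H"
  onC <- el == "H" & is.na(role) & seq_along(el) %in% .h_on_c_indices(el, pos)
  lj[onC] <- "H_C"
  s <- nanostructure(el, pos, charge = q, lj_label = lj, role = role,
                     name = paste0("SSZ_", tautomer))
  attr(s, "charge_scheme") <-
    sprintf("tabulated roles from reference Mulliken charges (%s); residual %+.4f e spread over %d untabulated H",
            tautomer, -sum(unlist(charges)) - charges[["O_S"]],
            sum(free_h))
  s
}

# indices of H atoms whose nearest heavy atom is carbon
.h_on_c_indices <- function(el, pos) {
  heavy <- which(el != "H")
  out <- integer(0)
  for (i in which(el == "H")) {
    d <- sqrt(rowSums((pos[heavy, , drop = FALSE] -
                         matrix(pos[i, ], length(heavy), 3, TRUE))^2))
    if (el[heavy[which.min(d)]] == "C") out <- c(out, i)
  }
  out
}

.ssz_role_charges <- function(species) {
  tab <- load_reference_table("charges")
  row <- tab[tab$species == species, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown species in charge table: ", species)
  as.list(row[, setdiff(names(row), "species")])
}

#' Place a drug on the outer surface of a nanotube
#'
#' Deterministically poses a rigid drug molecule against the tube outer
#' wall so that the interaction atoms of the named site face the surface
#' with the requested closest-approach gap.  Only the closest-contact
#' atom pair and the gap are contractual; the remainder of the pose is a
#' fixed construction: the site's anchor atom is aimed at the surface
#' atom of the target element nearest the tube's axial midplane, the drug
#' is rotated so its centroid points radially outward, and it is then
#' slid along the radial direction until the minimum cross-body distance
#' equals `gap`.
#'
#' @param tube a `nanostructure` with a defined axis.
#' @param drug a rigid `nanostructure` (e.g. from [build_ssz_fixture()]).
#' @param site one of `"carbonyl_v1"`, `"carbonyl_v2"`, `"sulfonamide"`,
#'   `"pyridine"`.  The two carbonyl variants aim the C=O oxygen at an N
#'   or a B surface atom respectively; `sulfonamide` aims a sulfonyl
#'   oxygen and `pyridine` the ring nitrogen at a B atom.
#' @param gap requested closest-approach distance in Angstrom, in
#'   \[2, 5\].
#' @return A combined `nanostructure` (tube atoms first) inheriting the
#'   tube's axis.
#' @export
place_complex <- function(tube, drug, site = c("carbonyl_v1", "carbonyl_v2",
                                               "sulfonamide", "pyridine"),
                          gap = 2.55) {
  site <- match.arg(site)
  if (is.null(tube$axis)) stop("'tube' has no axis")
  if (gap < 2 || gap > 5) stop("'gap' must lie in [2, 5] Angstrom")
  anchor_role <- switch(site, carbonyl_v1 = "O1", carbonyl_v2 = "O1",
                        sulfonamide = "O_S", pyridine = "N4")
  target_el <- switch(site, carbonyl_v1 = "N", carbonyl_v2 = "B",
                      sulfonamide = "B", pyridine = "B")
  ai <- which(!is.na(drug$atoms$role) & drug$atoms$role == anchor_role)[1]
  if (is.na(ai)) stop("drug has no atom with role ", anchor_role)

  tp <- atom_positions(tube)
  cand <- which(tube$atoms$element == target_el)
  if (!length(cand)) stop("tube has no ", target_el, " atoms")
  zmid <- mean(range(tp[tube$atoms$element %in% c("B", "N"), 3]))
  ti <- cand[which.min(abs(tp[cand, 3] - zmid))]
  target <- tp[ti, ]
  u <- c(target[1], target[2], 0)
  u <- u / sqrt(sum(u^2)) # outward radial direction at the target atom

  # orient the drug so the anchor leads: the mean direction from the
  # anchor to its bonded heavy atoms (its local bond direction) is
  # aligned with the outward radial, i.e. the anchor points at the tube
  dp <- atom_positions(drug)
  heavy <- which(drug$atoms$element != "H" & seq_len(nrow(dp)) != ai)
  dd <- sqrt(rowSums((dp[heavy, , drop = FALSE] -
                        matrix(dp[ai, ], length(heavy), 3, TRUE))^2))
  bonded <- heavy[dd < 1.8]
  if (!length(bonded)) bonded <- heavy[which.min(dd)]
  v <- colMeans(dp[bonded, , drop = FALSE]) - dp[ai, ]
  v <- v / sqrt(sum(v^2))
  R <- .rotation_between(v, u)
  drug2 <- rotate_structure(drug, R)
  dp <- atom_positions(drug2)
  drug2 <- translate_structure(drug2, target + gap * u - dp[ai, ])

  # tilt about the anchor until the anchor atom itself is the closest
  # contact: pivot whichever atom currently binds the minimum away from
  # the surface (deterministic 2-degree steps)
  for (iter in seq_len(180L)) {
    p <- atom_positions(drug2)
    jmin <- which.min(apply(.cross_min_dist(tp, p), 2, min))
    if (jmin == ai) break
    w <- p[jmin, ] - p[ai, ]
    axv <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
             w[1] * u[2] - w[2] * u[1])
    nv <- sqrt(sum(axv^2))
    if (nv < 1e-9) axv <- c(u[3], 0, -u[1]) else axv <- axv / nv
    Rt <- .axis_angle(axv, 2 * pi / 180)
    anchor <- p[ai, ]
    drug2 <- translate_structure(
      rotate_structure(translate_structure(drug2, -anchor), Rt), anchor)
  }

  mind <- function(t) {
    p <- atom_positions(drug2) + matrix(u * t, nrow(drug2$atoms), 3, TRUE)
    min(.cross_min_dist(tp, p))
  }
  # slide along u until the global closest contact equals the gap
  f <- function(t) mind(t) - gap
  t0 <- 0
  if (abs(f(0)) > 1e-9) {
    lo <- -2; hi <- 8
    while (f(hi) < 0 && hi < 40) hi <- hi + 4
    t0 <- stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
  }
  drug2 <- translate_structure(drug2, u * t0)

  dmin <- min(.cross_min_dist(tp, atom_positions(drug2)))
  if (dmin < 2.0 - 1e-9) {
    ij <- which(.cross_min_dist(tp, atom_positions(drug2)) == dmin,
                arr.ind = TRUE)[1, ]
    stop(sprintf("clash: tube atom %d and drug atom %d are %.2f Angstrom apart",
                 ij[1], ij[2], dmin))
  }
  atoms <- rbind(tube$atoms, drug2$atoms)
  structure(list(atoms = atoms,
                 name = paste0(tube$name, "+", drug$name, ":", site),
                 axis = tube$axis, rigid = TRUE),
            class = "nanostructure")
}

.cross_min_dist <- function(a, b) {
  # matrix of pairwise distances between two coordinate sets
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

.rotation_between <- function(v, u) {
  # rotation matrix taking unit vector v onto unit vector u
  c_ <- sum(v * u)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # antiparallel: rotate pi about any axis perpendicular to v
    a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- a - sum(a * v) * v; w <- w / sqrt(sum(w^2))
    return(2 * outer(w, w) - diag(3))
  }
  k <- c(v[2] * u[3] - v[3] * u[2], v[3] * u[1] - v[1] * u[3],
         v[1] * u[2] - v[2] * u[1])
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c_)
}

# rigid three-site water geometry: O at origin, H in the xz plane
.water_template <- function(r_oh = 0.9572, angle_hoh = 104.52) {
  half <- angle_hoh / 2 * pi / 180
  rbind(O = c(0, 0, 0),
        H1 = r_oh * c(sin(half), 0, cos(half)),
        H2 = r_oh * c(-sin(half), 0, cos(half)))
}

#' Solvate a solute in a cubic water box
#'
#' Fills a cubic box (centred on the origin) with rigid three-site waters
#' at the requested density: molecules are seeded on a simple-cubic
#' lattice, jittered by a small uniform displacement, and given random
#' orientations; waters whose oxygen lies within `carve` Angstrom of any
#' solute atom are then removed.  The solute is *not* moved: it must be
#' pre-centred (structures from [build_bnnt()] and [build_ssz_fixture()]
#' are).
#'
#' @param solute a `nanostructure`, or `NULL` for a pure-water box.
#' @param box a [box_spec()].
#' @param seed integer seed; identical seeds give bit-identical states.
#' @param carve solute-atom to water-oxygen exclusion distance, Angstrom.
#' @param jitter half-width of the uniform lattice jitter, Angstrom.
#' @return A `simulation_state`.
#' @export
solvate <- function(solute = NULL, box = box_spec(), seed, carve = 2.6,
                    jitter = 0.2) {
  if (missing(seed)) stop("'seed' is required for reproducibility")
  edge <- box$edge
  if (!is.null(solute)) {
    ext <- max(sqrt(rowSums(atom_positions(solute)^2)))
    if (edge < 2 * (ext + 3))
      stop(sprintf("box too small for solute: edge %.1f < %.1f Angstrom",
                   edge, 2 * (ext + 3)))
  }
  # number density from mass density (water molar mass 18.0153 g/mol)
  rho_n <- box$density * 6.02214076e23 / 18.0153 * 1e-24 # molecules/A^3
  n_target <- round(rho_n * edge^3)

  with_seed(seed, {
    m <- ceiling(n_target^(1 / 3))
    g <- (seq_len(m) - 0.5) / m * edge - edge / 2
    sites <- as.matrix(expand.grid(x = g, y = g, z = g))
    keep <- if (nrow(sites) > n_target)
      sort(sample.int(nrow(sites), n_target)) else seq_len(nrow(sites))
    o <- sites[keep, , drop = FALSE] +
      matrix(runif(3 * length(keep), -jitter, jitter), length(keep), 3)

    tmpl <- .water_template()
    waters <- matrix(0, nrow(o), 9)
    colnames(waters) <- c("Ox", "Oy", "Oz", "H1x", "H1y", "H1z",
                          "H2x", "H2y", "H2z")
    for (i in seq_len(nrow(o))) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- runif(1, 0, 2 * pi)
      R <- .axis_angle(ax, ang)
      h <- tmpl[2:3, ] %*% t(R)
      waters[i, ] <- c(o[i, ], o[i, ] + h[1, ], o[i, ] + h[2, ])
    }
    if (!is.null(solute)) {
      sp <- atom_positions(solute)
      d <- .cross_min_dist(waters[, 1:3, drop = FALSE], sp)
      waters <- waters[apply(d, 1, min) >= carve, , drop = FALSE]
    }
    new_simulation_state(solute, waters, edge, box$temperature)
  })
}

.axis_angle <- function(axis, angle) {
  u <- axis; ca <- cos(angle); sa <- sin(angle)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sa * K + (1 - ca) * (K %*% K)
}
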