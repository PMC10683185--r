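# Readers and writers for XYZ and PDB, the charge/LJ sidecar CSV, and the
# YAML run configuration.

#' Write a structure to XYZ or PDB
#'
#' XYZ carries element and coordinates at 1e-6 Angstrom; PDB uses HETATM
#' records (fixed format, 1e-3 Angstrom) with a CRYST1 record when a box
#' edge is given.  Charges and LJ labels do not fit either format and are
#' written to a sidecar CSV (`<path>.csv` with columns atom_index,
#' element, charge, lj_label, role) that [read_structure()] picks up
#' automatically.
#'
#' @param s a `nanostructure`.
#' @param path output file.
#' @param format `"xyz"` or `"pdb"` (default from the file extension).
#' @param box_edge optional cubic box edge for the PDB CRYST1 record.
#' @param sidecar write the charge/LJ sidecar CSV?
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, format = NULL, box_edge = NULL,
                            sidecar = TRUE) {
  format <- .guess_format(path, format)
  a <- s$atoms
  if (format == "xyz") {
    lines <- c(sprintf("%d", nrow(a)), s$name,
               sprintf("%-2s %14.6f %14.6f %14.6f", a$element, a$x, a$y, a$z))
  } else {
    lines <- character(0)
    if (!is.null(box_edge))
      lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1",
                       box_edge, box_edge, box_edge, 90, 90, 90)
    lines <- c(lines, sprintf(
      "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)), substr(a$element, 1, 4), "MOL", 1L,
      a$x, a$y, a$z, a$element), "END")
  }
  writeLines(lines, path)
  if (sidecar) {
    utils::write.csv(data.frame(atom_index = seq_len(nrow(a)),
                                element = a$element, charge = a$charge,
                                lj_label = a$lj_label, role = a$role),
                     paste0(path, ".csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a structure from XYZ or PDB
#'
#' @param path input file.
#' @param format `"xyz"` or `"pdb"` (default from the file extension).
#' @param sidecar read charges/LJ labels from `<path>.csv` when present?
#' @return A `nanostructure`.  Malformed records abort with the
#'   offending line number.
#' @export
read_structure <- function(path, format = NULL, sidecar = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- .guess_format(path, format)
  lines <- readLines(path)
  if (format == "xyz") {
    n <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(n)) stop("line 1: expected an atom count")
    name <- if (length(lines) >= 2) trimws(lines[2]) else "structure"
    el <- character(n); pos <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      ln <- 2L + i
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(tok) < 4) stop(sprintf("line %d: expected 'element x y z'", ln))
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(xyz))
        stop(sprintf("line %d: bad coordinate token '%s'", ln,
                     tok[2:4][which(is.na(xyz))[1]]))
      el[i] <- tok[1]; pos[i, ] <- xyz
    }
  } else {
    rec <- grepl("^(ATOM  |HETATM)", lines)
    if (!any(rec)) stop("no ATOM/HETATM records found")
    idx <- which(rec)
    el <- character(length(idx)); pos <- matrix(NA_real_, length(idx), 3)
    for (j in seq_along(idx)) {
      ln <- idx[j]; l <- lines[ln]
      xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                           substr(l, 39, 46),
                                           substr(l, 47, 54))))
      if (anyNA(xyz) || nchar(l) < 54)
        stop(sprintf("line %d: malformed coordinate fields", ln))
      e <- trimws(substr(l, 77, 78))
      if (e == "") e <- gsub("[0-9']", "", trimws(substr(l, 13, 16)))
      el[j] <- e; pos[j, ] <- xyz
    }
    name <- sub("\\.[^.]*$", "", basename(path))
  }
  charge <- 0; lj <- el; role <- NA_character_
  side <- paste0(path, ".csv")
  if (sidecar && file.exists(side)) {
    sc <- read.csv(side, stringsAsFactors = FALSE)
    if (nrow(sc) != length(el))
      stop("sidecar CSV row count does not match structure")
    charge <- sc$charge; lj <- sc$lj_label; role <- sc$role
  }
  nanostructure(el, pos, charge = charge, lj_label = lj, role = role,
                name = name, total_charge = sum(charge))
}

.guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("xyz", "pdb")))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("xyz", "pdb")) ext else
    stop("cannot infer format from extension: ", path)
}

#' Write a solvated state to PDB
#'
#' Solute atoms (HETATM, residue MOL) followed by waters (residue HOH),
#' with a CRYST1 record for the cubic box.
#'
#' @param state a `simulation_state`.
#' @param path output file.
#' @export
write_state_pdb <- function(state, path) {
  L <- state$box_edge
  lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1",
                   L, L, L, 90, 90, 90)
  serial <- 0L
  emit <- function(el, x, y, z, res, resid) {
    serial <<- serial + 1L
    sprintf("HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, el, res, resid, x, y, z, el)
  }
  if (!is.null(state$solute)) {
    a <- state$solute$atoms
    for (i in seq_len(nrow(a)))
      lines <- c(lines, emit(a$element[i], a$x[i], a$y[i], a$z[i], "MOL", 1L))
  }
  w <- state$waters
  for (i in seq_len(nrow(w))) {
    lines <- c(lines,
               emit("O", w[i, 1], w[i, 2], w[i, 3], "HOH", i + 1L),
               emit("H", w[i, 4], w[i, 5], w[i, 6], "HOH", i + 1L),
               emit("H", w[i, 7], w[i, 8], w[i, 9], "HOH", i + 1L))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a solvated state from a PDB written by [write_state_pdb()]
#'
#' @param path input file.
#' @param temperature Kelvin for the reconstructed state.
#' @param solute optional `nanostructure` to reattach (PDB does not carry
#'   charges); when `NULL`, MOL records are returned as a bare structure.
#' @export
read_state_pdb <- function(path, temperature = 298, solute = NULL) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cr)) stop("no CRYST1 record: box edge unknown")
  L <- as.numeric(substr(cr[1], 7, 15))
  rec <- lines[grepl("^HETATM", lines)]
  res <- trimws(substr(rec, 18, 20))
  xyz <- cbind(as.numeric(substr(rec, 31, 38)),
               as.numeric(substr(rec, 39, 46)),
               as.numeric(substr(rec, 47, 54)))
  wat <- xyz[res == "HOH", , drop = FALSE]
  if (nrow(wat) %% 3 != 0) stop("water record count is not a multiple of 3")
  nw <- nrow(wat) / 3
  waters <- t(matrix(t(wat), 9, nw))
  if (is.null(solute) && any(res == "MOL")) {
    mol <- xyz[res == "MOL", , drop = FALSE]
    el <- trimws(substr(rec, 77, 78))[res == "MOL"]
    solute <- nanostructure(el, mol, name = "from_pdb")
  }
  new_simulation_state(solute, waters, L, temperature)
}

#' Load and validate a simulation configuration
#'
#' Reads a YAML (or JSON) run configuration, applies the reference
#' protocol defaults (50 Angstrom box, 0.993 g/cm3, 298 K, +/-0.13
#' Angstrom translations, +/-10 degree rotations, 9.5 Angstrom cutoff)
#' and validates the result.  Unknown keys and invalid values are
#' collected and reported together.  A seed is required unless
#' `require_seed = FALSE`, because every run must be reproducible.
#'
#' @param path file path, or `NULL` for pure defaults.
#' @param require_seed error when no seed is given?
#' @return A named list of class `run_config`.
#' @export
load_config <- function(path = NULL, require_seed = TRUE) {
  defaults <- list(edge = 50, density = 0.993, temperature = 298,
                   d_translate = 0.13, d_rotate = 10, cutoff = 9.5,
                   n_equil = 1e4, n_prod = 1e5, sample_every = 100,
                   coord_every = 0, seed = NULL)
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  problems <- character(0)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    problems <- c(problems, paste("unknown key(s):",
                                  paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, user[intersect(names(user),
                                                    names(defaults))])
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk(cfg$edge > 0, "edge must be positive")
  chk(cfg$density > 0, "density must be positive")
  chk(cfg$temperature > 0, "temperature must be positive")
  chk(cfg$d_translate > 0, "d_translate must be positive")
  chk(cfg$d_rotate > 0 && cfg$d_rotate <= 180,
      "d_rotate must lie in (0, 180]")
  chk(cfg$cutoff > 0, "cutoff must be positive")
  chk(cfg$n_equil >= 0 && cfg$n_prod >= 0,
      "configuration counts must be >= 0")
  if (require_seed && is.null(cfg$seed))
    problems <- c(problems, "seed is required (reproducibility)")
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  structure(cfg, class = "run_config")
}
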