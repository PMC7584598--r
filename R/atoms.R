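#' @keywords internal
"_PACKAGE"

# Atom-table column order shared by every constructor and parser.
ATOM_COLS <- c("serial", "atom_name", "residue_name", "residue_number",
               "monomer_id", "x", "y", "z", "mass", "radius", "element")

# Monoisotopic-free average atomic masses (Da) for the elements that occur in
# protein heavy-atom / reduced-hydrogen models.
ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974)

# Average residue masses (Da), used to assign default bead masses for
# coarse-grained models (residue mass / bead count).
RESIDUE_MASSES <- c(
  ALA = 71.08,  ARG = 156.19, ASN = 114.10, ASP = 115.09, CYS = 103.14,
  GLN = 128.13, GLU = 129.12, GLY = 57.05,  HIS = 137.14, ILE = 113.16,
  LEU = 113.16, LYS = 128.17, MET = 131.19, PHE = 147.18, PRO = 97.12,
  SER = 87.08,  THR = 101.10, TRP = 186.21, TYR = 163.18, VAL = 99.13,
  LIP = 700.00)

# Bead names that mark a model as coarse-grained (configurable in readers).
CG_BEAD_NAMES <- c("BB", "SC1", "SC2", "SC3", "SC4")

#' Build an atom table
#'
#' Validates and assembles the flat atom table used throughout the package:
#' one row per particle (atom or coarse-grained bead) with monomer, residue
#' and coordinate information in Angstrom.
#'
#' @param serial integer atom serial numbers.
#' @param atom_name particle names (e.g. `"CA"`, or `"BB"` for CG beads).
#' @param residue_name three-letter residue codes.
#' @param residue_number 1-based residue numbers (human dynamin-2 numbering).
#' @param monomer_id chain/monomer identifiers.
#' @param x,y,z coordinates in Angstrom.
#' @param mass optional particle masses in Da (`NA` allowed).
#' @param radius optional particle radii in Angstrom (`NA` allowed).
#' @param element optional element symbols.
#' @return a `data.frame` with the standard atom columns.
#' @export
atom_table <- function(serial, atom_name, residue_name, residue_number,
                       monomer_id, x, y, z, mass = NA_real_,
                       radius = NA_real_, element = NA_character_) {
  n <- length(x)
  df <- data.frame(
    serial = as.integer(serial), atom_name = as.character(atom_name),
    residue_name = as.character(residue_name),
    residue_number = as.integer(residue_number),
    monomer_id = as.character(monomer_id),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    mass = rep_len(as.numeric(mass), n), radius = rep_len(as.numeric(radius), n),
    element = rep_len(as.character(element), n),
    stringsAsFactors = FALSE)
  validate_atom_table(df)
  df
}

validate_atom_table <- function(df) {
  stopifnot(all(ATOM_COLS %in% names(df)))
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop("atom table: non-finite coordinates", call. = FALSE)
  if (any(df$residue_number < 1L))
    stop("atom table: residue_number must be >= 1", call. = FALSE)
  bad <- !is.na(df$radius) & df$radius <= 0
  if (any(bad)) stop("atom table: radius must be > 0 when present", call. = FALSE)
  invisible(df)
}

#' Construct one frame of an oligomer ensemble
#'
#' @param atoms atom table (see [atom_table()]).
#' @param frame_index integer frame index (>= 0).
#' @param time_ns optional simulation time in ns.
#' @param resolution `"full_atom"` or `"coarse_grained"`; when `NULL` it is
#'   auto-detected from the bead names (`BB`/`SC1`..`SC4`).
#' @return an object of class `oligomer_frame`.
#' @export
oligomer_frame <- function(atoms, frame_index = 0L, time_ns = NULL,
                           resolution = NULL) {
  validate_atom_table(atoms)
  if (nrow(atoms) == 0L || length(unique(atoms$monomer_id)) < 1L)
    stop("oligomer_frame: at least one monomer required", call. = FALSE)
  if (is.null(resolution)) {
    resolution <- if (all(atoms$atom_name %in% c(CG_BEAD_NAMES, "LP")))
      "coarse_grained" else "full_atom"
  }
  resolution <- match.arg(resolution, c("full_atom", "coarse_grained"))
  structure(list(frame_index = as.integer(frame_index),
                 time_ns = if (is.null(time_ns)) NA_real_ else as.numeric(time_ns),
                 atoms = atoms, resolution = resolution),
            class = "oligomer_frame")
}

#' @export
print.oligomer_frame <- function(x, ...) {
  cat(sprintf("<oligomer_frame> frame %d (%s): %d monomers, %d particles\n",
              x$frame_index, x$resolution,
              length(unique(x$atoms$monomer_id)), nrow(x$atoms)))
  invisible(x)
}

#' Construct a trajectory (ordered list of frames)
#'
#' Frames must share monomer identities; frame indices must strictly increase.
#'
#' @param frames list of [oligomer_frame()] objects.
#' @param metadata free-form named list.
#' @return an object of class `oligo_trajectory`.
#' @export
oligo_trajectory <- function(frames, metadata = list()) {
  if (length(frames) < 1L) stop("trajectory: no frames", call. = FALSE)
  ids0 <- sort(unique(frames[[1L]]$atoms$monomer_id))
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  if (any(diff(idx) <= 0L))
    stop("trajectory: frame_index must strictly increase", call. = FALSE)
  for (f in frames) {
    if (!identical(sort(unique(f$atoms$monomer_id)), ids0))
      stop("trajectory: monomer sets differ across frames", call. = FALSE)
  }
  structure(list(frames = frames, metadata = metadata),
            class = "oligo_trajectory")
}

#' @export
print.oligo_trajectory <- function(x, ...) {
  f1 <- x$frames[[1L]]
  cat(sprintf("<oligo_trajectory> %d frames, %d monomers (%s)\n",
              length(x$frames), length(unique(f1$atoms$monomer_id)),
              f1$resolution))
  invisible(x)
}

#' @export
length.oligo_trajectory <- function(x) length(x$frames)

#' Monomer identifiers of a frame or trajectory
#' @param x an `oligomer_frame` or `oligo_trajectory`.
#' @param proteins_only drop pseudo-molecules such as the lipid nanotube
#'   (monomer id `"TUBE"`).
#' @return character vector of monomer ids in first-appearance order.
#' @export
monomer_ids <- function(x, proteins_only = FALSE) {
  atoms <- if (inherits(x, "oligo_trajectory")) x$frames[[1L]]$atoms else x$atoms
  ids <- unique(atoms$monomer_id)
  if (proteins_only) ids <- setdiff(ids, "TUBE")
  ids
}

# Row indices of a monomer's atoms, optionally restricted to residue numbers.
atom_rows <- function(frame, monomer_id, residues = NULL) {
  sel <- frame$atoms$monomer_id == monomer_id
  if (!is.null(residues)) sel <- sel & frame$atoms$residue_number %in% residues
  which(sel)
}

coords <- function(atoms) cbind(atoms$x, atoms$y, atoms$z)

#' Genotype of each monomer from residue 465
#'
#' WT carries ARG at position 465, the centronuclear-myopathy mutant TRP
#' (R465W).  Monomers lacking residue 465 get `NA`.
#'
#' @param frame an `oligomer_frame`.
#' @param mutation_site residue number to inspect (default 465).
#' @return named character vector (`"WT"`, `"R465W"` or `NA`).
#' @export
monomer_genotypes <- function(frame, mutation_site = 465L) {
  ids <- monomer_ids(frame)
  at <- frame$atoms[frame$atoms$residue_number == mutation_site, ]
  out <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (nrow(at)) {
    g <- tapply(at$residue_name, at$monomer_id, function(r) {
      if (all(r == "TRP")) "R465W" else if (all(r == "ARG")) "WT" else NA_character_
    })
    out[names(g)] <- as.character(g)
  }
  out
}

# Default mass assignment: element lookup for full-atom particles, residue
# mass / bead count for coarse-grained beads.
fill_masses <- function(atoms, resolution) {
  need <- is.na(atoms$mass)
  if (!any(need)) return(atoms)
  if (resolution == "full_atom") {
    el <- atoms$element
    guess <- is.na(el) | !nzchar(el)
    el[guess] <- substr(atoms$atom_name[guess], 1L, 1L)
    atoms$mass[need] <- unname(ELEMENT_MASSES[el[need]])
  } else {
    key <- paste(atoms$monomer_id, atoms$residue_number)
    nb <- stats::ave(atoms$serial, key, FUN = length)
    rm <- unname(RESIDUE_MASSES[atoms$residue_name])
    rm[is.na(rm)] <- 110
    atoms$mass[need] <- (rm / nb)[need]
  }
  atoms$mass[is.na(atoms$mass)] <- 12.011
  atoms
}
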