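# Deterministic generator of pseudo-dynamin fixtures: reduced-residue
# monomers with exact inter-domain angle targets, dimers with a crisscross
# stalk interface, 56-monomer helical assemblies with engineered G-G,
# interface-2 and residue-465/BSE contacts, and a lipid-head nanotube.

DEFAULT_HELIX_GEOM <- list(radius_A = 180, rise_per_monomer_A = 4,
                           monomers_per_turn = 14)

# Residue names for positions the analyses care about; everything else ALA.
SPECIAL_RESIDUES <- c(
  "429" = "ASN", "433" = "GLN", "466" = "GLU", "468" = "GLU",
  "474" = "GLN", "478" = "LEU", "480" = "LYS", "482" = "GLU", "484" = "ARG",
  "487" = "ASN", "489" = "ASN",
  "666" = "GLU", "670" = "ASP", "676" = "SER", "678" = "THR", "680" = "GLN",
  "294" = "PRO", "298" = "SER", "742" = "SER", "744" = "VAL", "745" = "SER")

# A straight run of residue centers: centroid `at`, direction `dir`,
# inter-residue spacing `sp` (centroid lands on `at` exactly).
center_line <- function(res, at, dir = c(0, 1, 0), sp = 1) {
  k <- length(res)
  off <- (seq_len(k) - (k + 1) / 2) * sp
  data.frame(residue_number = res,
             cx = at[1L] + off * dir[1L], cy = at[2L] + off * dir[2L],
             cz = at[3L] + off * dir[3L])
}

# Residue centers of the reduced scaffold in the monomer design frame:
# local x = radially outward, y = along the helical path, z = helix axis.
# The G-BSE and BSE-stalk anchor centroids are placed so both angles equal
# their targets exactly (uniform weighting; equal-mass residues make the
# mass-weighted case exact too).
base_centers <- function(g_bse_deg, bse_stalk_deg, exposure, pitch) {
  deg <- pi / 180
  V <- c(15, 0, 20)                         # G-BSE vertex centroid (291-293)
  h <- g_bse_deg / 2 * deg
  A1 <- V + 9 * c(sin(h), 0, cos(h))        # arm 277-285 centroid
  A2 <- V + 9 * c(-sin(h), 0, cos(h))       # arm 299-306 centroid
  # BSE-stalk: hinge vertex at the origin, V3 to the pooled G center,
  # V4 rotated from V3 by the target angle within the x-z plane.
  v3 <- c(0.6, 0, 0.8)
  th <- atan2(v3[1L], v3[3L]) + bse_stalk_deg * deg
  C4 <- 25 * c(sin(th), 0, cos(th))         # pooled stalk-center centroid
  arm_top <- pitch + 14                     # G arm engineered for G-G contact
  p465 <- if (exposure == "exposed") c(16, 38, -19) else c(7, 38, -19)
  rbind(
    center_line(30:36,   c(12, 3.5, 18)),
    center_line(170:176, c(12, -3.5, 14)),
    center_line(186:194, c(15, 0, arm_top - 15), dir = c(0, 0, 1), sp = 30 / 8),
    center_line(250:256, c(17, -2, 26)),
    center_line(277:285, A1),
    center_line(291:293, V),
    center_line(299:306, A2),
    center_line(315:321, c(0, 5, 0.5)),
    center_line(325:335, c(3, -11, -5)),
    center_line(390:400, c(0, 15, -30)),
    center_line(410:422, C4 + c(0, 8.5, 1.2), sp = 2),
    center_line(425:435, c(7, 39, -23), sp = 0.6),
    center_line(c(455:464, 466:470), c(7, 36.4, -19), sp = 0.6),
    data.frame(residue_number = 465L, cx = p465[1L], cy = p465[2L],
               cz = p465[3L]),
    center_line(471:495, c(8, 42, -14), sp = 0.5),
    center_line(540:548, c(-25, 0, -25)),
    center_line(610:626, C4 + c(0, -6.5, -1.2 * 13 / 17), sp = 2),
    center_line(660:692, c(8, -44, -14), sp = -0.5),
    center_line(702:711, c(0, -3.5, -0.35)),
    data.frame(residue_number = c(742L, 744L, 745L), cx = 0, cy = 0, cz = 0))
}

# Local coordinates (design frame) of the BSE "finger" (294-298, 742-745)
# of the *next* monomer along the helix, chosen so that it lands within
# contact range of this monomer's residue 465: P294/V744/S745 reach both the
# buried and the exposed 465, S298/S742 only the exposed (mutant-like) one.
finger_local <- function(c0, geom) {
  r <- geom$radius_A; rise <- geom$rise_per_monomer_A
  dphi <- 2 * pi / geom$monomers_per_turn
  cc <- cos(dphi); ss <- sin(dphi)
  gb <- c(r + 7 - c0[1L], 38 - c0[2L], -19 - c0[3L])   # buried 465, global
  ge <- c(r + 16 - c0[1L], 38 - c0[2L], -19 - c0[3L])  # exposed 465, global
  M <- (gb + ge) / 2
  targets <- rbind(
    "294" = M + c(0, 0.4, -0.8),
    "295" = M + c(0, 6, -2.2), "296" = M + c(0, 7, -2.2),
    "297" = M + c(0, 8, -2.2),
    "298" = ge + c(3.2, 0.4, -0.5),
    "742" = ge + c(3.2, -0.4, 0.4),
    "744" = M + c(0, -0.4, 0.8),
    "745" = M + c(-0.7, 0, -1.6))
  # Invert the placement transform of the neighbor (azimuth +dphi, +rise).
  px <- targets[, 1L] * cc + targets[, 2L] * ss - r
  py <- -targets[, 1L] * ss + targets[, 2L] * cc
  pz <- targets[, 3L] - rise
  data.frame(residue_number = as.integer(rownames(targets)),
             cx = px + c0[1L], cy = py + c0[2L], cz = pz + c0[3L])
}

# Full residue-center layout, centered so the uniform centroid is exactly at
# the origin (monomer COMs then sit exactly on the helix radius).  The
# finger depends on the centroid, so the two are solved by fixed-point
# iteration (strongly contracting: 8 of ~230 residues).
monomer_layout <- function(g_bse_deg, bse_stalk_deg, exposure,
                           geom = DEFAULT_HELIX_GEOM, scaffold_scale = 1) {
  pitch <- geom$rise_per_monomer_A * geom$monomers_per_turn
  fixed <- base_centers(g_bse_deg, bse_stalk_deg, exposure, pitch)
  fixed <- fixed[!fixed$residue_number %in% c(294:298, 742, 744, 745), ]
  c0 <- c(colMeans(fixed[, c("cx", "cy", "cz")]))
  for (it in 1:25) {
    fing <- finger_local(c0, geom)
    all <- rbind(fixed, fing)
    c0 <- c(colMeans(all[, c("cx", "cy", "cz")]))
  }
  all$cx <- (all$cx - c0[1L]) * scaffold_scale
  all$cy <- (all$cy - c0[2L]) * scaffold_scale
  all$cz <- (all$cz - c0[3L]) * scaffold_scale
  all[order(all$residue_number), ]
}

residue_names_for <- function(res, genotype) {
  nm <- rep("ALA", length(res))
  hit <- as.character(res) %in% names(SPECIAL_RESIDUES)
  nm[hit] <- SPECIAL_RESIDUES[as.character(res[hit])]
  nm[res == 465L] <- if (genotype == "R465W") "TRP" else "ARG"
  nm
}

SIDECHAIN_ATOMS <- list(
  ALA = "CB", ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"), ASP = c("CB", "CG", "OD1", "OD2"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"), GLY = character(),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  LEU = c("CB", "CG", "CD1", "CD2"), LYS = c("CB", "CG", "CD", "CE", "NZ"),
  PRO = c("CB", "CG", "CD"), SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  VAL = c("CB", "CG1", "CG2"))

# Expand residue centers into particles.  Coarse-grained: one BB bead per
# residue at the center.  Full-atom: reduced heavy-atom set whose
# mass-weighted centroid is shifted back onto the residue center, so range
# centroids (and hence angle targets) stay exact under mass weighting.
expand_atoms <- function(centers, resnames, resolution, monomer_id) {
  if (resolution == "coarse_grained") {
    return(atom_table(serial = seq_len(nrow(centers)), atom_name = "BB",
                      residue_name = resnames,
                      residue_number = centers$residue_number,
                      monomer_id = monomer_id,
                      x = centers$cx, y = centers$cy, z = centers$cz))
  }
  rows <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    rn <- resnames[i]
    sgn <- if (centers$residue_number[i] %% 2L == 0L) 1 else -1
    bb_n <- c("N", "CA", "C", "O")
    bb_o <- rbind(c(-0.70, 0.45, 0), c(0, 0, 0), c(0.70, 0.45, 0),
                  c(1.10, 1.40, 0.35))
    sc <- SIDECHAIN_ATOMS[[rn]]
    if (length(sc)) {
      k <- seq_along(sc)
      lat <- rep_len(c(0, 0.35, -0.35), length(sc))
      sc_o <- cbind(lat, 0, sgn * (0.9 + 0.7 * (k - 1)))
    } else sc_o <- matrix(numeric(), 0L, 3L)
    nm <- c(bb_n, sc)
    off <- rbind(bb_o, sc_o)
    el <- substr(nm, 1L, 1L)
    m <- unname(ELEMENT_MASSES[el])
    off <- sweep(off, 2L, drop(crossprod(off, m)) / sum(m))  # mass recentring
    rows[[i]] <- data.frame(
      atom_name = nm, residue_name = rn,
      residue_number = centers$residue_number[i],
      x = centers$cx[i] + off[, 1L], y = centers$cy[i] + off[, 2L],
      z = centers$cz[i] + off[, 3L], mass = m, element = el,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  atom_table(serial = seq_len(nrow(df)), atom_name = df$atom_name,
             residue_name = df$residue_name, residue_number = df$residue_number,
             monomer_id = monomer_id, x = df$x, y = df$y, z = df$z,
             mass = df$mass, element = df$element)
}

#' Build a synthetic reduced-residue monomer
#'
#' The scaffold contains every residue range the analyses select (G-domain
#' anchors, BSE arms, hinge, stalk centers, interface segments, residue 465
#' and its neighborhood) placed so that [g_bse_angle()] and
#' [bse_stalk_angle()] return the targets exactly on the noiseless model.
#'
#' @param target_g_bse_deg G-BSE angle target in degrees (WT-like ~118,
#'   mutant-like ~150); must lie strictly inside (0, 180).
#' @param target_bse_stalk_deg BSE-stalk angle target (default 109).
#' @param genotype `"WT"` (ARG 465) or `"R465W"` (TRP 465).
#' @param residue465_exposure `"buried"` or `"exposed"`; default buried for
#'   WT and exposed for the mutant.
#' @param scaffold_scale overall size multiplier (default 1 = Angstrom-scale
#'   defaults).
#' @param resolution `"coarse_grained"` (one backbone bead per residue) or
#'   `"full_atom"` (reduced heavy-atom residues).
#' @param monomer_id chain identifier.
#' @param helix_geom helix geometry (radius, rise, monomers per turn) used to
#'   pre-position the neighbor-facing BSE contact residues.
#' @return an `oligomer_frame` containing the single monomer.
#' @export
build_monomer <- function(target_g_bse_deg = 118, target_bse_stalk_deg = 109,
                          genotype = c("WT", "R465W"),
                          residue465_exposure = NULL, scaffold_scale = 1,
                          resolution = c("coarse_grained", "full_atom"),
                          monomer_id = "A", helix_geom = DEFAULT_HELIX_GEOM) {
  genotype <- match.arg(genotype)
  resolution <- match.arg(resolution)
  for (t in c(target_g_bse_deg, target_bse_stalk_deg)) {
    if (!is.finite(t) || t <= 0 || t >= 180)
      stop("construction error: angle target must lie strictly in (0, 180)",
           call. = FALSE)
  }
  if (is.null(residue465_exposure))
    residue465_exposure <- if (genotype == "R465W") "exposed" else "buried"
  residue465_exposure <- match.arg(residue465_exposure, c("buried", "exposed"))
  lay <- monomer_layout(target_g_bse_deg, target_bse_stalk_deg,
                        residue465_exposure, helix_geom, scaffold_scale)
  at <- expand_atoms(lay, residue_names_for(lay$residue_number, genotype),
                     resolution, monomer_id)
  at <- fill_masses(at, resolution)
  oligomer_frame(at, frame_index = 0L, resolution = resolution)
}

place_monomer <- function(atoms, radius, azimuth, z_off) {
  cc <- cos(azimuth); ss <- sin(azimuth)
  gx <- (radius + atoms$x) * cc - atoms$y * ss
  gy <- (radius + atoms$x) * ss + atoms$y * cc
  atoms$x <- gx; atoms$y <- gy; atoms$z <- atoms$z + z_off
  atoms
}

#' Build a synthetic helical assembly with ground truth
#'
#' Monomers are placed at azimuth `i * 2*pi / monomers_per_turn` and axial
#' position `i * rise`, with each monomer's center of mass exactly on the
#' helix radius.  The scaffold engineers cross-rung G-G contacts, crisscross
#' interface-2 contacts between azimuthal neighbors, and residue-465/BSE
#' contacts at the defaults (radius 180 A, rise 4 A, 14 monomers per turn).
#' Mutant monomers get the extended G-BSE target, WT the bent one; all
#' monomers share the BSE-stalk target.  Per-frame isotropic Gaussian
#' coordinate noise emulates thermal jitter.
#'
#' @param n_monomers monomer count (divisible by 4; default 56).
#' @param radius_A,rise_per_monomer_A,monomers_per_turn helix lattice.
#' @param genotype_pattern `"all_wt"`, `"alternating"` (strict WT/mutant
#'   intercalation) or `"all_mutant"`.
#' @param n_frames number of frames (default 1).
#' @param noise_sigma_A per-coordinate Gaussian noise SD in Angstrom.
#' @param seed RNG seed (integer); output is fully determined by it.
#' @param dt_ns time between frames in ns (default 10).
#' @param wt_g_bse_deg,mut_g_bse_deg,bse_stalk_deg angle targets.
#' @param nanotube optional [build_nanotube()] spec list
#'   (`outer_diameter_A`, `length_A`, `bead_spacing_A`): adds a lipid-head
#'   pseudo-monomer `"TUBE"` along the helix axis.
#' @return an [oligo_trajectory()]; `metadata$ground_truth` carries the true
#'   genotypes, rung/tetramer labels, neighbor and G-G pairs, angle targets
#'   and helix parameters.
#' @export
build_helix <- function(n_monomers = 56L, radius_A = 180,
                        rise_per_monomer_A = 4, monomers_per_turn = 14,
                        genotype_pattern = c("all_wt", "alternating",
                                             "all_mutant"),
                        n_frames = 1L, noise_sigma_A = 0, seed = 1L,
                        dt_ns = 10, wt_g_bse_deg = 118, mut_g_bse_deg = 150,
                        bse_stalk_deg = 109, nanotube = NULL) {
  genotype_pattern <- match.arg(genotype_pattern)
  if (n_monomers %% 4L != 0L)
    stop("spec error: n_monomers must be divisible by 4", call. = FALSE)
  if (genotype_pattern == "alternating" && n_monomers %% 2L != 0L)
    stop("spec error: alternating pattern needs an even monomer count",
         call. = FALSE)
  geom <- list(radius_A = radius_A, rise_per_monomer_A = rise_per_monomer_A,
               monomers_per_turn = monomers_per_turn)
  ids <- sprintf("M%02d", seq_len(n_monomers))
  geno <- switch(genotype_pattern,
                 all_wt = rep("WT", n_monomers),
                 all_mutant = rep("R465W", n_monomers),
                 alternating = rep(c("WT", "R465W"), length.out = n_monomers))
  names(geno) <- ids
  layouts <- list(
    WT = build_monomer(wt_g_bse_deg, bse_stalk_deg, "WT",
                       helix_geom = geom)$atoms,
    R465W = build_monomer(mut_g_bse_deg, bse_stalk_deg, "R465W",
                          helix_geom = geom)$atoms)
  base <- vector("list", n_monomers)
  for (i in seq_len(n_monomers)) {
    a <- layouts[[geno[i]]]
    a$monomer_id <- ids[i]
    base[[i]] <- place_monomer(a, radius_A,
                               (i - 1L) * 2 * pi / monomers_per_turn,
                               (i - 1L) * rise_per_monomer_A)
  }
  base <- do.call(rbind, base)
  if (!is.null(nanotube)) {
    tube <- do.call(build_nanotube, nanotube)$atoms
    tube$z <- tube$z + (min(base$z) + max(base$z) - max(tube$z)) / 2
    base <- rbind(base, tube)
  }
  base$serial <- seq_len(nrow(base))
  base <- fill_masses(base, "coarse_grained")
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      a <- base
      if (noise_sigma_A > 0) {
        a$x <- a$x + stats::rnorm(nrow(a), 0, noise_sigma_A)
        a$y <- a$y + stats::rnorm(nrow(a), 0, noise_sigma_A)
        a$z <- a$z + stats::rnorm(nrow(a), 0, noise_sigma_A)
      }
      oligomer_frame(a, frame_index = f - 1L, time_ns = (f - 1L) * dt_ns,
                     resolution = "coarse_grained")
    })
  })
  rung <- as.integer(floor((seq_len(n_monomers) - 1L) / monomers_per_turn))
  gt <- list(
    spec = c(geom, list(n_monomers = n_monomers,
                        genotype_pattern = genotype_pattern,
                        n_frames = n_frames, noise_sigma_A = noise_sigma_A,
                        seed = seed)),
    genotype = geno,
    rung = stats::setNames(rung, ids),
    tetramer = stats::setNames(as.integer((seq_len(n_monomers) - 1L) %/% 4L),
                               ids),
    order = ids,
    g_bse_target = stats::setNames(
      ifelse(geno == "WT", wt_g_bse_deg, mut_g_bse_deg), ids),
    bse_stalk_target = stats::setNames(rep(bse_stalk_deg, n_monomers), ids),
    helix = list(diameter_A = 2 * radius_A,
                 pitch_A = rise_per_monomer_A * monomers_per_turn,
                 rise_per_monomer_A = rise_per_monomer_A,
                 monomers_per_turn = monomers_per_turn,
                 helix_angle_deg = atan2(rise_per_monomer_A,
                                         radius_A * 2 * pi / monomers_per_turn)
                 * 180 / pi),
    neighbor_pairs = if (n_monomers > 1L)
      cbind(ids[-n_monomers], ids[-1L])[rung[-n_monomers] == rung[-1L], ,
                                        drop = FALSE],
    gg_pairs = {
      k <- as.integer(round(monomers_per_turn))
      if (abs(monomers_per_turn - k) < 1e-9 && n_monomers > k)
        cbind(ids[seq_len(n_monomers - k)], ids[seq.int(k + 1L, n_monomers)])
      else matrix(character(), 0L, 2L)
    })
  oligo_trajectory(frames, metadata = list(ground_truth = gt))
}

# Evaluate `expr` under a private, restored RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Build a synthetic dimer with a crisscross stalk interface
#'
#' Monomer B is monomer A rotated 180 degrees about the radial axis and
#' offset so the central alpha-S2..S4 stalk segments of the two monomers
#' interdigitate (interface-2).  `loosened` pulls the monomers apart by
#' `loosen_offset` so that contact counts drop.
#'
#' @param genotype_a,genotype_b `"WT"` or `"R465W"`.
#' @param interface_mode `"tight"` or `"loosened"`.
#' @param loosen_offset extra separation in Angstrom for loosened mode
#'   (default 5).
#' @param resolution particle resolution (default full-atom, matching
#'   atomistic dimer simulations).
#' @return an `oligomer_frame` with monomers `"A"` and `"B"`.
#' @export
build_dimer <- function(genotype_a = "WT", genotype_b = "WT",
                        interface_mode = c("tight", "loosened"),
                        loosen_offset = 5,
                        resolution = c("full_atom", "coarse_grained")) {
  interface_mode <- match.arg(interface_mode)
  resolution <- match.arg(resolution)
  a <- build_monomer(genotype = genotype_a, resolution = resolution,
                     monomer_id = "A")$atoms
  b <- build_monomer(genotype = genotype_b, resolution = resolution,
                     monomer_id = "B")$atoms
  off <- 2 + if (interface_mode == "loosened") loosen_offset else 0
  # 180-degree rotation about x through z = -13.5, then radial offset.
  b$y <- -b$y
  b$z <- -27 - b$z
  b$x <- b$x + off
  at <- rbind(a, b)
  at$serial <- seq_len(nrow(at))
  oligomer_frame(at, frame_index = 0L, resolution = resolution)
}

#' Build a lipid-head nanotube pseudo-molecule
#'
#' Cylindrical bead lattice emulating the membrane tube the helix wraps:
#' rings of beads at the outer radius, stacked along z.
#'
#' @param outer_diameter_A outer diameter in Angstrom (default 137,
#'   i.e. 13.7 nm).
#' @param length_A tube length (0 gives a single ring).
#' @param bead_spacing_A bead spacing within and between rings (default 3.5).
#' @return an `oligomer_frame` with the single pseudo-monomer `"TUBE"`.
#' @export
build_nanotube <- function(outer_diameter_A = 137, length_A = 100,
                           bead_spacing_A = 3.5) {
  r <- outer_diameter_A / 2
  if (outer_diameter_A <= 0) stop("spec error: diameter must be > 0",
                                  call. = FALSE)
  if (bead_spacing_A > r)
    stop("spec error: bead spacing exceeds tube radius", call. = FALSE)
  zs <- seq(0, length_A, by = bead_spacing_A)
  nring <- max(3L, as.integer(round(2 * pi * r / bead_spacing_A)))
  phi <- seq(0, 2 * pi, length.out = nring + 1L)[-(nring + 1L)]
  g <- expand.grid(phi = phi, z = zs)
  at <- atom_table(serial = seq_len(nrow(g)), atom_name = "LP",
                   residue_name = "LIP", residue_number = seq_len(nrow(g)),
                   monomer_id = "TUBE",
                   x = r * cos(g$phi), y = r * sin(g$phi), z = g$z,
                   radius = 2.3)
  at <- fill_masses(at, "coarse_grained")
  oligomer_frame(at, frame_index = 0L, resolution = "coarse_grained")
}

#' Expand a single frame into a noisy trajectory
#'
#' Adds i.i.d. Gaussian coordinate noise per frame -- a stand-in for thermal
#' fluctuation when testing window statistics on dimers or custom fixtures.
#'
#' @param frame an `oligomer_frame`.
#' @param n_frames number of frames.
#' @param noise_sigma_A per-coordinate noise SD in Angstrom.
#' @param seed RNG seed.
#' @param dt_ns time step between frames in ns.
#' @return an [oligo_trajectory()].
#' @export
perturb_trajectory <- function(frame, n_frames = 10L, noise_sigma_A = 0.5,
                               seed = 1L, dt_ns = 1) {
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      a <- frame$atoms
      if (noise_sigma_A > 0) {
        a$x <- a$x + stats::rnorm(nrow(a), 0, noise_sigma_A)
        a$y <- a$y + stats::rnorm(nrow(a), 0, noise_sigma_A)
        a$z <- a$z + stats::rnorm(nrow(a), 0, noise_sigma_A)
      }
      oligomer_frame(a, frame_index = f - 1L, time_ns = (f - 1L) * dt_ns,
                     resolution = frame$resolution)
    })
  })
  oligo_trajectory(frames)
}
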