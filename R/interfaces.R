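# Monomer-monomer contact detection, interface classification and areas,
# residue occupancy, hydrogen-bond and salt-bridge counting.

#' Interface analysis configuration
#'
#' @param contact_cutoff contact distance cutoff in Angstrom (default 6.0,
#'   inclusive); a residue is in contact when any of its particles lies
#'   within the cutoff of any particle of the partner monomer.
#' @param area_mode `"exposed_sum"` (summed in-assembly SASA of the contact
#'   residues) or `"buried"` (isolated-monomer SASA minus in-pair SASA).
#' @return object of class `interface_config`.
#' @export
interface_config <- function(contact_cutoff = 6.0,
                             area_mode = c("exposed_sum", "buried")) {
  if (contact_cutoff <= 0) stop("contact_cutoff must be > 0", call. = FALSE)
  structure(list(contact_cutoff = contact_cutoff,
                 distance_mode = "closest_particle",
                 area_mode = match.arg(area_mode)),
            class = "interface_config")
}

# Squared cross-distance matrix built from coordinate differences (same
# floating-point path as a scalar loop, so boundary cases agree with a
# brute-force oracle).
cross_dist2 <- function(xa, xb) {
  outer(xa[, 1L], xb[, 1L], "-")^2 + outer(xa[, 2L], xb[, 2L], "-")^2 +
    outer(xa[, 3L], xb[, 3L], "-")^2
}

#' Contact residues between two monomers
#'
#' Residue `r` of monomer `a` is reported when the minimum inter-particle
#' distance between `r` and any particle of monomer `b` is `<=` the cutoff
#' (and symmetrically for `b`).
#'
#' @param frame an `oligomer_frame`.
#' @param monomer_a,monomer_b monomer ids.
#' @param config an [interface_config()].
#' @return list with sorted integer vectors `residues_a`, `residues_b`.
#' @export
find_contact_residues <- function(frame, monomer_a, monomer_b,
                                  config = interface_config()) {
  for (id in c(monomer_a, monomer_b)) {
    if (!id %in% frame$atoms$monomer_id)
      stop("unknown monomer: ", id, call. = FALSE)
  }
  aa <- frame$atoms[frame$atoms$monomer_id == monomer_a, , drop = FALSE]
  ab <- frame$atoms[frame$atoms$monomer_id == monomer_b, , drop = FALSE]
  d2 <- cross_dist2(coords(aa), coords(ab))
  hit <- d2 <= config$contact_cutoff^2
  list(residues_a = sort(unique(aa$residue_number[rowSums(hit) > 0L])),
       residues_b = sort(unique(ab$residue_number[colSums(hit) > 0L])))
}

#' Classify a monomer-monomer interface
#'
#' Deterministic domain-majority rule over the four interface types of the
#' dynamin helix: `GG` (cross-rung G-domain contact), `IF1` (stalk against
#' BSE), `IF2` (central crisscross stalk-stalk contact, alpha-S2..S4
#' segments), `IF3` (stalk-stalk contact dominated by the L1N-S loop).
#'
#' @param frame an `oligomer_frame` (unused by the default rule, kept for
#'   signature stability).
#' @param pair character 2-vector of monomer ids.
#' @param topology an [assign_topology()] result, or `NULL` when rung
#'   information is unavailable (e.g. isolated dimers).
#' @param map a [default_domain_map()].
#' @param contacts result of [find_contact_residues()].
#' @param majority domain-majority threshold (default 0.5).
#' @return one of `"GG"`, `"IF1"`, `"IF2"`, `"IF3"`, `"unclassified"`.
#' @export
classify_interface <- function(frame, pair, topology, map, contacts,
                               majority = 0.5) {
  ra <- contacts$residues_a; rb <- contacts$residues_b
  if (!length(ra) || !length(rb))
    stop("classification error: empty contact set for pair ",
         paste(pair, collapse = "-"), call. = FALSE)
  da <- domain_of(ra, map); db <- domain_of(rb, map)
  frac <- function(d, what) mean(d == what)
  cross_rung <- !is.null(topology) &&
    topology$rung_of[pair[1L]] != topology$rung_of[pair[2L]]
  if (cross_rung && frac(c(da, db), "g_domain") >= majority) return("GG")
  if ((frac(da, "stalk") >= majority && frac(db, "bse") >= majority) ||
      (frac(da, "bse") >= majority && frac(db, "stalk") >= majority))
    return("IF1")
  if (frac(da, "stalk") >= majority && frac(db, "stalk") >= majority) {
    if (any(c(ra, rb) %in% map$if2_core)) return("IF2")
    if (frac(c(ra, rb) %in% map$l1ns, TRUE) >= majority) return("IF3")
    return("unclassified")
  }
  "unclassified"
}

# Plain container for one interface observation.
interface_instance <- function(pair, itype, residues_a, residues_b,
                               area_A2 = NA_real_, frame_index = NA_integer_) {
  structure(list(pair = pair, itype = itype,
                 residues_a = residues_a, residues_b = residues_b,
                 area_A2 = area_A2, frame_index = frame_index),
            class = "interface_instance")
}

#' Interface area
#'
#' `exposed_sum` (default): summed in-assembly residue SASA over the contact
#' residues of both monomers -- the area included by amino acids falling
#' within the contact cutoff of the adjacent monomer.  `buried`: summed loss
#' of SASA between the isolated monomers and the pair.
#'
#' @param frame an `oligomer_frame`.
#' @param instance an `interface_instance` (from [catalog_interfaces()] or
#'   built manually).
#' @param sasa_cfg a [sasa_config()].
#' @param mode area definition, defaulting to `"exposed_sum"`.
#' @return area in A^2.
#' @export
interface_area <- function(frame, instance, sasa_cfg = sasa_config(),
                           mode = c("exposed_sum", "buried")) {
  mode <- match.arg(mode)
  if (!length(instance$residues_a) && !length(instance$residues_b)) return(0)
  a <- instance$pair[1L]; b <- instance$pair[2L]
  if (mode == "exposed_sum") {
    cfg <- sasa_cfg; cfg$context <- "in_assembly"
    s <- 0
    for (side in list(list(a, instance$residues_a), list(b, instance$residues_b))) {
      for (r in side[[2L]])
        s <- s + residue_sasa(frame, side[[1L]], r, cfg)$sasa_A2
    }
    return(s)
  }
  # buried: evaluate each contact residue in isolation and in the pair.
  pair_atoms <- frame$atoms[frame$atoms$monomer_id %in% c(a, b), , drop = FALSE]
  pair_frame <- oligomer_frame(pair_atoms, frame$frame_index,
                               resolution = frame$resolution)
  iso <- sasa_cfg; iso$context <- "isolated_monomer"
  inp <- sasa_cfg; inp$context <- "in_assembly"
  s <- 0
  for (side in list(list(a, instance$residues_a), list(b, instance$residues_b))) {
    for (r in side[[2L]]) {
      s <- s + residue_sasa(pair_frame, side[[1L]], r, iso)$sasa_A2 -
        residue_sasa(pair_frame, side[[1L]], r, inp)$sasa_A2
    }
  }
  max(0, s)
}

#' Catalog interface instances over a trajectory
#'
#' Evaluates candidate monomer pairs (within-rung neighbors plus G-G
#' partners) in every frame, classifies each non-empty contact set and
#' optionally measures areas on a subsample of frames.
#'
#' @param trajectory an [oligo_trajectory()].
#' @param topology an [assign_topology()] result.
#' @param map a [default_domain_map()].
#' @param config an [interface_config()].
#' @param sasa_cfg a [sasa_config()]; used when `n_area_frames > 0`.
#' @param n_area_frames number of (evenly spaced) frames on which interface
#'   areas are computed (areas are the slow step; default 5).
#' @return list of `interface_instance` objects.
#' @export
catalog_interfaces <- function(trajectory, topology,
                               map = default_domain_map(),
                               config = interface_config(),
                               sasa_cfg = sasa_config(),
                               n_area_frames = 5L) {
  ord <- topology$order
  pairs <- list()
  for (i in seq_along(ord)[-length(ord)]) {
    if (ord[i + 1L] %in% topology$within_rung_neighbors[[ord[i]]])
      pairs[[length(pairs) + 1L]] <- c(ord[i], ord[i + 1L])
  }
  if (nrow(topology$gg_partners))
    pairs <- c(pairs, split(topology$gg_partners,
                            seq_len(nrow(topology$gg_partners))))
  nf <- length(trajectory$frames)
  area_frames <- if (n_area_frames > 0L)
    unique(round(seq(1L, nf, length.out = min(n_area_frames, nf)))) else integer()
  out <- list()
  for (fi in seq_len(nf)) {
    f <- trajectory$frames[[fi]]
    for (p in pairs) {
      ct <- find_contact_residues(f, p[1L], p[2L], config)
      if (!length(ct$residues_a)) next
      ity <- classify_interface(f, p, topology, map, ct)
      inst <- interface_instance(p, ity, ct$residues_a, ct$residues_b,
                                 frame_index = f$frame_index)
      if (fi %in% area_frames)
        inst$area_A2 <- interface_area(f, inst, sasa_cfg,
                                       mode = config$area_mode)
      out[[length(out) + 1L]] <- inst
    }
  }
  out
}

#' Residue occupancy per interface type
#'
#' Occupancy of residue `r` in interface type `t` is the fraction of observed
#' (instance, frame) pairs of type `t` in which `r` belongs to the contact
#' residue set -- how often a residue participating in an interface is also
#' present in the same interface formed by other monomers or frames.
#'
#' @param instances list of `interface_instance` objects (one per
#'   instance-frame observation).
#' @return data frame: `itype`, `residue_number`, `count`, `n_obs`,
#'   `fraction` (in \[0, 1\]).
#' @export
occupancy <- function(instances) {
  if (!length(instances)) {
    warning("occupancy: no interface instances")
    return(data.frame(itype = character(), residue_number = integer(),
                      count = integer(), n_obs = integer(),
                      fraction = numeric()))
  }
  types <- vapply(instances, function(i) i$itype, character(1))
  out <- list()
  for (t in sort(unique(types))) {
    obs <- instances[types == t]
    resl <- lapply(obs, function(i) unique(c(i$residues_a, i$residues_b)))
    tab <- table(unlist(resl))
    out[[t]] <- data.frame(itype = t,
                           residue_number = as.integer(names(tab)),
                           count = as.integer(tab), n_obs = length(obs),
                           fraction = as.numeric(tab) / length(obs),
                           stringsAsFactors = FALSE)
  }
  rn <- do.call(rbind, out)
  rownames(rn) <- NULL
  rn
}

#' Hydrogen-bond criteria
#'
#' @param max_distance donor(-heavy-atom)/acceptor distance cutoff in
#'   Angstrom (default 3.5).
#' @param min_angle minimum angle in degrees (default 120): at the hydrogen
#'   (D-H...A) when hydrogens are present, otherwise at the donor using its
#'   nearest bonded heavy atom as antecedent (hydrogen-free proxy).
#' @param donors,acceptors atom-name lists.
#' @return object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_distance = 3.5, min_angle = 120,
                           donors = c("N", "NE", "NH1", "NH2", "NZ", "ND1",
                                      "NE2", "ND2", "OG", "OG1", "OH", "SG"),
                           acceptors = c("O", "OD1", "OD2", "OE1", "OE2",
                                         "OG", "OG1", "OH", "ND1", "NE2")) {
  stopifnot(max_distance > 0, min_angle > 0, min_angle <= 180)
  structure(list(max_distance = max_distance, min_angle = min_angle,
                 donors = donors, acceptors = acceptors),
            class = "hbond_criteria")
}

#' Salt-bridge criteria
#'
#' @param max_distance maximum distance between charged-group atoms in
#'   Angstrom (default 4.0).
#' @return object of class `salt_bridge_criteria` carrying the basic
#'   (Arg NH1/NH2/NE, Lys NZ, His ND1/NE2) and acidic (Asp OD1/OD2,
#'   Glu OE1/OE2) atom sets.
#' @export
salt_bridge_criteria <- function(max_distance = 4.0) {
  stopifnot(max_distance > 0)
  structure(list(
    max_distance = max_distance,
    basic = list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                 HIS = c("ND1", "NE2")),
    acidic = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))),
    class = "salt_bridge_criteria")
}

restrict_atoms <- function(atoms, residues) {
  if (is.null(residues)) atoms
  else atoms[atoms$residue_number %in% residues, , drop = FALSE]
}

#' Count cross-monomer hydrogen bonds
#'
#' Counts donor-acceptor atom pairs across the two monomers that satisfy the
#' distance and angle criteria.  Requires a full-atom frame.
#'
#' @param frame full-atom `oligomer_frame`.
#' @param pair character 2-vector of monomer ids.
#' @param criteria an [hbond_criteria()].
#' @param restrict_to optional `interface_instance` (or list with
#'   `residues_a`, `residues_b`): only residues of that interface are
#'   considered.
#' @return integer count.
#' @export
count_hbonds <- function(frame, pair, criteria = hbond_criteria(),
                         restrict_to = NULL) {
  if (frame$resolution != "full_atom")
    stop("resolution error: hydrogen bonds require a full-atom frame",
         call. = FALSE)
  ra <- if (!is.null(restrict_to)) restrict_to$residues_a
  rb <- if (!is.null(restrict_to)) restrict_to$residues_b
  aa <- restrict_atoms(frame$atoms[frame$atoms$monomer_id == pair[1L], ], ra)
  ab <- restrict_atoms(frame$atoms[frame$atoms$monomer_id == pair[2L], ], rb)
  count_hbonds_directional(aa, ab, criteria) +
    count_hbonds_directional(ab, aa, criteria)
}

count_hbonds_directional <- function(don_at, acc_at, criteria) {
  d <- don_at[don_at$atom_name %in% criteria$donors, , drop = FALSE]
  a <- acc_at[acc_at$atom_name %in% criteria$acceptors, , drop = FALSE]
  if (!nrow(d) || !nrow(a)) return(0L)
  d2 <- cross_dist2(coords(d), coords(a))
  hits <- which(d2 <= criteria$max_distance^2, arr.ind = TRUE)
  n <- 0L
  for (k in seq_len(nrow(hits))) {
    di <- hits[k, 1L]; ai <- hits[k, 2L]
    dp <- c(d$x[di], d$y[di], d$z[di])
    ap <- c(a$x[ai], a$y[ai], a$z[ai])
    # Hydrogen on the donor, if present, else nearest bonded heavy atom.
    same_res <- don_at$monomer_id == d$monomer_id[di] &
      don_at$residue_number == d$residue_number[di]
    others <- don_at[same_res & !(don_at$atom_name == d$atom_name[di]), ,
                     drop = FALSE]
    hyd <- others[grepl("^H", others$atom_name), , drop = FALSE]
    if (nrow(hyd)) {
      dh <- cross_dist2(coords(hyd), matrix(dp, 1L))
      h <- coords(hyd)[which.min(dh), ]
      ang <- angle_between(dp - h, ap - h)
    } else if (nrow(others)) {
      dh <- cross_dist2(coords(others), matrix(dp, 1L))
      ante <- coords(others)[which.min(dh), ]
      ang <- angle_between(ante - dp, ap - dp)
    } else ang <- 180
    if (ang >= criteria$min_angle) n <- n + 1L
  }
  n
}

#' Count cross-monomer salt bridges
#'
#' Basic-atom/acidic-atom pairs across the two monomers within the distance
#' cutoff, collapsed to one bridge per residue pair.
#'
#' @param frame full-atom `oligomer_frame`.
#' @param pair character 2-vector of monomer ids.
#' @param criteria a [salt_bridge_criteria()].
#' @param restrict_to optional interface restriction as in [count_hbonds()].
#' @return integer count.
#' @export
count_salt_bridges <- function(frame, pair, criteria = salt_bridge_criteria(),
                               restrict_to = NULL) {
  if (frame$resolution != "full_atom")
    stop("resolution error: salt bridges require a full-atom frame",
         call. = FALSE)
  ra <- if (!is.null(restrict_to)) restrict_to$residues_a
  rb <- if (!is.null(restrict_to)) restrict_to$residues_b
  aa <- restrict_atoms(frame$atoms[frame$atoms$monomer_id == pair[1L], ], ra)
  ab <- restrict_atoms(frame$atoms[frame$atoms$monomer_id == pair[2L], ], rb)
  charged <- function(at, groups) {
    keep <- rep(FALSE, nrow(at))
    for (res in names(groups))
      keep <- keep | (at$residue_name == res & at$atom_name %in% groups[[res]])
    at[keep, , drop = FALSE]
  }
  n <- 0L
  seen <- character()
  for (dir in list(list(aa, ab), list(ab, aa))) {
    bas <- charged(dir[[1L]], criteria$basic)
    aci <- charged(dir[[2L]], criteria$acidic)
    if (!nrow(bas) || !nrow(aci)) next
    d2 <- cross_dist2(coords(bas), coords(aci))
    hits <- which(d2 <= criteria$max_distance^2, arr.ind = TRUE)
    for (k in seq_len(nrow(hits))) {
      key <- paste(bas$monomer_id[hits[k, 1L]], bas$residue_number[hits[k, 1L]],
                   aci$monomer_id[hits[k, 2L]], aci$residue_number[hits[k, 2L]])
      if (!key %in% seen) { seen <- c(seen, key); n <- n + 1L }
    }
  }
  n
}

#' Residue-465 to neighbor-BSE interaction
#'
#' For each monomer carrying residue 465, contacts between that residue and
#' the BSE residues of its within-rung neighbor (the successor along the
#' helix when present, else the predecessor), with the interaction area.
#' In WT-like packing residue 465 touches P294/V744/S745 of the adjacent
#' BSE; the bulkier exposed tryptophan additionally reaches S298/S742.
#'
#' @param frame an `oligomer_frame`.
#' @param topology an [assign_topology()] result.
#' @param map a [default_domain_map()].
#' @param config an [interface_config()].
#' @param sasa_cfg a [sasa_config()]; set `measure_area = FALSE` to skip.
#' @param measure_area compute the interaction area (default TRUE).
#' @return list of `interface_instance` objects with `itype = "R465_BSE"`
#'   (one per monomer; empty contact sets give `area_A2 = 0`).
#' @export
residue465_bse_interaction <- function(frame, topology,
                                       map = default_domain_map(),
                                       config = interface_config(),
                                       sasa_cfg = sasa_config(),
                                       measure_area = TRUE) {
  site <- map$mutation_site
  out <- list()
  for (i in seq_along(topology$order)) {
    id <- topology$order[i]
    if (!length(atom_rows(frame, id, site))) next
    nb <- topology$within_rung_neighbors[[id]]
    if (!length(nb))
      stop("topology error: monomer ", id, " has no within-rung neighbor",
           call. = FALSE)
    succ <- if (i < length(topology$order)) topology$order[i + 1L]
    j <- if (!is.null(succ) && succ %in% nb) succ else nb[1L]
    a465 <- frame$atoms[frame$atoms$monomer_id == id &
                        frame$atoms$residue_number == site, , drop = FALSE]
    bse <- frame$atoms[frame$atoms$monomer_id == j &
                       frame$atoms$residue_number %in% map$bse, , drop = FALSE]
    inst <- if (nrow(bse)) {
      d2 <- cross_dist2(coords(a465), coords(bse))
      hit <- d2 <= config$contact_cutoff^2
      rb <- sort(unique(bse$residue_number[colSums(hit) > 0L]))
      interface_instance(c(id, j), "R465_BSE",
                         residues_a = if (length(rb)) site else integer(),
                         residues_b = rb, frame_index = frame$frame_index)
    } else interface_instance(c(id, j), "R465_BSE", integer(), integer(),
                              frame_index = frame$frame_index)
    inst$area_A2 <- if (!length(inst$residues_b)) 0
    else if (measure_area) interface_area(frame, inst, sasa_cfg) else NA_real_
    out[[id]] <- inst
  }
  out
}

#' Intra-monomer contact residues of a query residue
#'
#' Residues of the same monomer with any particle within the cutoff of the
#' query residue, excluding the query itself and its `exclude_bonded`
#' sequence neighbors on each side.
#'
#' @param frame an `oligomer_frame`.
#' @param monomer_id,residue_number query residue.
#' @param config an [interface_config()].
#' @param exclude_bonded how many sequence neighbors on each side to drop
#'   (default 1; use 0 to keep direct neighbors such as 466 next to 465).
#' @return sorted integer vector of residue numbers.
#' @export
intramonomer_contacts <- function(frame, monomer_id, residue_number,
                                  config = interface_config(),
                                  exclude_bonded = 1L) {
  at <- frame$atoms[frame$atoms$monomer_id == monomer_id, , drop = FALSE]
  q <- at[at$residue_number == residue_number, , drop = FALSE]
  if (!nrow(q))
    stop("selection error: residue ", residue_number, " of monomer ",
         monomer_id, " not found", call. = FALSE)
  excl <- seq.int(residue_number - exclude_bonded,
                  residue_number + exclude_bonded)
  rest <- at[!at$residue_number %in% excl, , drop = FALSE]
  if (!nrow(rest)) return(integer())
  d2 <- cross_dist2(coords(rest), coords(q))
  sort(unique(rest$residue_number[apply(d2 <= config$contact_cutoff^2, 1L, any)]))
}
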