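# Solvent-accessible surface area by Shrake-Rupley quadrature on a
# deterministic generalized-spiral point set, plus per-residue empirical
# normalization.

.dynhelix_cache <- new.env(parent = emptyenv())

#' SASA configuration
#'
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param points_per_sphere quadrature points per atom sphere (>= 92;
#'   default 960).
#' @param radii named radius table (see [radii_table()]).
#' @param context `"in_assembly"` (all other monomers occlude) or
#'   `"isolated_monomer"`.
#' @return object of class `sasa_config`.
#' @export
sasa_config <- function(probe_radius = 1.4, points_per_sphere = 960L,
                        radii = radii_table(),
                        context = c("in_assembly", "isolated_monomer")) {
  if (probe_radius <= 0) stop("probe_radius must be > 0", call. = FALSE)
  if (points_per_sphere < 92L)
    stop("points_per_sphere must be >= 92", call. = FALSE)
  structure(list(probe_radius = probe_radius,
                 points_per_sphere = as.integer(points_per_sphere),
                 radii = radii, context = match.arg(context)),
            class = "sasa_config")
}

# Deterministic generalized-spiral (Fibonacci) unit-sphere point set.
sphere_points <- function(n) {
  key <- as.character(n)
  if (!is.null(.dynhelix_cache[[key]])) return(.dynhelix_cache[[key]])
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (i - 1) * pi * (3 - sqrt(5))
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  .dynhelix_cache[[key]] <- pts
  pts
}

# Resolve per-atom radii: explicit radius column, then atom-name lookup,
# then element lookup; unknown names are an error.
atom_radii <- function(atoms, radii) {
  r <- atoms$radius
  need <- is.na(r)
  if (any(need)) {
    byname <- radii[atoms$atom_name[need]]
    el <- ifelse(is.na(atoms$element[need]) | !nzchar(atoms$element[need]),
                 substr(atoms$atom_name[need], 1L, 1L), atoms$element[need])
    byel <- radii[el]
    r[need] <- ifelse(!is.na(byname), byname, byel)
  }
  if (anyNA(r))
    stop("no radius for atom(s): ",
         paste(unique(atoms$atom_name[is.na(r)]), collapse = ", "),
         call. = FALSE)
  r
}

#' Shrake-Rupley per-atom solvent-accessible surface area
#'
#' Each atom's extended sphere (radius + probe) is sampled on a deterministic
#' spiral point set; the accessible fraction of points (outside every
#' neighbor's extended sphere) scales the analytic sphere area.
#'
#' @param atoms atom table; all rows act as occluders.
#' @param config a [sasa_config()].
#' @param subset integer row indices for which areas are computed (default
#'   all rows).
#' @return numeric vector of areas (A^2) along `subset`.
#' @export
shrake_rupley <- function(atoms, config = sasa_config(), subset = NULL) {
  if (is.null(subset)) subset <- seq_len(nrow(atoms))
  xyz <- coords(atoms)
  rad <- atom_radii(atoms, config$radii)
  probe <- config$probe_radius
  pts <- sphere_points(config$points_per_sphere)
  ext <- rad + probe
  areas <- numeric(length(subset))
  for (k in seq_along(subset)) {
    i <- subset[k]
    Ri <- ext[i]
    d2 <- (xyz[, 1L] - xyz[i, 1L])^2 + (xyz[, 2L] - xyz[i, 2L])^2 +
      (xyz[, 3L] - xyz[i, 3L])^2
    nbr <- which(d2 < (Ri + ext)^2 & d2 > 0)
    nbr <- nbr[nbr != i]
    if (!length(nbr)) { areas[k] <- 4 * pi * Ri^2; next }
    p <- pts * Ri
    p <- cbind(p[, 1L] + xyz[i, 1L], p[, 2L] + xyz[i, 2L], p[, 3L] + xyz[i, 3L])
    acc <- rep(TRUE, nrow(p))
    for (j in nbr) {
      dj2 <- (p[, 1L] - xyz[j, 1L])^2 + (p[, 2L] - xyz[j, 2L])^2 +
        (p[, 3L] - xyz[j, 3L])^2
      acc <- acc & dj2 >= ext[j]^2
      if (!any(acc)) break
    }
    areas[k] <- 4 * pi * Ri^2 * mean(acc)
  }
  areas
}

#' Residue SASA with empirical normalization
#'
#' @param frame an `oligomer_frame`.
#' @param monomer_id,residue_number residue to measure.
#' @param config a [sasa_config()]; `context = "in_assembly"` includes every
#'   other monomer as occluder, `"isolated_monomer"` only the residue's own
#'   monomer.
#' @param max_table named maximal-SASA vector (see [max_sasa_table()]).
#' @return one-row data frame: `monomer_id`, `residue_number`, `sasa_A2`,
#'   `normalized`.
#' @export
residue_sasa <- function(frame, monomer_id, residue_number,
                         config = sasa_config(),
                         max_table = max_sasa_table()) {
  atoms <- if (config$context == "in_assembly") frame$atoms else
    frame$atoms[frame$atoms$monomer_id == monomer_id, , drop = FALSE]
  sel <- which(atoms$monomer_id == monomer_id &
               atoms$residue_number == residue_number)
  if (!length(sel))
    stop("selection error: residue ", residue_number, " of monomer ",
         monomer_id, " not found", call. = FALSE)
  a <- sum(shrake_rupley(atoms, config, subset = sel))
  resname <- atoms$residue_name[sel[1L]]
  mx <- max_table[resname]
  data.frame(monomer_id = monomer_id, residue_number = residue_number,
             residue_name = resname, sasa_A2 = a,
             normalized = if (is.na(mx)) NA_real_ else a / unname(mx),
             stringsAsFactors = FALSE)
}

#' SASA profile over a trajectory window
#'
#' @param trajectory an [oligo_trajectory()].
#' @param residue_number residue to profile (e.g. the 465 mutation site).
#' @param monomers monomer ids (default all protein monomers).
#' @param config a [sasa_config()].
#' @param window a [window_spec()].
#' @param max_table named maximal-SASA vector.
#' @return data frame with one row per (frame, monomer): `monomer_id`,
#'   `residue_number`, `frame_index`, `sasa_A2`, `normalized`; attribute
#'   `window_mean` holds per-monomer means.
#' @export
sasa_profile <- function(trajectory, residue_number, monomers = NULL,
                         config = sasa_config(), window = window_spec("all"),
                         max_table = max_sasa_table()) {
  trajectory <- select_window(trajectory, window)
  if (is.null(monomers))
    monomers <- monomer_ids(trajectory, proteins_only = TRUE)
  out <- list()
  for (f in trajectory$frames) {
    for (id in monomers) {
      r <- residue_sasa(f, id, residue_number, config, max_table)
      r$frame_index <- f$frame_index
      out[[length(out) + 1L]] <- r
    }
  }
  out <- do.call(rbind, out)
  wm <- stats::aggregate(cbind(sasa_A2, normalized) ~ monomer_id, data = out,
                         FUN = mean)
  attr(out, "window_mean") <- wm
  out
}
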