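# Assembly topology: rung assignment, tetramer grouping, neighbor graphs,
# and analysis-window selection.

#' Analysis window specification
#'
#' @param mode `"last_n_frames"`, `"last_t_ns"` or `"all"`.
#' @param value positive number (frame count or time span in ns); ignored for
#'   `"all"`.
#' @return object of class `window_spec`.
#' @export
window_spec <- function(mode = c("all", "last_n_frames", "last_t_ns"),
                        value = NULL) {
  mode <- match.arg(mode)
  if (mode != "all") {
    if (is.null(value) || !is.finite(value) || value <= 0)
      stop("window_spec: value must be a positive number", call. = FALSE)
  }
  structure(list(mode = mode, value = value), class = "window_spec")
}

#' Restrict a trajectory to its analysis window
#'
#' Returns the suffix of frames selected by `spec`; the applied window is
#' recorded in the trajectory metadata.  Idempotent.
#'
#' @param trajectory an [oligo_trajectory()].
#' @param spec a [window_spec()].
#' @return the windowed [oligo_trajectory()].
#' @export
select_window <- function(trajectory, spec) {
  stopifnot(inherits(trajectory, "oligo_trajectory"),
            inherits(spec, "window_spec"))
  n <- length(trajectory$frames)
  keep <- switch(spec$mode,
    all = seq_len(n),
    last_n_frames = {
      if (spec$value > n)
        stop("window: last_n_frames = ", spec$value,
             " exceeds trajectory length ", n, call. = FALSE)
      seq.int(n - as.integer(spec$value) + 1L, n)
    },
    last_t_ns = {
      times <- vapply(trajectory$frames, function(f) f$time_ns, numeric(1))
      if (anyNA(times))
        stop("window: last_t_ns requested but frames lack time_ns",
             call. = FALSE)
      which(times >= max(times) - spec$value)
    })
  meta <- trajectory$metadata
  meta$window <- list(mode = spec$mode, value = spec$value,
                      n_frames = length(keep))
  oligo_trajectory(trajectory$frames[keep], metadata = meta)
}

# Uniform or mass-weighted COM of each monomer, as a matrix keyed by id.
monomer_coms <- function(frame, ids = NULL, weighting = NULL) {
  if (is.null(ids)) ids <- monomer_ids(frame, proteins_only = TRUE)
  if (is.null(weighting))
    weighting <- if (frame$resolution == "full_atom") "mass" else "uniform"
  out <- matrix(NA_real_, length(ids), 3L, dimnames = list(ids, c("x", "y", "z")))
  for (id in ids) {
    at <- frame$atoms[frame$atoms$monomer_id == id, ]
    out[id, ] <- center_of_mass(at, weighting = weighting)
  }
  out
}

#' Assign helical-assembly topology
#'
#' Monomers are ordered along the helix (axial position, then azimuth about
#' the axis, then monomer id for determinism), grouped into consecutive
#' tetramers, and assigned rung indices from the accumulated azimuth.
#' Cross-rung monomer pairs whose G-domain particles approach within the
#' contact cutoff become G-G partners.
#'
#' @param frame an `oligomer_frame` (lipid pseudo-monomer `"TUBE"` ignored).
#' @param helix_axis 3-vector giving the approximate helix axis direction.
#' @param tetramer_size monomers per tetramer (default 4).
#' @param map a [default_domain_map()].
#' @param contact_cutoff G-G contact cutoff in Angstrom (default 6).
#' @return object of class `assembly_topology` with elements `order`,
#'   `rung_of`, `tetramer_of`, `within_rung_neighbors`, `gg_partners`.
#' @export
assign_topology <- function(frame, helix_axis = c(0, 0, 1), tetramer_size = 4L,
                            map = default_domain_map(), contact_cutoff = 6.0) {
  ids <- monomer_ids(frame, proteins_only = TRUE)
  n <- length(ids)
  if (n %% tetramer_size != 0L)
    stop("topology: ", n, " monomers not divisible by tetramer size ",
         tetramer_size, call. = FALSE)
  axis <- helix_axis / sqrt(sum(helix_axis^2))
  coms <- monomer_coms(frame, ids)
  center <- colMeans(coms)
  rel <- sweep(coms, 2L, center)
  axial <- drop(rel %*% axis)
  # Orthonormal basis perpendicular to the axis for azimuth measurement.
  ref <- if (abs(axis[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2L] * e1[3L] - axis[3L] * e1[2L],
          axis[3L] * e1[1L] - axis[1L] * e1[3L],
          axis[1L] * e1[2L] - axis[2L] * e1[1L])
  azim <- atan2(drop(rel %*% e2), drop(rel %*% e1))
  ord <- order(axial, azim, ids)
  ids_o <- ids[ord]
  un <- unwrap_angles(azim[ord])
  # Rung = accumulated turns; a half-step offset makes the floor robust to
  # coordinate noise at exact turn boundaries.
  step <- if (n > 1L) mean(diff(un)) else 0
  rung <- floor((un - un[1L] + step / 2) / (2 * pi))
  rung <- as.integer(rung - min(rung))
  tet <- as.integer((seq_len(n) - 1L) %/% tetramer_size)
  rung_of <- stats::setNames(rung, ids_o)
  tetramer_of <- stats::setNames(tet, ids_o)
  nbrs <- stats::setNames(vector("list", n), ids_o)
  for (i in seq_len(n)) {
    cand <- c(if (i > 1L) ids_o[i - 1L], if (i < n) ids_o[i + 1L])
    nbrs[[ids_o[i]]] <- cand[rung_of[cand] == rung[i]]
  }
  gg <- find_gg_partners(frame, ids_o, rung_of, map, contact_cutoff, coms)
  structure(list(order = ids_o, rung_of = rung_of, tetramer_of = tetramer_of,
                 within_rung_neighbors = nbrs, gg_partners = gg,
                 axis = list(point = center, direction = axis),
                 tetramer_size = as.integer(tetramer_size)),
            class = "assembly_topology")
}

#' @export
print.assembly_topology <- function(x, ...) {
  cat(sprintf("<assembly_topology> %d monomers, %d rungs, %d tetramers, %d G-G pairs\n",
              length(x$order), length(unique(x$rung_of)),
              length(unique(x$tetramer_of)), nrow(x$gg_partners)))
  invisible(x)
}

unwrap_angles <- function(a) {
  if (length(a) < 2L) return(a)
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(a[1L], d))
}

find_gg_partners <- function(frame, ids, rung_of, map, cutoff, coms) {
  g_atoms <- lapply(ids, function(id)
    coords(frame$atoms[frame$atoms$monomer_id == id &
                       frame$atoms$residue_number %in% map$g_domain, ,
                       drop = FALSE]))
  names(g_atoms) <- ids
  pairs <- matrix(character(), 0L, 2L,
                  dimnames = list(NULL, c("monomer_a", "monomer_b")))
  n <- length(ids)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      a <- ids[i]; b <- ids[j]
      if (rung_of[a] == rung_of[b]) next
      if (sqrt(sum((coms[a, ] - coms[b, ])^2)) > 150) next
      if (!nrow(g_atoms[[a]]) || !nrow(g_atoms[[b]])) next
      if (min_cross_distance(g_atoms[[a]], g_atoms[[b]]) <= cutoff)
        pairs <- rbind(pairs, c(a, b))
    }
  }
  pairs
}

# Minimum inter-particle distance between two coordinate matrices.
min_cross_distance <- function(xa, xb) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(max(0, min(d2)))
}
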