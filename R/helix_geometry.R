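# Helical-lattice geometry: axis fitting, diameter, pitch, helix angle, and
# per-tetramer radius-of-gyration series.

#' Fit the helix axis of an assembly frame
#'
#' The initial direction is the principal axis of the monomer centers of
#' mass; axis direction and a point on the axis are then refined by
#' minimizing the variance of the radial distances of the monomer COMs
#' (Nelder-Mead, deterministic start).
#'
#' @param frame an `oligomer_frame` with >= 8 protein monomers.
#' @param topology optional [assign_topology()] result (for monomer order).
#' @return list with unit 3-vector `direction` and 3-vector `point`.
#' @export
fit_axis <- function(frame, topology = NULL) {
  ids <- if (!is.null(topology)) topology$order
  else monomer_ids(frame, proteins_only = TRUE)
  if (length(ids) < 8L)
    stop("fit_axis: need at least 8 monomers", call. = FALSE)
  coms <- monomer_coms(frame, ids)
  center <- colMeans(coms)
  rel <- sweep(coms, 2L, center)
  ev <- eigen(crossprod(rel) / nrow(rel), symmetric = TRUE)
  if (ev$values[2L] < 1e-8 * ev$values[1L])
    stop("fit_axis: degenerate (collinear) monomer centers", call. = FALSE)
  # Start from whichever principal direction minimizes the radial variance:
  # the long axis for extended helices, the plane normal for flat rings.
  cand_obj <- vapply(1:3, function(k)
    stats::var(radial_distances(coms, center, ev$vectors[, k])), numeric(1))
  dir0 <- ev$vectors[, which.min(cand_obj)]
  obj <- function(par) {
    d <- rotate_dir(dir0, par[1L], par[2L])
    p <- center + par[3L] * basis_perp(d)$e1 + par[4L] * basis_perp(d)$e2
    r <- radial_distances(coms, p, d)
    stats::var(r)
  }
  fit <- stats::optim(c(0, 0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  d <- rotate_dir(dir0, fit$par[1L], fit$par[2L])
  p <- center + fit$par[3L] * basis_perp(d)$e1 + fit$par[4L] * basis_perp(d)$e2
  # Canonical orientation: positive z-component (or x/y fallback).
  s <- sign(d[3L]); if (s == 0) s <- sign(d[1L] + d[2L]); if (s == 0) s <- 1
  list(direction = s * d, point = p)
}

basis_perp <- function(d) {
  ref <- if (abs(d[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * d) * d; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2L] * e1[3L] - d[3L] * e1[2L],
          d[3L] * e1[1L] - d[1L] * e1[3L],
          d[1L] * e1[2L] - d[2L] * e1[1L])
  list(e1 = e1, e2 = e2)
}

# Tilt dir0 by small spherical offsets (a, b) in its perpendicular plane.
rotate_dir <- function(dir0, a, b) {
  bp <- basis_perp(dir0)
  d <- dir0 + a * bp$e1 + b * bp$e2
  d / sqrt(sum(d^2))
}

radial_distances <- function(coms, point, dir) {
  rel <- sweep(coms, 2L, point)
  ax <- drop(rel %*% dir)
  sqrt(pmax(0, rowSums(rel^2) - ax^2))
}

#' Helical parameters of one frame
#'
#' After axis fitting, monomer COMs are expressed in cylindrical coordinates
#' and the azimuth is unwrapped along the assembly order.  Linear fits of
#' axial position and azimuth against monomer index give the rise per
#' monomer and the azimuthal step; from these: `monomers_per_turn = 2*pi /
#' step`, `pitch = rise * monomers_per_turn`, and the helix (pitch) angle
#' `atan(rise / (radius * step))` -- the angle between the local helical
#' path and the plane normal to the axis.
#'
#' @param frame an `oligomer_frame`.
#' @param topology an [assign_topology()] result (assembly order).
#' @return data frame of class `helix_params`: `diameter_A`,
#'   `outer_diameter_A`, `pitch_A`, `helix_angle_deg`, `rise_per_monomer_A`,
#'   `monomers_per_turn`; the fitted axis is attached as attribute `axis`.
#' @export
helix_params <- function(frame, topology) {
  axis <- fit_axis(frame, topology)
  ids <- topology$order
  coms <- monomer_coms(frame, ids)
  d <- axis$direction; p <- axis$point
  rel <- sweep(coms, 2L, p)
  axial <- drop(rel %*% d)
  bp <- basis_perp(d)
  azim <- atan2(drop(rel %*% bp$e2), drop(rel %*% bp$e1))
  radius <- mean(radial_distances(coms, p, d))
  un <- unwrap_angles(azim)
  dstep <- diff(un)
  # Either handedness is fine; mixed azimuthal steps mean the assembly order
  # is unreliable for this frame, so fall back to axial ordering.
  if (length(dstep) &&
      !(all(dstep > 0 & dstep < pi) || all(dstep < 0 & dstep > -pi))) {
    warning("helix_params: non-monotone azimuth; re-ordering by axial position")
    o <- order(axial)
    axial <- axial[o]; un <- unwrap_angles(azim[o])
  }
  idx <- seq_along(ids)
  step <- unname(stats::coef(stats::lm(un ~ idx))[2L])
  rise <- unname(stats::coef(stats::lm(axial ~ idx))[2L])
  if (step < 0) { step <- -step; rise <- -rise }  # direction convention
  rise <- abs(rise)
  mpt <- 2 * pi / step
  # Outer diameter: maximal radial extent of any particle (figure envelope).
  prot <- frame$atoms[frame$atoms$monomer_id %in% ids, , drop = FALSE]
  router <- max(radial_distances(coords(prot), p, d))
  out <- data.frame(diameter_A = 2 * radius, outer_diameter_A = 2 * router,
                    pitch_A = rise * mpt,
                    helix_angle_deg = atan2(rise, radius * step) * 180 / pi,
                    rise_per_monomer_A = rise, monomers_per_turn = mpt)
  attr(out, "axis") <- axis
  class(out) <- c("helix_params", "data.frame")
  out
}

#' Helix-parameter series over a trajectory
#'
#' @param trajectory an [oligo_trajectory()].
#' @param topology an [assign_topology()] result.
#' @return data frame with one row per frame (`frame_index` plus the
#'   [helix_params()] columns).
#' @export
helix_params_series <- function(trajectory, topology) {
  out <- lapply(trajectory$frames, function(f) {
    hp <- helix_params(f, topology)
    cbind(data.frame(frame_index = f$frame_index), as.data.frame(hp))
  })
  do.call(rbind, out)
}

#' Per-tetramer radius-of-gyration series
#'
#' @param trajectory an [oligo_trajectory()].
#' @param topology an [assign_topology()] result.
#' @param window a [window_spec()].
#' @return data frame `tetramer`, `frame_index`, `rg_A`; per-tetramer window
#'   means attached as attribute `window_mean`.
#' @export
tetramer_rg_series <- function(trajectory, topology,
                               window = window_spec("all")) {
  trajectory <- select_window(trajectory, window)
  tets <- sort(unique(topology$tetramer_of))
  members <- lapply(tets, function(t)
    names(topology$tetramer_of)[topology$tetramer_of == t])
  out <- list()
  for (f in trajectory$frames) {
    w <- default_weighting(f)
    for (k in seq_along(tets)) {
      at <- f$atoms[f$atoms$monomer_id %in% members[[k]], , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        tetramer = tets[k], frame_index = f$frame_index,
        rg_A = radius_of_gyration(at, weighting = w))
    }
  }
  out <- do.call(rbind, out)
  attr(out, "window_mean") <-
    stats::aggregate(rg_A ~ tetramer, data = out, FUN = mean)
  out
}
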