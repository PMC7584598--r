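# Shared fixtures and independent brute-force oracles.

# Minimal frame from a compact spec: list(monomer_id = list(residue_number =
# matrix-of-atom-positions)).  All atoms named BB (CG) unless full_atom.
tiny_frame <- function(spec, resolution = "coarse_grained",
                       residue_name = "ALA", atom_name = NULL,
                       masses = NULL) {
  rows <- list()
  serial <- 0L
  for (mid in names(spec)) {
    for (res in names(spec[[mid]])) {
      xyz <- spec[[mid]][[res]]
      if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L, byrow = TRUE)
      for (i in seq_len(nrow(xyz))) {
        serial <- serial + 1L
        rows[[serial]] <- data.frame(
          serial = serial,
          atom_name = if (is.null(atom_name)) {
            if (resolution == "coarse_grained") "BB" else "CA"
          } else atom_name,
          residue_name = residue_name, residue_number = as.integer(res),
          monomer_id = mid, x = xyz[i, 1L], y = xyz[i, 2L], z = xyz[i, 3L],
          mass = if (is.null(masses)) 1 else masses[[serial]],
          radius = NA_real_, element = "C", stringsAsFactors = FALSE)
      }
    }
  }
  oligomer_frame(do.call(rbind, rows), resolution = resolution)
}

# All-pairs brute-force contact oracle (scalar loops, sqrt distances).
oracle_contacts <- function(frame, a, b, cutoff = 6.0) {
  aa <- frame$atoms[frame$atoms$monomer_id == a, ]
  ab <- frame$atoms[frame$atoms$monomer_id == b, ]
  ra <- integer(); rb <- integer()
  for (i in seq_len(nrow(aa))) {
    for (j in seq_len(nrow(ab))) {
      d <- sqrt((aa$x[i] - ab$x[j])^2 + (aa$y[i] - ab$y[j])^2 +
                (aa$z[i] - ab$z[j])^2)
      if (d <= cutoff) {
        ra <- c(ra, aa$residue_number[i])
        rb <- c(rb, ab$residue_number[j])
      }
    }
  }
  list(residues_a = sort(unique(ra)), residues_b = sort(unique(rb)))
}

# Loop-based radius-of-gyration oracle.
oracle_rg <- function(xyz, w) {
  com <- c(sum(xyz[, 1] * w), sum(xyz[, 2] * w), sum(xyz[, 3] * w)) / sum(w)
  s <- 0
  for (i in seq_len(nrow(xyz))) s <- s + w[i] * sum((xyz[i, ] - com)^2)
  sqrt(s / sum(w))
}

# Dense Monte-Carlo SASA oracle for a set of spheres (centers, radii already
# probe-extended): random directions, independent of the spiral quadrature.
oracle_mc_sasa <- function(centers, ext_radii, n_points = 1e5, seed = 99) {
  set.seed(seed)
  total <- numeric(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    u <- matrix(rnorm(n_points * 3), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * ext_radii[i], 2L, centers[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in seq_len(nrow(centers))) {
      if (j == i) next
      d2 <- (p[, 1] - centers[j, 1])^2 + (p[, 2] - centers[j, 2])^2 +
        (p[, 3] - centers[j, 3])^2
      acc <- acc & d2 >= ext_radii[j]^2
    }
    total[i] <- 4 * pi * ext_radii[i]^2 * mean(acc)
  }
  total
}

# Rigid-body transform of a frame: rotation about axis u by angle, plus shift.
rotate_frame <- function(frame, angle = 0.7, axis = c(1, 2, 3),
                         shift = c(5, -3, 11)) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3L, 3L,
              byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  xyz <- cbind(frame$atoms$x, frame$atoms$y, frame$atoms$z) %*% t(R)
  frame$atoms$x <- xyz[, 1] + shift[1]
  frame$atoms$y <- xyz[, 2] + shift[2]
  frame$atoms$z <- xyz[, 3] + shift[3]
  list(frame = frame, R = R, shift = shift)
}

# Small randomized two-monomer assembly on a half-Angstrom grid (so exact
# 6.0 A separations occur), for contact-oracle equivalence checks.
random_assembly <- function(seed) {
  set.seed(seed)
  mk <- function(n_res, offset) {
    xyz <- matrix(sample(seq(0, 30, by = 0.5), n_res * 9, replace = TRUE),
                  ncol = 3L)
    xyz[, 1] <- xyz[, 1] + offset
    split.data.frame(xyz, rep(seq_len(n_res), each = 3L))
  }
  spec <- list(A = mk(sample(3:6, 1), 0), B = mk(sample(3:6, 1), 25))
  names(spec$A) <- as.character(seq_along(spec$A))
  names(spec$B) <- as.character(seq_along(spec$B))
  tiny_frame(spec)
}
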