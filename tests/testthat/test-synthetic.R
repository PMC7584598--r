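# Synthetic-assembly generator: exactness, determinism, ground truth.

test_that("monomer angle targets are hit exactly at both resolutions", {
  for (res in c("coarse_grained", "full_atom")) {
    for (tg in c(118, 150, 135.5)) {
      m <- build_monomer(tg, 109, resolution = res)
      expect_equal(g_bse_angle(m, "A"), tg, tolerance = 1e-6)
      expect_equal(bse_stalk_angle(m, "A"), 109, tolerance = 1e-6)
    }
  }
  m2 <- build_monomer(120, 95)
  expect_equal(bse_stalk_angle(m2, "A"), 95, tolerance = 1e-6)
  expect_error(build_monomer(180, 109), "construction|0, 180")
  expect_error(build_monomer(0, 109), "construction|0, 180")
})

test_that("genotype controls the residue-465 identity", {
  wt <- build_monomer(genotype = "WT")
  mut <- build_monomer(genotype = "R465W")
  expect_equal(unique(wt$atoms$residue_name[wt$atoms$residue_number == 465]),
               "ARG")
  expect_equal(unique(mut$atoms$residue_name[mut$atoms$residue_number == 465]),
               "TRP")
  expect_equal(unname(monomer_genotypes(wt)["A"]), "WT")
  expect_equal(unname(monomer_genotypes(mut)["A"]), "R465W")
})

test_that("helix generation is deterministic given the seed", {
  h1 <- build_helix(n_frames = 3, noise_sigma_A = 0.7, seed = 123)
  h2 <- build_helix(n_frames = 3, noise_sigma_A = 0.7, seed = 123)
  expect_identical(h1$frames, h2$frames)
  h3 <- build_helix(n_frames = 3, noise_sigma_A = 0.7, seed = 124)
  expect_false(identical(h1$frames[[1]]$atoms$x, h3$frames[[1]]$atoms$x))
  # generation does not disturb the caller's RNG stream
  set.seed(9); a <- rnorm(1)
  set.seed(9); invisible(build_helix(n_frames = 1, noise_sigma_A = 1,
                                     seed = 5)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("alternating pattern intercalates 28 WT with 28 mutants", {
  h <- build_helix(genotype_pattern = "alternating")
  geno <- monomer_genotypes(h$frames[[1]])
  expect_equal(sum(geno == "WT"), 28L)
  expect_equal(sum(geno == "R465W"), 28L)
  ord <- h$metadata$ground_truth$order
  expect_true(all(geno[ord][c(TRUE, FALSE)] == "WT"))
  expect_true(all(geno[ord][c(FALSE, TRUE)] == "R465W"))
  expect_error(build_helix(n_monomers = 54), "divisible")
})

test_that("generator ground truth is recovered by the analyzers (closed loop)", {
  h <- build_helix(genotype_pattern = "alternating")
  f <- h$frames[[1]]
  gt <- h$metadata$ground_truth
  topo <- assign_topology(f)
  expect_identical(topo$rung_of[gt$order], gt$rung)
  expect_identical(topo$tetramer_of[gt$order], gt$tetramer)
  hp <- helix_params(f, topo)
  expect_equal(hp$diameter_A, gt$helix$diameter_A, tolerance = 0.001)
  expect_equal(hp$pitch_A, gt$helix$pitch_A, tolerance = 0.001)
  expect_equal(hp$helix_angle_deg, gt$helix$helix_angle_deg,
               tolerance = 0.001)
  ang <- angle_series(oligo_trajectory(list(f)))
  gm <- ang[ang$angle_name == "g_bse", ]
  expect_equal(stats::setNames(gm$degrees, gm$monomer_id)[gt$order],
               gt$g_bse_target, tolerance = 1e-6)
})

test_that("noise ablation: estimator error shrinks with noise and frames", {
  err_for <- function(sigma, n_frames, seed = 77) {
    h <- build_helix(n_frames = n_frames, noise_sigma_A = sigma, seed = seed)
    ang <- angle_series(h, which = "g_bse")
    m <- tapply(ang$degrees, ang$monomer_id, mean)
    gt <- h$metadata$ground_truth$g_bse_target
    sqrt(mean((m[names(gt)] - gt)^2))
  }
  e0 <- err_for(0, 1)
  e_small <- err_for(0.3, 4)
  e_big <- err_for(1.5, 4)
  expect_lt(e0, 1e-6)
  expect_lt(e_small, e_big)
  # more frames shrink the per-monomer standard error (~1/sqrt(n))
  e_n4 <- err_for(1.0, 4, seed = 31)
  e_n16 <- err_for(1.0, 16, seed = 31)
  expect_lt(e_n16, e_n4)
})

test_that("dimer: crisscross interface-2 that loosening weakens", {
  tight <- build_dimer("WT", "R465W")
  expect_equal(unname(monomer_genotypes(tight)), c("WT", "R465W"))
  loose <- build_dimer("WT", "R465W", interface_mode = "loosened")
  ct_t <- find_contact_residues(tight, "A", "B")
  ct_l <- find_contact_residues(loose, "A", "B")
  n_t <- length(ct_t$residues_a) + length(ct_t$residues_b)
  n_l <- length(ct_l$residues_a) + length(ct_l$residues_b)
  expect_gt(n_t, 0)
  expect_lt(n_l, n_t)
  expect_equal(classify_interface(tight, c("A", "B"), NULL,
                                  default_domain_map(), ct_t), "IF2")
  expect_identical(build_dimer("WT", "WT")$atoms,
                   build_dimer("WT", "WT")$atoms)
})

test_that("nanotube lattice hits the requested envelope", {
  tube <- build_nanotube(137, length_A = 50, bead_spacing_A = 3.5)
  r <- sqrt(tube$atoms$x^2 + tube$atoms$y^2)
  expect_lt(abs(max(r) - 68.5), 3.5 / 2)
  ring <- build_nanotube(137, length_A = 0)
  expect_equal(length(unique(ring$atoms$z)), 1L)
  n1 <- nrow(build_nanotube(137, 50, 3.5)$atoms)
  n2 <- nrow(build_nanotube(137, 50, 7)$atoms)
  expect_equal(n1 / n2, 4, tolerance = 0.2)
  expect_error(build_nanotube(10, 10, 20), "spacing")
  # attached to a helix it appears as the TUBE pseudo-monomer
  h <- build_helix(n_monomers = 8, monomers_per_turn = 8,
                   nanotube = list(outer_diameter_A = 137, length_A = 30))
  expect_true("TUBE" %in% monomer_ids(h))
  expect_false("TUBE" %in% monomer_ids(h, proteins_only = TRUE))
})
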