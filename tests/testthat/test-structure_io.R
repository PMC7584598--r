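# Structure reading/writing and assembly topology.

test_that("PDB round-trip preserves ids, numbering and coordinates", {
  spec <- list(A = lapply(1:10, function(r) matrix(rnorm(3, r), 1)),
               B = lapply(1:10, function(r) matrix(rnorm(3, -r), 1)))
  names(spec$A) <- as.character(1:10); names(spec$B) <- as.character(1:10)
  set.seed(1)
  f <- tiny_frame(spec, resolution = "full_atom")
  path <- tempfile(fileext = ".pdb")
  write_structure(f, path, format = "pdb")
  tr <- read_structure(path)
  expect_length(tr$frames, 1L)
  expect_setequal(monomer_ids(tr), c("A", "B"))
  a0 <- f$atoms[order(f$atoms$monomer_id, f$atoms$serial), ]
  a1 <- tr$frames[[1]]$atoms[order(tr$frames[[1]]$atoms$monomer_id,
                                   tr$frames[[1]]$atoms$serial), ]
  expect_equal(a1$residue_number, a0$residue_number)
  expect_lt(max(abs(a1$x - a0$x), abs(a1$y - a0$y), abs(a1$z - a0$z)), 1e-3)
})

test_that("bio3d agrees with our PDB writer on a dimer fixture", {
  d <- build_dimer("WT", "R465W")
  path <- tempfile(fileext = ".pdb")
  write_structure(d, path, format = "pdb")
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  expect_setequal(unique(pdb$atom$chain), c("A", "B"))
  expect_equal(nrow(pdb$atom), nrow(d$atoms))
  expect_equal(sort(pdb$atom$x), sort(round(d$atoms$x, 3)), tolerance = 1e-6)
})

test_that("multi-model mmCIF round-trips a 56-monomer helix", {
  h <- build_helix(n_frames = 3, noise_sigma_A = 0.3, seed = 11)
  path <- tempfile(fileext = ".cif")
  write_structure(h, path, format = "mmcif")
  tr <- read_structure(path)
  expect_length(tr$frames, 3L)
  expect_setequal(monomer_ids(tr), monomer_ids(h))
  expect_equal(tr$frames[[1]]$resolution, "coarse_grained")
  for (k in c(1L, 3L)) {
    a0 <- h$frames[[k]]$atoms
    a1 <- tr$frames[[k]]$atoms
    expect_equal(a1$residue_number, a0$residue_number)
    expect_lt(max(abs(a1$x - a0$x)), 1e-3)
  }
  # topology identical after the round trip
  t0 <- assign_topology(h$frames[[1]])
  t1 <- assign_topology(tr$frames[[1]])
  expect_identical(t0$rung_of, t1$rung_of)
  expect_identical(t0$tetramer_of, t1$tetramer_of)
})

test_that("inconsistent monomer sets across models raise a consistency error", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA B   1       5.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA B   1       5.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL", "END"), path)
  expect_error(read_structure(path), "inconsistent|consistency|dimension|mismatch")
})

test_that("pdb format refuses more than 62 monomers", {
  spec <- lapply(1:70, function(i) list("1" = matrix(c(i * 10, 0, 0), 1)))
  names(spec) <- sprintf("M%02d", 1:70)
  f <- tiny_frame(spec)
  expect_error(write_structure(f, tempfile(), format = "pdb"), "mmcif")
})

test_that("unparseable mmCIF names the offending location", {
  path <- tempfile(fileext = ".cif")
  writeLines(c("data_x", "loop_", "_atom_site.id", "_atom_site.Cartn_x",
               "1 2 3 4"), path)
  expect_error(read_structure(path), "line|token|parse")
  writeLines(c("data_x", "# nothing"), path)
  expect_error(read_structure(path), "atom_site")
})

test_that("topology: generated helices give the designed rungs and tetramers", {
  # two-turn helix: 28 monomers per turn
  h <- build_helix(monomers_per_turn = 28, rise_per_monomer_A = 8)
  topo <- assign_topology(h$frames[[1]])
  expect_equal(length(unique(topo$tetramer_of)), 14L)
  expect_equal(sort(unique(topo$rung_of)), c(0L, 1L))
  gt <- h$metadata$ground_truth
  expect_identical(topo$rung_of[gt$order], gt$rung)
  expect_identical(topo$tetramer_of[gt$order], gt$tetramer)
  # standard four-turn helix: G-G partners are the vertical neighbor pairs
  h4 <- build_helix()
  topo4 <- assign_topology(h4$frames[[1]])
  got <- apply(topo4$gg_partners, 1L, paste, collapse = "-")
  want <- apply(h4$metadata$ground_truth$gg_pairs, 1L, paste, collapse = "-")
  expect_setequal(got, want)
})

test_that("topology: single ring has one rung and no G-G partners", {
  h <- build_helix(n_monomers = 4L, monomers_per_turn = 4,
                   rise_per_monomer_A = 0.001)
  topo <- assign_topology(h$frames[[1]])
  expect_equal(unique(topo$tetramer_of), 0L)
  expect_equal(unique(topo$rung_of), 0L)
  expect_equal(nrow(topo$gg_partners), 0L)
})

test_that("topology errors when count is not divisible by tetramer size", {
  spec <- lapply(1:6, function(i)
    list("30" = matrix(c(cos(i) * 50, sin(i) * 50, i), 1)))
  names(spec) <- sprintf("M%d", 1:6)
  expect_error(assign_topology(tiny_frame(spec)), "divisible")
})

test_that("topology is invariant under rigid-body transforms", {
  h <- build_helix(n_frames = 1, noise_sigma_A = 0.4, seed = 3)
  f <- h$frames[[1]]
  t0 <- assign_topology(f, helix_axis = c(0, 0, 1))
  rot <- rotate_frame(f)
  t1 <- assign_topology(rot$frame, helix_axis = drop(rot$R %*% c(0, 0, 1)))
  expect_identical(t0$rung_of, t1$rung_of)
  expect_identical(t0$tetramer_of, t1$tetramer_of)
  expect_identical(t0$order, t1$order)
})

test_that("select_window implements suffix semantics and is idempotent", {
  spec <- list(A = list("1" = matrix(0, 1, 3)))
  frames <- lapply(1:100, function(i) {
    f <- tiny_frame(spec)
    f$frame_index <- i - 1L
    f$time_ns <- (i - 1L) * 50
    f
  })
  tr <- oligo_trajectory(frames)
  w10 <- select_window(tr, window_spec("last_n_frames", 10))
  expect_equal(vapply(w10$frames, function(f) f$frame_index, integer(1)),
               90:99)
  wt <- select_window(tr, window_spec("last_t_ns", 500))
  expect_true(all(vapply(wt$frames, function(f) f$time_ns, numeric(1)) >= 4450))
  expect_equal(length(wt$frames), 11L)  # 4450..4950 inclusive of the edge
  expect_identical(select_window(tr, window_spec("all"))$frames, tr$frames)
  again <- select_window(wt, window_spec("last_t_ns", 500))
  expect_identical(lapply(again$frames, `[[`, "frame_index"),
                   lapply(wt$frames, `[[`, "frame_index"))
  expect_error(select_window(tr, window_spec("last_n_frames", 1000)),
               "exceeds")
  no_time <- oligo_trajectory(list(tiny_frame(spec)))
  expect_error(select_window(no_time, window_spec("last_t_ns", 10)),
               "time_ns")
})
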