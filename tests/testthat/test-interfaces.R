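# Contact detection, interface classification, occupancy, bonds.

test_that("contact detection: empty, single-pair and boundary cases", {
  far <- tiny_frame(list(A = list("1" = matrix(0, 1, 3)),
                         B = list("1" = matrix(c(50, 0, 0), 1))))
  ct <- find_contact_residues(far, "A", "B")
  expect_length(ct$residues_a, 0)
  expect_length(ct$residues_b, 0)
  # exactly one cross pair at 5.9 A, everything else remote
  f <- tiny_frame(list(
    A = list("1" = matrix(c(0, 0, 0), 1), "2" = matrix(c(0, 0, 30), 1),
             "3" = matrix(c(0, 30, 0), 1)),
    B = list("7" = matrix(c(5.9, 0, 0), 1), "8" = matrix(c(40, 0, 0), 1),
             "9" = matrix(c(0, -30, 0), 1))))
  ct <- find_contact_residues(f, "A", "B")
  expect_identical(ct, oracle_contacts(f, "A", "B"))
  expect_equal(ct$residues_a, 1L)
  expect_equal(ct$residues_b, 7L)
  # inclusive boundary at exactly 6.0 A
  fb <- tiny_frame(list(A = list("1" = matrix(0, 1, 3)),
                        B = list("2" = matrix(c(6, 0, 0), 1))))
  ctb <- find_contact_residues(fb, "A", "B")
  expect_equal(ctb$residues_a, 1L)
  expect_error(find_contact_residues(fb, "A", "Z"), "Z")
})

test_that("contact detection equals the brute-force oracle on random assemblies", {
  for (seed in 1:40) {
    f <- random_assembly(seed)
    got <- find_contact_residues(f, "A", "B")
    want <- oracle_contacts(f, "A", "B")
    expect_identical(got, want)
    # symmetry: contacts(b, a) mirrors contacts(a, b)
    swapped <- find_contact_residues(f, "B", "A")
    expect_identical(swapped$residues_a, got$residues_b)
    expect_identical(swapped$residues_b, got$residues_a)
  }
})

test_that("counting operators ignore particle order within residues", {
  f <- random_assembly(123)
  ct0 <- find_contact_residues(f, "A", "B")
  perm <- f
  set.seed(5)
  perm$atoms <- perm$atoms[sample(nrow(perm$atoms)), ]
  expect_identical(find_contact_residues(perm, "A", "B"), ct0)
})

test_that("interface classification follows the domain-majority rules", {
  map <- default_domain_map()
  # cross-rung pair with only G-domain contacts -> GG
  topo <- structure(list(rung_of = c(A = 0L, B = 1L)),
                    class = "assembly_topology")
  ctg <- list(residues_a = c(40L, 41L, 200L), residues_b = c(180L, 181L))
  expect_equal(classify_interface(NULL, c("A", "B"), topo, map, ctg), "GG")
  # canonical central-stalk (alpha-S2..S4) residues -> IF2
  ct2 <- list(residues_a = c(474L, 478L, 482L, 487L, 489L),
              residues_b = c(678L, 661L))
  expect_equal(classify_interface(NULL, c("A", "B"), NULL, map, ct2), "IF2")
  # stalk-vs-BSE contacts around 330 and the BSE hinge -> IF1
  ct1 <- list(residues_a = c(328L, 330L, 332L), residues_b = c(704L, 706L, 744L))
  expect_equal(classify_interface(NULL, c("A", "B"), NULL, map, ct1), "IF1")
  # L1N-S loop dominated stalk-stalk contact -> IF3
  ct3 <- list(residues_a = c(391L, 393L, 395L), residues_b = c(396L, 398L))
  expect_equal(classify_interface(NULL, c("A", "B"), NULL, map, ct3), "IF3")
  # mixed bag -> unclassified; empty -> error
  ctu <- list(residues_a = c(520L, 530L), residues_b = c(540L, 550L))
  expect_equal(classify_interface(NULL, c("A", "B"), NULL, map, ctu),
               "unclassified")
  expect_error(classify_interface(NULL, c("A", "B"), NULL, map,
                                  list(residues_a = integer(),
                                       residues_b = integer())),
               "classification")
})

test_that("interface area: empty is zero, toy case equals per-residue SASA sums", {
  f <- tiny_frame(list(A = list("470" = matrix(c(0, 0, 0), 1)),
                       B = list("662" = matrix(c(5, 0, 0), 1))))
  empty <- dynhelix:::interface_instance(c("A", "B"), "IF2",
                                         integer(), integer())
  expect_equal(interface_area(f, empty), 0)
  inst <- dynhelix:::interface_instance(c("A", "B"), "IF2", 470L, 662L)
  cfg <- sasa_config()
  want <- residue_sasa(f, "A", 470, cfg)$sasa_A2 +
    residue_sasa(f, "B", 662, cfg)$sasa_A2
  expect_equal(interface_area(f, inst, cfg), want)
  expect_gte(interface_area(f, inst, cfg, mode = "buried"), 0)
})

test_that("occupancy reproduces hand-computed fractions exactly", {
  mk <- function(res_a, frame)
    dynhelix:::interface_instance(c("A", "B"), "IF2", res_a, 700L,
                                  frame_index = frame)
  # 4 instances x 3 frames; residue 474 present in 9 of 12 observations,
  # residue 999 never, residue 700 always (side b)
  insts <- list()
  k <- 0
  for (fr in 0:2) {
    for (i in 1:4) {
      k <- k + 1
      insts[[k]] <- mk(if (k <= 9) c(474L, 478L) else 478L, fr)
    }
  }
  occ <- occupancy(insts)
  expect_true(all(occ$fraction >= 0 & occ$fraction <= 1))
  expect_equal(occ$fraction[occ$residue_number == 474], 9 / 12)
  expect_equal(occ$fraction[occ$residue_number == 700], 1.0)
  expect_equal(occ$count[occ$residue_number == 474], 9L)
  expect_false(999 %in% occ$residue_number)
  expect_warning(out <- occupancy(list()), "no interface")
  expect_equal(nrow(out), 0L)
})

hb_fixture <- function(angle_deg, dist = 2.9) {
  # Ser OG donor on A (antecedent CB), backbone O acceptor on B, with the
  # acceptor placed at the requested antecedent-donor-acceptor angle.
  # Angle at the donor between OG->CB = (-1, 0, 0) and OG->acceptor must be
  # angle_deg, so the acceptor sits at dist * (-cos(th), sin(th), 0).
  th <- angle_deg * pi / 180
  og <- c(0, 0, 0); cb <- c(-1.4, 0, 0)
  acc <- dist * c(-cos(th), sin(th), 0)
  at <- rbind(
    data.frame(serial = 1L, atom_name = "CB", residue_name = "SER",
               residue_number = 10L, monomer_id = "A", x = cb[1], y = cb[2],
               z = cb[3], mass = 12.011, radius = NA_real_, element = "C"),
    data.frame(serial = 2L, atom_name = "OG", residue_name = "SER",
               residue_number = 10L, monomer_id = "A", x = og[1], y = og[2],
               z = og[3], mass = 15.999, radius = NA_real_, element = "O"),
    data.frame(serial = 3L, atom_name = "O", residue_name = "ALA",
               residue_number = 20L, monomer_id = "B", x = acc[1],
               y = acc[2], z = acc[3], mass = 15.999, radius = NA_real_,
               element = "O"))
  oligomer_frame(at, resolution = "full_atom")
}

test_that("hydrogen bonds respect distance and angle criteria", {
  f165 <- hb_fixture(165)
  expect_equal(count_hbonds(f165, c("A", "B")), 1L)
  f90 <- hb_fixture(90)
  expect_equal(count_hbonds(f90, c("A", "B")), 0L)
  ffar <- hb_fixture(165, dist = 12)
  expect_equal(count_hbonds(ffar, c("A", "B")), 0L)
  cg <- build_helix(n_monomers = 8, monomers_per_turn = 4)$frames[[1]]
  expect_error(count_hbonds(cg, c("M01", "M02")), "full-atom")
})

sb_fixture <- function(dist, both_nh = FALSE) {
  rows <- list(
    data.frame(serial = 1L, atom_name = if (both_nh) "NH1" else "NZ",
               residue_name = if (both_nh) "ARG" else "LYS",
               residue_number = 10L, monomer_id = "A", x = 0, y = 0, z = 0,
               mass = 14.007, radius = NA_real_, element = "N"),
    data.frame(serial = 3L, atom_name = "OE1", residue_name = "GLU",
               residue_number = 20L, monomer_id = "B", x = dist, y = 0,
               z = 0, mass = 15.999, radius = NA_real_, element = "O"))
  if (both_nh) {
    rows[[3]] <- data.frame(serial = 2L, atom_name = "NH2",
                            residue_name = "ARG", residue_number = 10L,
                            monomer_id = "A", x = 0.5, y = 1, z = 0,
                            mass = 14.007, radius = NA_real_, element = "N")
    rows[[4]] <- data.frame(serial = 4L, atom_name = "OE2",
                            residue_name = "GLU", residue_number = 20L,
                            monomer_id = "B", x = dist, y = 1, z = 0,
                            mass = 15.999, radius = NA_real_, element = "O")
  }
  oligomer_frame(do.call(rbind, rows), resolution = "full_atom")
}

test_that("salt bridges: distance cutoff and residue-pair collapse", {
  expect_equal(count_salt_bridges(sb_fixture(3.5), c("A", "B")), 1L)
  expect_equal(count_salt_bridges(sb_fixture(8), c("A", "B")), 0L)
  # Arg with both NH1/NH2 in range of one Glu still counts once
  expect_equal(count_salt_bridges(sb_fixture(3.0, both_nh = TRUE),
                                  c("A", "B")), 1L)
  cg <- build_helix(n_monomers = 8, monomers_per_turn = 4)$frames[[1]]
  expect_error(count_salt_bridges(cg, c("M01", "M02")), "full-atom")
})

test_that("residue-465/BSE interaction recovers the genotype-specific sets", {
  h <- build_helix()
  topo <- assign_topology(h$frames[[1]])
  r <- residue465_bse_interaction(h$frames[[1]], topo, measure_area = FALSE)
  expect_equal(r[["M01"]]$residues_b, c(294L, 744L, 745L))
  hm <- build_helix(genotype_pattern = "all_mutant")
  tm <- assign_topology(hm$frames[[1]])
  rm <- residue465_bse_interaction(hm$frames[[1]], tm, measure_area = FALSE)
  expect_equal(rm[["M01"]]$residues_b, c(294L, 298L, 742L, 744L, 745L))
  # mutant interaction area exceeds the WT one (more residues recruited)
  a_wt <- interface_area(h$frames[[1]], r[["M01"]])
  a_mut <- interface_area(hm$frames[[1]], rm[["M01"]])
  expect_gt(a_mut, a_wt)
  # rung-end monomer without a facing neighbor: empty instance, zero area
  expect_length(r[["M14"]]$residues_b, 0L)
  expect_equal(r[["M14"]]$area_A2, 0)
})

test_that("intramonomer contacts: exclusion rule and the 465 neighborhood", {
  # minimal fixture: only the four interaction partners are within range
  spec <- list(A = list(
    "465" = matrix(c(0, 0, 0), 1),
    "429" = matrix(c(4, 0, 0), 1), "433" = matrix(c(0, 4, 0), 1),
    "466" = matrix(c(0, 0, 4), 1), "468" = matrix(c(-4, 0, 0), 1),
    "500" = matrix(c(30, 0, 0), 1)))
  f <- tiny_frame(spec, resolution = "full_atom")
  expect_equal(intramonomer_contacts(f, "A", 465, exclude_bonded = 0L),
               c(429L, 433L, 466L, 468L))
  # the +-1 exclusion removes 466
  expect_equal(intramonomer_contacts(f, "A", 465, exclude_bonded = 1L),
               c(429L, 433L, 468L))
  # only a sequence neighbor nearby -> empty under the default rule
  spec2 <- list(A = list("465" = matrix(c(0, 0, 0), 1),
                         "466" = matrix(c(2, 0, 0), 1),
                         "600" = matrix(c(50, 0, 0), 1)))
  expect_equal(intramonomer_contacts(tiny_frame(spec2), "A", 465), integer())
  # isolated residue -> empty
  spec3 <- list(A = list("465" = matrix(c(0, 0, 0), 1),
                         "700" = matrix(c(90, 0, 0), 1)))
  expect_equal(intramonomer_contacts(tiny_frame(spec3), "A", 465), integer())
  expect_error(intramonomer_contacts(tiny_frame(spec3), "A", 9), "not found")
})

test_that("dimer WT monomer keeps the R465 local interaction network", {
  d <- build_dimer("WT", "R465W")
  ct_wt <- intramonomer_contacts(d, "A", 465, exclude_bonded = 0L)
  expect_true(all(c(429L, 433L, 466L, 468L) %in% ct_wt))
  # the mutant's exposed W465 loses the 429/433 contacts
  ct_mut <- intramonomer_contacts(d, "B", 465, exclude_bonded = 0L)
  expect_false(any(c(429L, 433L) %in% ct_mut))
})
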