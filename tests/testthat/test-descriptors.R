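cfg_fast <- descriptor_config(sasa_points = 60)

test_that("formal charge sums partial charges and rounds to the formal value", {
  fr <- mk_complex_frame(matrix(0, 1, 3), matrix(c(0, 0, 4), 1, 3),
                         lig_args = list(charge = -0.5))
  fr$atoms$charge[fr$atoms$role == "LIGAND"] <- c(-0.5)
  fr2 <- mk_complex_frame(matrix(0, 1, 3), matrix(c(0, 0, 4, 0, 0, 6),
                                                  2, 3, byrow = TRUE),
                          lig_args = list(charge = -0.5))
  q <- formal_charge(fr2, "LIGAND")
  expect_equal(as.numeric(q), -1.0)
  expect_identical(attr(q, "formal"), -1L)
  expect_equal(as.numeric(formal_charge(fr2, "RECEPTOR")), 0)
})

test_that("residue neighbourhood uses the minimum atom-atom distance criterion", {
  # single receptor residue: nearest atom at 4.9 then 5.1 Angstrom
  for (d in c(4.9, 5.1)) {
    fr <- mk_complex_frame(matrix(c(0, 0, d, 0, 0, d + 3), 2, 3, byrow = TRUE),
                           matrix(0, 1, 3),
                           rec_args = list(residue_id = c(1, 1)))
    got <- residues_near_ligand(fr, 5)
    if (d < 5) expect_equal(got, 1) else expect_equal(got, integer(0))
  }
})

test_that("charged and polarity counts follow the residue class lists", {
  rec <- rbind(c(0, 0, 1), c(0, 0, 2), c(0, 0, 3), c(0, 0, 50))
  fr <- mk_complex_frame(rec, matrix(0, 1, 3),
                         rec_args = list(residue_name = c("LYS", "LYS",
                                                          "ASP", "ARG"),
                                         residue_id = 1:4))
  cc <- charged_counts(fr, 5)
  expect_equal(unname(cc), c(2, 1, 1))
  # HIE counts as positive; GLY in neither polarity class
  fr2 <- mk_complex_frame(rbind(c(0, 0, 1), c(0, 0, 2)), matrix(0, 1, 3),
                          rec_args = list(residue_name = c("HIE", "GLY"),
                                          residue_id = 1:2))
  expect_equal(unname(charged_counts(fr2, 5)), c(1, 0, 1))
  pc <- polarity_counts(fr2, 5)
  expect_equal(unname(pc), c(0, 1, 1))   # HIE hydrophilic, GLY unclassified
  # 3 hydrophilic + 1 hydrophobic
  fr3 <- mk_complex_frame(rbind(c(0, 0, 1), c(0, 0, 2), c(0, 0, 3),
                                c(0, 0, 4)), matrix(0, 1, 3),
                          rec_args = list(residue_name = c("SER", "THR",
                                                           "GLN", "LEU"),
                                          residue_id = 1:4))
  expect_equal(unname(polarity_counts(fr3, 5)), c(1, 3, 2))
})

test_that("ligand geometry descriptors match closed forms", {
  # 3-4-5 triangle end-to-end
  fr <- mk_complex_frame(matrix(0, 1, 3),
                         rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(end_to_end_distance(fr), 5.0)
  # coincident anchors
  fr0 <- mk_complex_frame(matrix(0, 1, 3), rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(end_to_end_distance(fr0), 0.0)
  fr1 <- mk_complex_frame(matrix(0, 1, 3), matrix(1, 1, 3))
  expect_error(end_to_end_distance(fr1), "2 atoms")

  # symmetric dumbbell and unit square radius of gyration
  db <- mk_complex_frame(matrix(0, 1, 3), rbind(c(-1, 0, 0), c(1, 0, 0)),
                         lig_args = list(mass = 1))
  expect_equal(radius_of_gyration(db), 1.0)
  sq <- mk_complex_frame(matrix(0, 1, 3),
                         rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                               c(1, 1, 0)), lig_args = list(mass = 1))
  expect_equal(radius_of_gyration(sq), sqrt(0.5), tolerance = 1e-12)

  # center-of-mass distance
  cd <- mk_complex_frame(rbind(c(-1, 0, 0), c(1, 0, 0)),
                         rbind(c(-1, 0, 10), c(1, 0, 10)))
  expect_equal(com_distance(cd), 10.0)
  same <- mk_complex_frame(rbind(c(-1, 0, 0), c(1, 0, 0)),
                           rbind(c(-1, 0, 0), c(1, 0, 0)))
  expect_equal(com_distance(same), 0.0)
})

test_that("orientation angle folds to [0, 90] and flags degenerate geometry", {
  rod_x <- rbind(c(-2, 0, 0), c(0, 0, 0), c(2, 0, 0))
  rod_y <- rbind(c(0, -2, 0), c(0, 0, 0), c(0, 2, 0))
  expect_equal(orientation_angle(mk_complex_frame(rod_x, rod_y)), 90)
  expect_equal(orientation_angle(mk_complex_frame(rod_x, rod_x + 5)), 0)
  # antiparallel rod folds to 0
  expect_equal(orientation_angle(mk_complex_frame(rod_x, -rod_x + 5)), 0)
  # coincident ligand atoms: undefined
  pt <- matrix(1, 3, 3)
  expect_true(is.na(orientation_angle(mk_complex_frame(rod_x, pt))))
})

test_that("contacts count heavy-atom pairs within the cutoff", {
  rec <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0))
  lig <- matrix(c(0, 0, 3), 1, 3)
  fr <- mk_complex_frame(rec, lig)
  expect_equal(count_contacts(fr, 3.5), 1L)   # distances 3.00, 4.24, 6.71
  expect_equal(count_contacts(fr, 5.0), 2L)
  far <- mk_complex_frame(rec, matrix(50, 1, 3))
  expect_equal(count_contacts(far, 3.5), 0L)
  expect_equal(count_contacts(far, 5.0), 0L)
  # hydrogens excluded on either side
  frh <- mk_complex_frame(rec, lig, lig_args = list(element = "H"))
  expect_equal(count_contacts(frh, 5.0), 0L)
})

test_that("hydrogen bonds need donor H, distance and angle", {
  rec <- matrix(c(2.8, 0, 0), 1, 3)
  lig <- rbind(c(0, 0, 0), c(1, 0, 0))
  fr <- mk_complex_frame(rec, lig,
                         rec_args = list(element = "O"),
                         lig_args = list(element = c("O", "H")))
  expect_equal(count_hbonds(fr, ligand_is_donor = TRUE), 1L)
  expect_equal(suppressWarnings(count_hbonds(fr, ligand_is_donor = FALSE)), 0L)

  # donor-H-acceptor angle 90 degrees fails even at short distance
  fr90 <- mk_complex_frame(matrix(c(1, 1.8, 0), 1, 3), lig,
                           rec_args = list(element = "O"),
                           lig_args = list(element = c("O", "H")))
  expect_equal(count_hbonds(fr90, TRUE), 0L)

  # distance 3.6 fails the 3.5 cutoff at perfect angle
  fr36 <- mk_complex_frame(matrix(c(3.6, 0, 0), 1, 3), lig,
                           rec_args = list(element = "O"),
                           lig_args = list(element = c("O", "H")))
  expect_equal(count_hbonds(fr36, TRUE), 0L)

  # no hydrogens on the donor side: 0 with a warning
  noh <- mk_complex_frame(rec, matrix(0, 1, 3),
                          rec_args = list(element = "O"),
                          lig_args = list(element = "O"))
  expect_warning(n <- count_hbonds(noh, TRUE), "no hydrogens")
  expect_equal(n, 0L)
})

test_that("neighbourhoods and contacts are monotone in the radius", {
  gen <- gen_toy_complex(toy_complex_spec(com_offset = 1, seed = 2), cfg_fast)
  fr <- get_frame(gen$trajectory, 1)
  radii <- c(2, 3.5, 5, 8, 10)
  near <- lapply(radii, function(r) residues_near_ligand(fr, r))
  for (i in seq_len(length(radii) - 1))
    expect_true(all(near[[i]] %in% near[[i + 1]]))
  counts <- vapply(radii, function(r) count_contacts(fr, r), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("with default cutoffs every hydrogen bond implies a short contact", {
  for (seed in 1:6) {
    gen <- gen_toy_complex(varied_toy_spec(seed), cfg_fast)
    fr <- get_frame(gen$trajectory, 1)
    hb <- suppressWarnings(count_hbonds(fr, TRUE) + count_hbonds(fr, FALSE))
    expect_lte(hb, count_contacts(fr, 3.5))
  }
})

test_that("descriptors are invariant under rigid-body motion and deterministic", {
  cfg <- descriptor_config(sasa_points = 240)
  gen <- gen_toy_complex(toy_complex_spec(com_offset = 1, seed = 5), cfg)
  fr <- get_frame(gen$trajectory, 1)
  d1 <- compute_descriptors(fr, cfg)
  d2 <- compute_descriptors(fr, cfg)
  expect_identical(d1, d2)

  sasa <- c("sasa_prot", "sasa_gag", "sasa_complex")
  # translation is exact for every descriptor, including the surface areas
  fr_tr <- fr
  fr_tr$coords <- fr$coords + rep(c(12, -7, 3), each = nrow(fr$coords))
  expect_equal(unclass(compute_descriptors(fr_tr, cfg)), unclass(d1),
               tolerance = 1e-10)

  # rotation: exact for all descriptors except SASA, whose fixed point
  # lattice is only rotation invariant in the converged limit
  R <- random_rotation(3)
  fr_rot <- fr
  fr_rot$coords <- fr$coords %*% t(R) + rep(c(2, 5, -1), each = nrow(fr$coords))
  d3 <- compute_descriptors(fr_rot, cfg)
  other <- setdiff(CANONICAL_FEATURES, sasa)
  expect_equal(unname(d3[other]), unname(d1[other]), tolerance = 1e-8)
  expect_equal(unname(d3[sasa]), unname(d1[sasa]), tolerance = 0.02)
})

test_that("a dissociated ligand yields an empty interface", {
  gen <- gen_toy_complex(toy_complex_spec(com_offset = 100, seed = 1),
                         cfg_fast)
  d <- compute_descriptors(get_frame(gen$trajectory, 1), cfg_fast)
  expect_equal(unname(d[c("n_pos_5A", "n_neg_5A", "n_phobic_10A",
                          "n_philic_10A", "n_contacts_short",
                          "n_contacts_medium", "n_hbonds_gag_donor",
                          "n_hbonds_gag_acceptor")]), rep(0, 8))
  expect_equal(unname(d["lie_elec"]), 0)
})

test_that("feature tables carry metadata, features and optional target", {
  gen <- gen_toy_complex(toy_complex_spec(n_frames = 3, seed = 6), cfg_fast)
  tab <- compute_feature_table(gen$trajectory, cfg_fast, target = c(-10, -11, -9))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$frame_index, 0:2)
  expect_true(all(CANONICAL_FEATURES %in% names(tab)))
  expect_equal(tab$mmgbsa_kcal_mol, c(-10, -11, -9))
  expect_equal(feature_names(tab), CANONICAL_FEATURES)
})
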