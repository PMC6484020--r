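test_that("superposition recovers exact rigid motions", {
  set.seed(1)
  cloud <- matrix(rnorm(30), 10, 3)
  tf <- superpose(cloud, cloud)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tf$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(tf$rmsd, 1e-12)

  rot90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  moved <- cloud %*% t(rot90) + matrix(c(1, 0, 0), 10, 3, byrow = TRUE)
  tf <- superpose(moved, cloud)
  expect_lt(tf$rmsd, 1e-10)
  expect_equal(tf$rotation %*% rot90, diag(3), tolerance = 1e-10)
})

test_that("superposition inverts random rigid motions over 100 trials", {
  set.seed(7)
  for (i in 1:100) {
    cloud <- matrix(rnorm(30), 10, 3)
    r <- random_rotation()
    t <- rnorm(3)
    moved <- cloud %*% t(r) + matrix(t, 10, 3, byrow = TRUE)
    tf <- superpose(moved, cloud)
    expect_lt(tf$rmsd, 1e-9)
    expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
  }
})

test_that("degenerate superposition input is rejected", {
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), ">= 3")
  line <- cbind(1:5, 0, 0)  # collinear
  expect_error(superpose(line, line), "degenerate")
})

test_that("region RMSD is zero on the reference and exact on translations", {
  ref <- build_reference_complex()
  frames <- list(ref$coords, ref$coords)
  ens <- trajectory_ensemble(
    annotated_structure(ref$atoms, ref$coords, regions = ref$regions),
    frames)
  rs <- region_rmsd(ens, ref, "enzyme", "srm_helix")
  expect_equal(rs$values, c(0, 0), tolerance = 1e-12)

  # displace the measured region only: RMSD equals the displacement
  helix <- region_atoms(ref, "srm_helix", "all")
  co <- ref$coords
  co[helix, 1] <- co[helix, 1] + 0.1
  ens <- trajectory_ensemble(ens$topology, list(co))
  # fit on the reader chain, untouched by the displacement
  rs <- region_rmsd(ens, ref, "reader", "srm_helix")
  expect_equal(rs$values, 0.1, tolerance = 1e-9)
})

test_that("region RMSD matches an independent superposition oracle", {
  ref <- build_reference_complex()
  sc <- mutant_like_scenario(n_frames = 20, seed = 3, helix_unfold_prob = 0.5)
  ens <- simulate_trajectory(sc, ref)
  rs <- region_rmsd(ens, ref, "enzyme", "srm_helix", atom_filter = "CA")
  fit_idx <- region_atoms(ref, "enzyme", "CA")
  mea_idx <- region_atoms(ref, "srm_helix", "CA")
  oracle <- bio3d_region_rmsd(ens, ref, fit_idx, mea_idx)
  expect_equal(rs$values, oracle, tolerance = 1e-9)
})

test_that("minimum group distance equals the exhaustive oracle", {
  f <- rbind(c(0, 0, 0), c(0, 0, 0.3))
  expect_equal(min_residue_distance(f, 1, 2), 0.3)

  set.seed(11)
  for (i in 1:100) {
    frame <- matrix(rnorm(18), 6, 3)
    expect_equal(min_residue_distance(frame, 1:3, 4:6),
                 brute_min_dist(frame, 1:3, 4:6), tolerance = 1e-9)
  }
  # adding a distant atom leaves the minimum unchanged
  frame <- matrix(rnorm(18), 6, 3)
  frame2 <- rbind(frame, c(100, 100, 100))
  expect_equal(min_residue_distance(frame2, 1:3, c(4:6, 7)),
               min_residue_distance(frame, 1:3, 4:6))
  expect_error(min_residue_distance(frame, 1:3, 3:5), "overlap")
})

test_that("RMSD and minimum distance are invariant under common rigid motion", {
  set.seed(5)
  ref <- build_reference_complex()
  sc <- mutant_like_scenario(n_frames = 5, seed = 9)
  ens <- simulate_trajectory(sc, ref)
  rs0 <- region_rmsd(ens, ref, "enzyme", "srm_helix")
  d0 <- min_residue_distance(ens$frames[[1]], 1:10, 21:30)
  r <- random_rotation()
  t <- rnorm(3)
  ens$frames <- lapply(ens$frames, function(f) {
    f %*% t(r) + matrix(t, nrow(f), 3, byrow = TRUE)
  })
  rs1 <- region_rmsd(ens, ref, "enzyme", "srm_helix")
  expect_equal(rs1$values, rs0$values, tolerance = 1e-9)
  d1 <- min_residue_distance(ens$frames[[1]], 1:10, 21:30)
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("unbound-frame filter removes strictly above the threshold", {
  ref <- build_reference_complex()
  ens <- ligand_displacement_ensemble(ref, c(0.7, 0.8, 0.9))
  flt <- filter_unbound_frames(ens, ref, threshold_nm = 0.8)
  expect_equal(flt$mask$kept, c(TRUE, TRUE, FALSE))  # 0.8 itself is kept
  expect_equal(flt$mask$ligand_rmsd_nm, c(0.7, 0.8, 0.9), tolerance = 1e-9)
  expect_equal(n_frames(flt$ensemble), 2)
  expect_equal(flt$ensemble$times, c(0, 1))

  # idempotence: filtering a filtered ensemble removes nothing
  flt2 <- filter_unbound_frames(flt$ensemble, ref, threshold_nm = 0.8)
  expect_true(all(flt2$mask$kept))

  # all frames removed: warning plus empty result
  ens_far <- ligand_displacement_ensemble(ref, c(2, 3))
  expect_warning(flt3 <- filter_unbound_frames(ens_far, ref), "all frames")
  expect_null(flt3$ensemble)
  expect_error(contact_map(flt3$ensemble, "E", "L"), "empty input")
})

test_that("filter recovers generator ground truth", {
  ref <- build_reference_complex()
  sc <- trajectory_scenario(n_frames = 1000, seed = 21, bound_fraction = 0.8,
                            helix_unfold_prob = 0.1)
  ens <- simulate_trajectory(sc, ref)
  flt <- filter_unbound_frames(ens, ref)
  kept_frac <- mean(flt$mask$kept)
  expect_gte(kept_frac, 0.75)
  expect_lte(kept_frac, 0.85)
  # frames generated unbound (displacement 2.0 nm >= 1.5) are all removed
  expect_true(all(!flt$mask$kept[!ens$truth$bound]))
  expect_true(all(flt$mask$kept == ens$truth$bound))
})

test_that("contact map averages per-frame minimum distances", {
  ref <- build_reference_complex()
  topo <- annotated_structure(ref$atoms, ref$coords, regions = ref$regions)
  ens1 <- trajectory_ensemble(topo, list(ref$coords))
  cm1 <- contact_map(ens1, "E", "L", residues_a = c(136, 142))
  # single frame: entries equal direct per-frame minima
  lig <- region_atoms(ref, "ligand", "heavy")
  for (i in seq_along(cm1$rows)) {
    res <- 135 + i
    ra <- select_atoms(ref, "E", c(res, res), "heavy")
    expect_equal(cm1$values[i, 1], brute_min_dist(ref$coords, ra, lig),
                 tolerance = 1e-9)
  }
  # two frames: arithmetic mean of the per-frame entries
  co2 <- ref$coords
  lig_all <- region_atoms(ref, "ligand", "all")
  co2[lig_all, 2] <- co2[lig_all, 2] + 0.2
  ens2 <- trajectory_ensemble(topo, list(ref$coords, co2))
  cm2 <- contact_map(ens2, "E", "L", residues_a = c(136, 142))
  cm_b <- contact_map(trajectory_ensemble(topo, list(co2)), "E", "L",
                      residues_a = c(136, 142))
  expect_equal(cm2$values, (cm1$values + cm_b$values) / 2, tolerance = 1e-12)
  expect_equal(cm2$n_frames_used, 2)
})

test_that("contact map entries shrink as the atom filter is relaxed", {
  ref <- build_reference_complex()
  sc <- mutant_like_scenario(n_frames = 10, seed = 13)
  ens <- simulate_trajectory(sc, ref)
  flt <- filter_unbound_frames(ens, ref)
  rng <- c(143, 153)  # residues with side chains (the loop glycine has none)
  cm_sc <- contact_map(flt$ensemble, "E", "L", residues_a = rng,
                       atom_filter = "side_chain")
  cm_h <- contact_map(flt$ensemble, "E", "L", residues_a = rng,
                      atom_filter = "heavy")
  cm_a <- contact_map(flt$ensemble, "E", "L", residues_a = rng,
                      atom_filter = "all")
  expect_true(all(cm_h$values <= cm_sc$values + 1e-12))
  expect_true(all(cm_a$values <= cm_h$values + 1e-12))
})

test_that("the engineered persistent salt bridge is the contact-map argmin", {
  ref <- build_reference_complex()
  sc <- mutant_like_scenario(n_frames = 200, seed = 17)
  ens <- simulate_trajectory(sc, ref)
  flt <- filter_unbound_frames(ens, ref)
  cm <- contact_map(flt$ensemble, "E", "L")
  amin <- arrayInd(which.min(cm$values), dim(cm$values))
  expect_match(cm$rows[amin[1]], "ASP140")
})
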