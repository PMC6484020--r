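# Fixture builders shared across the suite. Everything is generated in
# code; no files ship with the tests.

# random single-chain structure with unique atom identities
random_structure <- function(n_atoms = 50, seed = 1) {
  set.seed(seed)
  atoms <- data.frame(
    atom_name = "CA",
    element = "C",
    chain_id = "A",
    residue_number = seq_len(n_atoms),
    residue_name = "ALA",
    stringsAsFactors = FALSE
  )
  coords <- matrix(runif(n_atoms * 3, -2, 2), n_atoms, 3)
  annotated_structure(atoms, coords)
}

# random proper rotation (det = +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# minimal two-group structure: n_a + n_b single-atom residues on two chains
two_group_frame <- function(coords_a, coords_b) {
  n_a <- nrow(coords_a)
  n_b <- nrow(coords_b)
  atoms <- data.frame(
    atom_name = "X",
    element = "C",
    chain_id = rep(c("A", "B"), c(n_a, n_b)),
    residue_number = c(seq_len(n_a), seq_len(n_b)),
    residue_name = "UNK",
    stringsAsFactors = FALSE
  )
  annotated_structure(atoms, rbind(coords_a, coords_b))
}

# ensemble whose frames displace the whole ligand chain by given distances
# along +y; ligand RMSD then equals the displacement exactly
ligand_displacement_ensemble <- function(reference, displacements) {
  lig <- region_atoms(reference, "ligand", "all")
  frames <- lapply(displacements, function(d) {
    co <- reference$coords
    co[lig, 2] <- co[lig, 2] + d
    co
  })
  ens <- trajectory_ensemble(
    annotated_structure(reference$atoms, reference$coords,
                        regions = reference$regions),
    frames, times = seq_along(displacements) - 1
  )
  ens
}

# brute-force minimum cross-pair distance
brute_min_dist <- function(frame, ia, ib) {
  best <- Inf
  for (i in ia) for (j in ib) {
    best <- min(best, sqrt(sum((frame[i, ] - frame[j, ])^2)))
  }
  best
}

# independent per-frame region RMSD via bio3d's superposition
bio3d_region_rmsd <- function(ensemble, reference, fit_idx, mea_idx) {
  ref_xyz <- as.vector(t(reference$coords))
  vapply(ensemble$frames, function(f) {
    mob_xyz <- as.vector(t(f))
    fitted <- bio3d::fit.xyz(fixed = ref_xyz, mobile = mob_xyz,
                             fixed.inds = bio3d::atom2xyz(fit_idx),
                             mobile.inds = bio3d::atom2xyz(fit_idx))
    sqrt(mean((matrix(fitted, ncol = 3, byrow = TRUE)[mea_idx, ] -
                 reference$coords[mea_idx, ])^2) * 3)
  }, numeric(1))
}
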