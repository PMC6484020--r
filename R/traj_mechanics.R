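# Per-frame geometric metrics: Kabsch superposition, region RMSD, minimum
# inter-residue distances, contact maps, and the unbound-ligand frame
# filter. No periodic-boundary imaging is applied: inputs are assumed
# whole/imaged.

#' Least-squares rigid superposition (Kabsch)
#'
#' Computes the proper rotation (det = +1) and translation minimising the
#' coordinate RMSD between a mobile point set and a matched reference.
#'
#' @param mobile n x 3 coordinate matrix (nm).
#' @param reference matched n x 3 coordinate matrix (nm).
#' @return A list with `rotation` (3 x 3), `translation` (length 3) such
#'   that `coords %*% t(rotation) + translation` maps mobile onto the
#'   reference frame, and `rmsd` of the fit atoms after superposition.
#' @export
superpose <- function(mobile, reference) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3, ncol(reference) == 3)
  n <- nrow(mobile)
  if (nrow(reference) != n) stop("superposition error: atom count mismatch")
  if (n < 3L) stop("superposition error: need >= 3 atom pairs")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  p <- sweep(mobile, 2, cm)
  q <- sweep(reference, 2, cr)
  # collinear (rank < 2) point sets leave the rotation undetermined
  sv <- svd(p)$d
  if (sv[2] < 1e-8 * max(sv[1], 1e-12)) {
    stop("superposition error: degenerate (collinear) geometry")
  }
  h <- crossprod(p, q)              # 3x3 covariance
  dec <- svd(h)
  d <- sign(det(dec$v %*% t(dec$u)))
  r <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  translation <- as.numeric(cr - r %*% cm)
  fitted <- mobile %*% t(r) + matrix(translation, n, 3, byrow = TRUE)
  list(rotation = r, translation = translation,
       rmsd = rmsd_coords(fitted, reference))
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix.
#' @param transform result of [superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  coords %*% t(transform$rotation) +
    matrix(transform$translation, nrow(coords), 3, byrow = TRUE)
}

#' RMSD between two matched coordinate sets (no fitting)
#'
#' @param a,b matched n x 3 matrices (nm).
#' @return RMSD in nm.
#' @export
rmsd_coords <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

#' Per-frame region RMSD against a reference structure
#'
#' For each frame the ensemble is superposed on the `fit_role` atoms of the
#' reference, then the RMSD of the `measure_role` atoms is taken without
#' refitting — the displacement of the measured region is reported in the
#' frame of the fitted region. The default CA-only selection measures
#' backbone geometry (e.g. folding state of the stimulation-responsive
#' helix) independently of side-chain motion.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param reference an `annotated_structure` with matching annotations.
#' @param fit_role region role used for superposition.
#' @param measure_role region role whose RMSD is reported.
#' @param atom_filter atom class for both selections (see [select_atoms()]);
#'   default `"CA"` (alpha carbons).
#' @return An `rmsd_series` object: list with `values` (nm per frame),
#'   `times`, `region_role`, `fit_region_role`.
#' @export
region_rmsd <- function(ensemble, reference, fit_role, measure_role,
                        atom_filter = "CA") {
  fit_idx <- region_atoms(ensemble$topology, fit_role, atom_filter)
  mea_idx <- region_atoms(ensemble$topology, measure_role, atom_filter)
  ref_fit_idx <- region_atoms(reference, fit_role, atom_filter)
  ref_mea_idx <- region_atoms(reference, measure_role, atom_filter)
  if (length(fit_idx) != length(ref_fit_idx) ||
      length(mea_idx) != length(ref_mea_idx)) {
    stop("correspondence error: ensemble and reference select different ",
         "atom counts for roles ", fit_role, "/", measure_role)
  }
  ref_fit <- reference$coords[ref_fit_idx, , drop = FALSE]
  ref_mea <- reference$coords[ref_mea_idx, , drop = FALSE]
  values <- vapply(ensemble$frames, function(f) {
    tf <- superpose(f[fit_idx, , drop = FALSE], ref_fit)
    rmsd_coords(apply_transform(f[mea_idx, , drop = FALSE], tf), ref_mea)
  }, numeric(1))
  structure(
    list(values = values, times = ensemble$times, region_role = measure_role,
         fit_region_role = fit_role),
    class = "rmsd_series"
  )
}

# Per-frame ligand RMSD: superpose each frame on the receptor backbone
# (enzyme + reader N/CA/C/O) of the reference, then measure ligand heavy
# atoms against the reference pose.
.ligand_rmsd_series <- function(ensemble, reference) {
  topo <- ensemble$topology
  for (role in c("ligand", "enzyme", "reader")) {
    if (is.null(topo$regions[[role]]) || is.null(reference$regions[[role]])) {
      stop("role '", role, "' must be annotated in both ensemble and ",
           "reference for the unbound-frame filter")
    }
  }
  fit_idx <- c(region_atoms(topo, "enzyme", .BACKBONE_NAMES),
               region_atoms(topo, "reader", .BACKBONE_NAMES))
  lig_idx <- region_atoms(topo, "ligand", "heavy")
  ref_fit_idx <- c(region_atoms(reference, "enzyme", .BACKBONE_NAMES),
                   region_atoms(reference, "reader", .BACKBONE_NAMES))
  ref_lig_idx <- region_atoms(reference, "ligand", "heavy")
  if (length(fit_idx) != length(ref_fit_idx) ||
      length(lig_idx) != length(ref_lig_idx)) {
    stop("correspondence error between ensemble and reference selections")
  }
  ref_fit <- reference$coords[ref_fit_idx, , drop = FALSE]
  ref_lig <- reference$coords[ref_lig_idx, , drop = FALSE]
  vapply(ensemble$frames, function(f) {
    tf <- superpose(f[fit_idx, , drop = FALSE], ref_fit)
    rmsd_coords(apply_transform(f[lig_idx, , drop = FALSE], tf), ref_lig)
  }, numeric(1))
}

#' Remove frames with an unbound ligand
#'
#' A frame is removed iff the ligand RMSD against its reference pose
#' (after superposing the frame on the receptor backbone) is strictly
#' greater than `threshold_nm`; a frame at exactly the threshold is kept.
#' The default 0.8 nm cutoff is the conventional bound/unbound divide for
#' this system.
#'
#' @param ensemble a `trajectory_ensemble` with `ligand`, `enzyme` and
#'   `reader` regions annotated.
#' @param reference matching `annotated_structure` holding the bound pose.
#' @param threshold_nm removal cutoff in nm (default 0.8).
#' @return A list with `ensemble` (filtered, frame order and times
#'   preserved) and `mask`, a `frame_mask` data.frame with columns
#'   `frame_index`, `kept`, `ligand_rmsd_nm` and attributes `threshold_nm`,
#'   `reference_id`. If every frame is removed the returned ensemble is
#'   `NULL` and a warning is raised; downstream operations reject it.
#' @export
filter_unbound_frames <- function(ensemble, reference, threshold_nm = 0.8) {
  stopifnot(threshold_nm >= 0)
  rmsd <- .ligand_rmsd_series(ensemble, reference)
  # strict ">" removal; the 1e-9 slack keeps a frame sitting numerically on
  # the threshold from being removed by superposition round-off
  kept <- rmsd <= threshold_nm + 1e-9
  mask <- data.frame(frame_index = seq_along(kept), kept = kept,
                     ligand_rmsd_nm = rmsd)
  attr(mask, "threshold_nm") <- threshold_nm
  attr(mask, "reference_id") <- attr(reference, "id") %||% "reference"
  class(mask) <- c("frame_mask", "data.frame")
  if (!any(kept)) {
    warning("all frames removed by the unbound-ligand filter")
    return(list(ensemble = NULL, mask = mask))
  }
  filtered <- trajectory_ensemble(
    ensemble$topology,
    ensemble$frames[kept],
    times = ensemble$times[kept],
    truth = if (!is.null(ensemble$truth)) ensemble$truth[kept, , drop = FALSE]
  )
  list(ensemble = filtered, mask = mask)
}

#' Write a frame mask as CSV
#' @param mask a `frame_mask`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_frame_mask <- function(mask, path) {
  write.csv(as.data.frame(mask)[, c("frame_index", "kept")], path,
            row.names = FALSE)
  invisible(path)
}

#' Minimum distance between two atom groups in one frame
#'
#' @param frame n x 3 coordinate matrix (nm).
#' @param atoms_a,atoms_b disjoint non-empty integer index sets.
#' @return Minimum over all cross pairs of Euclidean distances, nm.
#' @export
min_residue_distance <- function(frame, atoms_a, atoms_b) {
  if (length(atoms_a) == 0L || length(atoms_b) == 0L) {
    stop("selection error: empty atom group")
  }
  if (length(intersect(atoms_a, atoms_b)) > 0L) {
    stop("selection error: atom groups overlap")
  }
  a <- frame[atoms_a, , drop = FALSE]
  b <- frame[atoms_b, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

# Per-frame minimum distance between two fixed atom groups, vectorised
# over frames (frames supplied as a list of n x 3 matrices).
.min_dist_over_frames <- function(frames, atoms_a, atoms_b) {
  na <- length(atoms_a); nb <- length(atoms_b)
  ia <- rep(atoms_a, times = nb)
  ib <- rep(atoms_b, each = na)
  vapply(frames, function(f) {
    d2 <- (f[ia, 1] - f[ib, 1])^2 + (f[ia, 2] - f[ib, 2])^2 +
      (f[ia, 3] - f[ib, 3])^2
    sqrt(min(d2))
  }, numeric(1))
}

#' Inter-chain contact map of frame-averaged minimum residue distances
#'
#' Entry (i, j) is the arithmetic mean over frames of the minimum distance
#' between any atom of residue i (group A) and any atom of residue j
#' (group B), i.e. the "average minimum residue-residue distance". Apply
#' [filter_unbound_frames()] first when a ligand is annotated and only
#' bound frames should contribute.
#'
#' @param ensemble a non-empty `trajectory_ensemble`.
#' @param chain_a,chain_b chain ids of the two groups.
#' @param residues_a,residues_b inclusive residue ranges (`NULL` = whole
#'   chain).
#' @param atom_filter atom class used for distances; default `"heavy"`.
#' @return A `contact_matrix`: list with `rows`, `cols` (residue labels),
#'   `values` (nm matrix) and `n_frames_used`.
#' @export
contact_map <- function(ensemble, chain_a, chain_b, residues_a = NULL,
                        residues_b = NULL, atom_filter = "heavy") {
  if (is.null(ensemble) || n_frames(ensemble) == 0L) {
    stop("empty input: contact_map needs at least one frame")
  }
  at <- ensemble$topology$atoms
  sel_res <- function(chain, residues) {
    r <- sort(unique(at$residue_number[at$chain_id == chain]))
    if (!is.null(residues)) r <- r[r >= residues[1] & r <= residues[2]]
    if (length(r) == 0L) stop("empty selection: chain ", chain)
    r
  }
  res_a <- sel_res(chain_a, residues_a)
  res_b <- sel_res(chain_b, residues_b)
  groups_a <- lapply(res_a, function(r) {
    select_atoms(ensemble$topology, chain_a, c(r, r), atom_filter)
  })
  groups_b <- lapply(res_b, function(r) {
    select_atoms(ensemble$topology, chain_b, c(r, r), atom_filter)
  })
  values <- matrix(NA_real_, length(res_a), length(res_b))
  for (i in seq_along(groups_a)) {
    for (j in seq_along(groups_b)) {
      values[i, j] <- mean(.min_dist_over_frames(ensemble$frames,
                                                 groups_a[[i]],
                                                 groups_b[[j]]))
    }
  }
  label <- function(chain, res) {
    nm <- at$residue_name[match(paste(chain, res),
                                paste(at$chain_id, at$residue_number))]
    paste0(chain, ":", nm, res)
  }
  structure(
    list(rows = label(chain_a, res_a), cols = label(chain_b, res_b),
         values = values, n_frames_used = n_frames(ensemble)),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", length(x$rows), "x", length(x$cols),
      "residues, averaged over", x$n_frames_used, "frames\n")
  amin <- arrayInd(which.min(x$values), dim(x$values))
  cat(sprintf("  closest pair: %s -- %s (%.3f nm)\n",
              x$rows[amin[1]], x$cols[amin[2]], min(x$values)))
  invisible(x)
}

#' Write a contact matrix as TSV
#' @param cm a `contact_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(cm, path) {
  df <- as.data.frame(cm$values)
  names(df) <- cm$cols
  df <- cbind(residue = cm$rows, df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render a contact matrix as a heatmap PNG
#' @param cm a `contact_matrix`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_contact_map <- function(cm, path) {
  png(path, width = 900, height = 700, res = 110)
  op <- par(mar = c(6, 6, 2, 1))
  on.exit({ par(op); dev.off() })
  image(seq_along(cm$cols), seq_along(cm$rows), t(cm$values),
        col = rev(hcl.colors(64, "YlOrRd")), xlab = "", ylab = "",
        axes = FALSE,
        main = sprintf("Average minimum residue-residue distance (nm), %d frames",
                       cm$n_frames_used))
  axis(1, at = seq_along(cm$cols), labels = cm$cols, las = 2, cex.axis = 0.7)
  axis(2, at = seq_along(cm$rows), labels = cm$rows, las = 2, cex.axis = 0.7)
  box()
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
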