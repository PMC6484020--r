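# Structure and ensemble I/O.
#
# Internal length unit is nm throughout the package; PDB files (which are
# in Angstrom) are converted on read and write. Residue ranges are 1-based
# and inclusive on both ends, matching crystallographic numbering.

.BACKBONE_NAMES <- c("N", "CA", "C", "O")
.ANGSTROM_PER_NM <- 10

#' Construct an annotated structure
#'
#' An annotated structure couples an atom table (names, elements, chain and
#' residue labels) with one frame of coordinates in nm, plus named region
#' annotations mapping a role (e.g. `srm_helix`, `ezh2_loop`, `ligand`,
#' `reader`, `enzyme`) to a chain and an inclusive residue range.
#'
#' @param atoms data.frame with columns `atom_name`, `element`, `chain_id`,
#'   `residue_number`, `residue_name`.
#' @param coords numeric matrix, one row per atom, columns x/y/z in nm.
#' @param regions named list; each element a list with fields `chain`,
#'   `start`, `end` (inclusive residue range).
#' @return An object of class `annotated_structure`.
#' @export
annotated_structure <- function(atoms, coords, regions = list()) {
  stopifnot(is.data.frame(atoms), is.matrix(coords), ncol(coords) == 3)
  required <- c("atom_name", "element", "chain_id", "residue_number",
                "residue_name")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) != nrow(coords)) {
    stop("atom table and coordinate matrix disagree on atom count")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (any(atoms$residue_number < 1L)) stop("residue numbers must be >= 1")
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom name) records in structure")
  }
  x <- structure(
    list(atoms = atoms, coords = unname(coords), regions = list()),
    class = "annotated_structure"
  )
  if (length(regions) > 0L) x <- set_regions(x, regions)
  x
}

#' @export
print.annotated_structure <- function(x, ...) {
  cat("annotated_structure:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain_id)), "chains\n")
  if (length(x$regions) > 0L) {
    for (role in names(x$regions)) {
      r <- x$regions[[role]]
      cat(sprintf("  region %-10s chain %s residues %d-%d\n",
                  role, r$chain, r$start, r$end))
    }
  }
  invisible(x)
}

#' Attach region annotations to a structure
#'
#' Each region must select at least one atom; ranges are inclusive.
#'
#' @param structure an `annotated_structure`.
#' @param regions named list of `list(chain =, start =, end =)`.
#' @return The structure with regions replaced.
#' @export
set_regions <- function(structure, regions) {
  stopifnot(inherits(structure, "annotated_structure"))
  if (is.null(names(regions)) || any(!nzchar(names(regions)))) {
    stop("regions must be a named list")
  }
  for (role in names(regions)) {
    r <- regions[[role]]
    if (!all(c("chain", "start", "end") %in% names(r))) {
      stop("region '", role, "' needs fields chain, start, end")
    }
    if (r$start > r$end) stop("region '", role, "' has start > end")
    n_sel <- sum(structure$atoms$chain_id == r$chain &
                   structure$atoms$residue_number >= r$start &
                   structure$atoms$residue_number <= r$end)
    if (n_sel == 0L) {
      stop("region '", role, "' selects no atoms (chain ", r$chain,
           " residues ", r$start, "-", r$end, ")")
    }
  }
  structure$regions <- regions[order(names(regions))]
  structure
}

#' Read region annotations from a YAML or JSON config
#'
#' The file maps role names to `{chain, start, end}` blocks.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list suitable for [set_regions()].
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("region config not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    regions <- yaml::read_yaml(path)
  } else {
    regions <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  lapply(regions, function(r) {
    list(chain = as.character(r$chain), start = as.integer(r$start),
         end = as.integer(r$end))
  })
}

# Validate the ATOM/HETATM records of a PDB file before handing the file to
# the parser: fixed-width coordinate/residue fields must be numeric, chain
# ids present, insertion codes absent. Reports the offending line number.
.validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54L) {
      stop("malformed PDB record at line ", i, ": too short")
    }
    num_fields <- c(resno = substr(ln, 23, 26), x = substr(ln, 31, 38),
                    y = substr(ln, 39, 46), z = substr(ln, 47, 54))
    parsed <- suppressWarnings(as.numeric(num_fields))
    if (any(is.na(parsed))) {
      bad <- names(num_fields)[which(is.na(parsed))[1L]]
      stop("malformed PDB record at line ", i, ": field '", bad,
           "' is not numeric")
    }
    if (substr(ln, 22, 22) == " ") {
      stop("missing chain id in PDB record at line ", i)
    }
    if (substr(ln, 27, 27) != " ") {
      stop("insertion codes are not supported (line ", i, ")")
    }
  }
  invisible(sum(rec))
}

# bio3d atom table -> package atom table (+ first-altloc filtering).
.atoms_from_bio3d <- function(pdb) {
  at <- pdb$atom
  element <- at$elesy
  if (is.null(element)) element <- rep(NA_character_, nrow(at))
  # fall back to the leading letters of the atom name when the element
  # column is blank (common in hand-written files)
  blank <- is.na(element) | !nzchar(trimws(element))
  element[blank] <- sub("^([A-Za-z]).*$", "\\1", at$elety[blank])
  atoms <- data.frame(
    atom_name = trimws(at$elety),
    element = trimws(element),
    chain_id = as.character(at$chain),
    residue_number = as.integer(at$resno),
    residue_name = trimws(at$resid),
    stringsAsFactors = FALSE
  )
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
  keep <- !duplicated(key)  # first altloc kept
  list(atoms = atoms[keep, , drop = FALSE], keep = keep)
}

#' Read an annotated structure from file
#'
#' PDB input follows the wwPDB v3.3 fixed-width ATOM/HETATM subset
#' (coordinates converted from Angstrom to nm; first alternate location
#' kept; insertion codes rejected). XYZ input follows the package's
#' trajectory dialect (see [read_ensemble()]); only the first frame is
#' returned and chain/residue labels are synthesised.
#'
#' @param path input file.
#' @param format `"pdb"`, `"xyz"`, or `"auto"` (by extension).
#' @param regions optional region annotations (see [set_regions()]).
#' @return An `annotated_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz"),
                           regions = list()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  if (format == "xyz") {
    ens <- read_ensemble(path, format = "xyz")
    x <- ens$topology
    if (length(regions) > 0L) x <- set_regions(x, regions)
    return(x)
  }
  .validate_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  ab <- .atoms_from_bio3d(pdb)
  coords <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  coords <- coords[ab$keep, , drop = FALSE] / .ANGSTROM_PER_NM
  annotated_structure(ab$atoms, coords, regions)
}

#' Write an annotated structure to file
#'
#' @param structure an `annotated_structure`.
#' @param path output file.
#' @param format `"pdb"` or `"xyz"` (default by extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  ens <- trajectory_ensemble(structure, list(structure$coords), times = 0)
  write_ensemble(ens, path, format = format)
}

#' Construct a trajectory ensemble
#'
#' An ordered set of coordinate frames (nm) sharing one topology, with
#' per-frame times in ns and optional per-frame ground-truth labels (used
#' by the synthetic generator to validate the unbound-frame filter).
#'
#' @param topology an `annotated_structure`.
#' @param frames list of coordinate matrices (atoms x 3, nm).
#' @param times numeric vector of frame times in ns, strictly increasing.
#' @param truth optional data.frame with one row per frame (e.g. columns
#'   `bound`, `helix_folded`).
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(topology, frames, times = NULL, truth = NULL) {
  stopifnot(inherits(topology, "annotated_structure"), is.list(frames))
  if (length(frames) == 0L) stop("ensemble has zero frames")
  n_atoms <- nrow(topology$atoms)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n_atoms &&
                 ncol(f) == 3, logical(1))
  if (!all(ok)) stop("all frames must be atoms x 3 matrices matching topology")
  if (is.null(times)) times <- seq_along(frames) - 1
  if (length(times) != length(frames)) stop("times/frames length mismatch")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (!is.null(truth) && nrow(truth) != length(frames)) {
    stop("truth labels must have one row per frame")
  }
  structure(
    list(topology = topology, frames = lapply(frames, unname),
         times = as.numeric(times), truth = truth),
    class = "trajectory_ensemble"
  )
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("trajectory_ensemble:", length(x$frames), "frames,",
      nrow(x$topology$atoms), "atoms, t =", x$times[1], "-",
      x$times[length(x$times)], "ns\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `trajectory_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) length(ensemble$frames)

# Count atoms per MODEL block so inconsistent frames are reported as a
# format error rather than a parser crash.
.check_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) {
    return(if (sum(is_atom) == 0L) 0L else 1L)
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts)) {
    stop("unbalanced MODEL/ENDMDL records")
  }
  counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts, model_ends)
  if (length(unique(counts)) > 1L) {
    stop("inconsistent atom count across frames: ",
         paste(unique(counts), collapse = " vs "))
  }
  length(model_starts)
}

#' Read a multi-frame ensemble
#'
#' Supported formats: multi-model PDB (MODEL/ENDMDL; frame times are
#' synthesised as 0, 1, 2, ... ns since PDB carries none) and the XYZ
#' trajectory dialect: per frame, line 1 is the atom count, line 2 is
#' `t=<ns>`, then one `element x y z` line per atom with coordinates in nm.
#'
#' @param path input file.
#' @param format `"pdb"`, `"xyz"`, or `"auto"` (by extension).
#' @param regions optional region annotations applied to the topology.
#' @return A `trajectory_ensemble`.
#' @export
read_ensemble <- function(path, format = c("auto", "pdb", "xyz"),
                          regions = list()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  if (format == "xyz") {
    ens <- .read_xyz_ensemble(path)
  } else {
    n_models <- .check_pdb_models(path)
    if (n_models == 0L) stop("empty input: no frames in ", path)
    .validate_pdb_lines(path)
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    ab <- .atoms_from_bio3d(pdb)
    frames <- lapply(seq_len(nrow(pdb$xyz)), function(i) {
      m <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
      m[ab$keep, , drop = FALSE] / .ANGSTROM_PER_NM
    })
    topology <- annotated_structure(ab$atoms, frames[[1L]])
    ens <- trajectory_ensemble(topology, frames,
                               times = seq_along(frames) - 1)
  }
  if (length(regions) > 0L) {
    ens$topology <- set_regions(ens$topology, regions)
  }
  ens
}

.read_xyz_ensemble <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t]+$", "", lines)
  # drop trailing blank lines but keep internal structure intact
  i <- 1L
  n_total <- length(lines)
  frames <- list()
  times <- numeric(0)
  elements <- NULL
  n_atoms <- NA_integer_
  while (i <= n_total) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    cnt <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(cnt) || cnt < 1L) {
      stop("malformed XYZ frame header at line ", i, ": expected atom count")
    }
    if (is.na(n_atoms)) n_atoms <- cnt
    if (cnt != n_atoms) {
      stop("inconsistent atom count across frames at line ", i, ": ",
           cnt, " vs ", n_atoms)
    }
    tline <- trimws(lines[i + 1L])
    tm <- suppressWarnings(as.numeric(sub("^t=", "", tline)))
    if (!grepl("^t=", tline) || is.na(tm)) {
      stop("malformed XYZ time line at line ", i + 1L, ": expected t=<ns>")
    }
    body <- lines[(i + 2L):(i + 1L + cnt)]
    parts <- strsplit(trimws(body), "[ \t]+")
    ok <- vapply(parts, length, integer(1)) == 4L
    if (!all(ok)) {
      stop("malformed XYZ atom record at line ", i + 1L + which(!ok)[1L])
    }
    el <- vapply(parts, `[[`, character(1), 1L)
    xyz <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                  ncol = 3, byrow = TRUE)
    if (any(is.na(xyz))) {
      stop("non-numeric coordinate in XYZ frame starting at line ", i)
    }
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- xyz
    times <- c(times, tm)
    i <- i + 2L + cnt
  }
  if (length(frames) == 0L) stop("empty input: no frames in ", path)
  atoms <- data.frame(
    atom_name = elements,
    element = elements,
    chain_id = "A",
    residue_number = seq_len(n_atoms),
    residue_name = "UNK",
    stringsAsFactors = FALSE
  )
  topology <- annotated_structure(atoms, frames[[1L]])
  trajectory_ensemble(topology, frames, times = times)
}

#' Write an ensemble to file
#'
#' Multi-model PDB output quantises coordinates to the fixed-width 0.001
#' Angstrom precision (1e-4 nm) and drops frame times; the XYZ dialect
#' keeps full precision and times.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param path output file.
#' @param format `"pdb"` or `"xyz"` (default by extension).
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  at <- ensemble$topology$atoms
  if (format == "pdb") {
    xyz <- do.call(rbind, lapply(ensemble$frames, function(f) {
      as.vector(t(f * .ANGSTROM_PER_NM))
    }))
    bio3d::write.pdb(
      file = path, xyz = xyz,
      resno = at$residue_number, chain = at$chain_id,
      resid = at$residue_name, elety = at$atom_name,
      elesy = at$element, eleno = seq_len(nrow(at))
    )
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in seq_along(ensemble$frames)) {
      writeLines(as.character(nrow(at)), con)
      writeLines(sprintf("t=%.6g", ensemble$times[k]), con)
      f <- ensemble$frames[[k]]
      writeLines(sprintf("%s %.6f %.6f %.6f", at$element,
                         f[, 1], f[, 2], f[, 3]), con)
    }
  }
  invisible(path)
}

#' Select atoms by chain, residue range and atom class
#'
#' @param structure an `annotated_structure`.
#' @param chain chain id.
#' @param residues inclusive residue range `c(start, end)`, or `NULL` for
#'   the whole chain.
#' @param atom_filter `"all"`, `"heavy"` (element != H), `"side_chain"`
#'   (heavy atoms excluding backbone N/CA/C/O), or a character vector of
#'   atom names.
#' @return Integer atom indices in file order.
#' @export
select_atoms <- function(structure, chain, residues = NULL,
                         atom_filter = "all") {
  at <- structure$atoms
  if (!chain %in% at$chain_id) stop("chain '", chain, "' not in structure")
  sel <- at$chain_id == chain
  if (!is.null(residues)) {
    stopifnot(length(residues) == 2L)
    sel <- sel & at$residue_number >= residues[1] &
      at$residue_number <= residues[2]
  }
  sel <- sel & .atom_class_mask(at, atom_filter)
  idx <- which(sel)
  if (length(idx) == 0L) {
    rng <- if (is.null(residues)) "all residues"
           else paste0("residues ", residues[1], "-", residues[2])
    stop("empty selection: chain ", chain, ", ", rng, ", filter ",
         paste(atom_filter, collapse = ","))
  }
  idx
}

.atom_class_mask <- function(at, atom_filter) {
  if (length(atom_filter) == 1L &&
      atom_filter %in% c("all", "heavy", "side_chain")) {
    switch(atom_filter,
      all = rep(TRUE, nrow(at)),
      heavy = toupper(at$element) != "H",
      side_chain = toupper(at$element) != "H" &
        !(at$atom_name %in% .BACKBONE_NAMES)
    )
  } else {
    at$atom_name %in% atom_filter
  }
}

#' Select the atoms of an annotated region
#'
#' @param structure an `annotated_structure` with regions set.
#' @param role region role name (e.g. `"srm_helix"`).
#' @param atom_filter as in [select_atoms()].
#' @return Integer atom indices.
#' @export
region_atoms <- function(structure, role, atom_filter = "all") {
  r <- structure$regions[[role]]
  if (is.null(r)) stop("region '", role, "' not annotated")
  select_atoms(structure, r$chain, c(r$start, r$end), atom_filter)
}
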