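#' @importFrom stats dist setNames median var sd
#' @importFrom utils read.csv write.csv head tail
NULL

# Van der Waals radii (nm) used for SASA; unknown elements fall back to carbon.
.VDW_NM <- c(C = 0.170, N = 0.155, O = 0.152, S = 0.180, H = 0.120)
.VDW_DEFAULT_NM <- 0.170

#' Van der Waals radius lookup
#'
#' Returns the bundled van der Waals radius, in nm, for each element symbol.
#' Unknown elements get the carbon radius (0.170 nm) with a warning.
#'
#' @param element Character vector of element symbols (e.g. `"C"`, `"N"`).
#' @return Numeric vector of radii in nm.
#' @export
vdw_radius <- function(element) {
  element <- toupper(trimws(element))
  r <- unname(.VDW_NM[element])
  if (anyNA(r)) {
    unknown <- unique(element[is.na(r)])
    warning("Unknown element(s) ", paste(unknown, collapse = ", "),
            "; using default vdW radius ", .VDW_DEFAULT_NM, " nm")
    r[is.na(r)] <- .VDW_DEFAULT_NM
  }
  r
}

.make_atom_table <- function(serial, name, element, resname, resseq) {
  n <- length(serial)
  stopifnot(length(name) == n, length(element) == n,
            length(resname) == n, length(resseq) == n)
  # dense 0-based residue index from runs of author numbering
  ridx <- cumsum(c(0L, as.integer(diff(as.integer(resseq)) != 0L |
                                    resname[-1] != resname[-n])))
  data.frame(serial = as.integer(serial), name = as.character(name),
             element = as.character(element), resname = as.character(resname),
             resseq = as.integer(resseq), residue_index = ridx,
             radius = suppressWarnings(vdw_radius(element)),
             stringsAsFactors = FALSE)
}

#' Molecular structure container
#'
#' A single conformation: an atom table plus an `n x 3` coordinate matrix
#' in nm. All coordinates must be finite.
#'
#' @param atoms Atom table as built by the readers (columns `serial`, `name`,
#'   `element`, `resname`, `resseq`, `residue_index`, `radius`).
#' @param xyz Numeric `n x 3` matrix of coordinates, nm.
#' @return An object of class `md_structure`.
#' @export
md_structure <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  if (nrow(xyz) != nrow(atoms))
    stop("coordinate count (", nrow(xyz), ") does not match atom count (",
         nrow(atoms), ")")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  structure(list(atoms = atoms, xyz = xyz), class = "md_structure")
}

#' Trajectory container
#'
#' An ordered ensemble of frames sharing one atom table. Coordinates are
#' stored as an `n_atoms x 3 x n_frames` array in nm.
#'
#' @param atoms Shared atom table.
#' @param coords `n_atoms x 3 x n_frames` array, nm.
#' @param times Optional per-frame times, ns.
#' @param temperature Optional ensemble temperature label, K.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(atoms, coords, times = NULL, temperature = NULL) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(atoms))
    stop("frame atom count (", dim(coords)[1],
         ") does not match topology (", nrow(atoms), ")")
  if (dim(coords)[3] < 1L) stop("trajectory needs at least one frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  structure(list(atoms = atoms, coords = coords, times = times,
                 temperature = temperature), class = "md_trajectory")
}

#' @export
print.md_structure <- function(x, ...) {
  cat("md_structure:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$residue_index)), "residues\n")
  invisible(x)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", n_frames(x), "frames x", nrow(x$atoms), "atoms")
  if (!is.null(x$temperature)) cat(" @", x$temperature, "K")
  cat("\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `md_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as a structure
#' @param traj An `md_trajectory`.
#' @param frame Frame index (1-based).
#' @return An `md_structure`.
#' @export
get_frame <- function(traj, frame = 1L) {
  stopifnot(frame >= 1L, frame <= n_frames(traj))
  md_structure(traj$atoms, traj$coords[, , frame, drop = TRUE])
}

#' Keep a subset of frames
#' @param traj An `md_trajectory`.
#' @param idx Frame indices to keep, in order.
#' @return An `md_trajectory`.
#' @export
slice_frames <- function(traj, idx) {
  idx <- as.integer(idx)
  stopifnot(all(idx >= 1L), all(idx <= n_frames(traj)), length(idx) >= 1L)
  md_trajectory(traj$atoms, traj$coords[, , idx, drop = FALSE],
                times = traj$times[idx], temperature = traj$temperature)
}

# ---- PDB trajectory I/O (bio3d behind the module surface) -------------------

.prescan_pdb <- function(lines) {
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  atom_lines <- which(is_atom)
  if (length(atom_lines) == 0L) stop("no ATOM records found")
  for (ln in atom_lines) {
    l <- lines[ln]
    if (nchar(l) < 54L)
      stop("parse error at line ", ln, ": ATOM record shorter than 54 columns")
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                         substr(l, 47, 54))))
    if (anyNA(xyz))
      stop("parse error at line ", ln, ": unparseable coordinates")
    icode <- substr(l, 27, 27)
    if (icode != " " && icode != "")
      stop("insertion codes are not supported (line ", ln, ")")
  }
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1L) {
    ends <- c(model_starts[-1L] - 1L, length(lines))
    counts <- vapply(seq_along(model_starts), function(k)
      sum(is_atom[model_starts[k]:ends[k]]), integer(1))
    if (length(unique(counts)) != 1L)
      stop("malformed trajectory: MODEL records have inconsistent atom counts (",
           paste(counts, collapse = ", "), ")")
  }
  invisible(TRUE)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL record becomes one frame; a single-model file yields a one-frame
#' trajectory. Coordinates are converted from the PDB's angstrom to nm. The
#' atom order must be identical across models; first alternate location is
#' kept and insertion codes are rejected.
#'
#' @param path Path to a PDB file.
#' @return An `md_trajectory` (coordinates in nm).
#' @export
read_pdb_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  .prescan_pdb(readLines(path, warn = FALSE))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt == unique(at$alt[!is.na(at$alt)])[1]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nfr <- nrow(xyz)
  nat <- nrow(at)
  coords <- array(NA_real_, c(nat, 3L, nfr))
  for (f in seq_len(nfr))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) / 10  # A -> nm
  elesy <- at$elesy
  elesy[is.na(elesy) | elesy == ""] <- substr(trimws(at$elety[is.na(elesy) | elesy == ""]), 1, 1)
  atoms <- .make_atom_table(at$eleno, trimws(at$elety), trimws(elesy),
                            trimws(at$resid), at$resno)
  md_trajectory(atoms[keep, , drop = FALSE], coords[keep, , , drop = FALSE])
}

#' Write a trajectory as a multi-model PDB file
#'
#' Inverse of [read_pdb_trajectory()]; nm converted back to angstrom.
#'
#' @param traj An `md_trajectory`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pdb_trajectory <- function(traj, path) {
  a <- traj$atoms
  nfr <- n_frames(traj)
  xyz <- matrix(NA_real_, nfr, 3L * nrow(a))
  for (f in seq_len(nfr))
    xyz[f, ] <- as.numeric(t(traj$coords[, , f])) * 10  # nm -> A
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resseq, resid = a$resname,
                   eleno = a$serial, elety = a$name, elesy = a$element)
  invisible(path)
}

# ---- plain-text trajectory ("natoms nframes" header, nm) --------------------

#' Read a plain-text coordinate trajectory
#'
#' Format: a header line `natoms nframes`, then `nframes` blocks of `natoms`
#' lines `x y z` in nm. Atom metadata is synthesized as one C-alpha per
#' residue (`CA`/`GLY`, author numbering 1..natoms).
#'
#' @param path Input path.
#' @return An `md_trajectory`.
#' @export
read_txt_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- scan(con, integer(), n = 2L, quiet = TRUE)
  if (length(hdr) != 2L || any(hdr < 1L)) stop("bad header: expected 'natoms nframes'")
  vals <- scan(con, numeric(), n = 3L * hdr[1] * hdr[2], quiet = TRUE)
  if (length(vals) != 3L * hdr[1] * hdr[2])
    stop("malformed trajectory: expected ", 3L * hdr[1] * hdr[2],
         " values, got ", length(vals))
  coords <- array(NA_real_, c(hdr[1], 3L, hdr[2]))
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  for (f in seq_len(hdr[2]))
    coords[, , f] <- m[((f - 1L) * hdr[1] + 1L):(f * hdr[1]), , drop = FALSE]
  atoms <- .make_atom_table(seq_len(hdr[1]), rep("CA", hdr[1]), rep("C", hdr[1]),
                            rep("GLY", hdr[1]), seq_len(hdr[1]))
  md_trajectory(atoms, coords)
}

#' Write a plain-text coordinate trajectory
#' @param traj An `md_trajectory`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_txt_trajectory <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(nrow(traj$atoms), n_frames(traj)), con)
  for (f in seq_len(n_frames(traj))) {
    m <- traj$coords[, , f, drop = TRUE]
    writeLines(apply(format(m, digits = 15, scientific = FALSE, trim = TRUE),
                     1L, paste, collapse = " "), con)
  }
  invisible(path)
}

# ---- atom selection ---------------------------------------------------------

#' Select atoms from a trajectory
#'
#' Restricts the trajectory to matching atoms, preserving frame order and the
#' author residue numbering; the dense internal residue index is recomputed.
#'
#' @param traj An `md_trajectory`.
#' @param selection One of the keywords `"calpha"`, `"heavy"`, `"all"`, a
#'   logical vector over atoms, or a predicate `function(atoms)` returning one.
#' @return The restricted `md_trajectory`.
#' @export
select_atoms <- function(traj, selection = "calpha") {
  a <- traj$atoms
  keep <- if (is.character(selection)) {
    switch(match.arg(selection, c("calpha", "heavy", "all")),
           calpha = a$name == "CA",
           heavy  = toupper(a$element) != "H",
           all    = rep(TRUE, nrow(a)))
  } else if (is.function(selection)) {
    selection(a)
  } else if (is.logical(selection)) {
    stopifnot(length(selection) == nrow(a))
    selection
  } else stop("selection must be a keyword, logical vector, or predicate function")
  if (!any(keep)) stop("empty selection: predicate matched no atoms")
  sub <- .make_atom_table(a$serial[keep], a$name[keep], a$element[keep],
                          a$resname[keep], a$resseq[keep])
  md_trajectory(sub, traj$coords[keep, , , drop = FALSE],
                times = traj$times, temperature = traj$temperature)
}

# ---- residue matrix CSV -----------------------------------------------------

#' Write a residue-by-residue matrix as labeled CSV
#'
#' Header row and first column carry the residue labels (author numbering).
#' Values are printed with 15 significant digits so a round trip through
#' [read_matrix_csv()] reproduces them to at least 12 significant digits.
#'
#' @param m Square numeric matrix.
#' @param path Output path.
#' @param labels Row/column labels; length must match `nrow(m)`.
#' @return The path, invisibly.
#' @export
write_matrix_csv <- function(m, path, labels = rownames(m)) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix is not square: ", nrow(m), "x", ncol(m))
  if (is.null(labels)) labels <- seq_len(nrow(m))
  if (length(labels) != nrow(m)) stop("labels length does not match matrix size")
  out <- data.frame(residue = labels,
                    format(m, digits = 15, scientific = TRUE, trim = TRUE),
                    check.names = FALSE)
  colnames(out) <- c("residue", labels)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labeled residue matrix CSV
#' @param path Path written by [write_matrix_csv()].
#' @return Numeric matrix with label dimnames.
#' @export
read_matrix_csv <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}
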