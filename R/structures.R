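## Core data model: md_structure (one conformation), md_trajectory (ordered
## frames sharing atom metadata), atom_selection (ordered unique indices).
## Coordinates are N x 3 matrices in angstrom; trajectories store one frame
## per row as a length-3N vector (x1 y1 z1 x2 ...).

#' Create a molecular structure
#'
#' A structure is an N x 3 coordinate matrix (angstrom) with parallel atom
#' metadata vectors. All metadata vectors are recycled/validated to N.
#'
#' @param xyz numeric N x 3 matrix of coordinates in angstrom.
#' @param atom_names character atom names (e.g. `"CA"`).
#' @param residue_ids integer residue numbers.
#' @param residue_names character residue names (e.g. `"ALA"`).
#' @param elements character element symbols.
#' @param chain_ids character chain identifiers.
#' @return An object of class `md_structure`.
#' @export
md_structure <- function(xyz, atom_names = NULL, residue_ids = NULL,
                         residue_names = NULL, elements = NULL,
                         chain_ids = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) abort("`xyz` must be an N x 3 matrix")
  if (!all(is.finite(xyz))) abort("all coordinates must be finite")
  n <- nrow(xyz)
  fill <- function(x, default, cast) {
    if (is.null(x) || length(x) == 0L) x <- default
    x <- cast(x)
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n) abort("atom metadata length must match atom count")
    x
  }
  atoms <- tibble(
    atom_name = fill(atom_names, "CA", as.character),
    residue_id = fill(residue_ids, seq_len(n), as.integer),
    residue_name = fill(residue_names, "ALA", as.character),
    element = fill(elements, "C", as.character),
    chain_id = fill(chain_ids, "A", as.character)
  )
  dimnames(xyz) <- NULL
  structure(list(xyz = xyz, atoms = atoms), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf(
    "<md_structure> %d atoms, %d residues\n",
    n_atoms(x), length(unique(x$atoms$residue_id))
  ))
  invisible(x)
}

#' Number of atoms in a structure or trajectory
#' @param x an `md_structure` or `md_trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "md_structure")) {
    nrow(x$xyz)
  } else if (inherits(x, "md_trajectory")) {
    nrow(x$atoms)
  } else {
    abort("not a structure or trajectory")
  }
}

#' Create a trajectory from a list of structures
#'
#' All frames must share atom count and ordering; metadata is taken from the
#' first frame.
#'
#' @param frames list of `md_structure` objects.
#' @param times optional numeric per-frame times (ps).
#' @return An object of class `md_trajectory` storing frames as rows of a
#'   frames x 3N coordinate matrix.
#' @export
md_trajectory <- function(frames, times = NULL) {
  if (length(frames) < 1L) abort("a trajectory needs at least one frame")
  n <- n_atoms(frames[[1L]])
  xyz <- matrix(0, nrow = length(frames), ncol = 3L * n)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (n_atoms(f) != n) {
      abort(sprintf("frame %d has %d atoms, expected %d", i, n_atoms(f), n))
    }
    xyz[i, ] <- as.vector(t(f$xyz))
  }
  if (!is.null(times) && length(times) != length(frames)) {
    abort("`times` must have one entry per frame")
  }
  structure(list(xyz = xyz, atoms = frames[[1L]]$atoms, times = times),
    class = "md_trajectory"
  )
}

## internal fast constructor from a frames x 3N matrix
new_trajectory_ <- function(xyz_mat, atoms, times = NULL) {
  structure(list(xyz = xyz_mat, atoms = atoms, times = times),
    class = "md_trajectory"
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d atoms\n", n_frames(x), n_atoms(x)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame of a trajectory as a structure
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return An `md_structure`.
#' @export
get_frame <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) abort("frame index out of bounds")
  xyz <- matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
  structure(list(xyz = xyz, atoms = traj$atoms), class = "md_structure")
}

## frame coordinates as N x 3 without metadata copies
frame_xyz_ <- function(traj, i) matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)

#' Define an ordered atom selection
#'
#' @param indices integer atom indices (1-based), unique and ordered.
#' @param label short text label (e.g. `"calpha"`).
#' @return An object of class `atom_selection`.
#' @export
atom_selection <- function(indices, label = "custom") {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) abort("selection indices must be unique")
  if (any(indices < 1L)) abort("selection indices must be positive")
  structure(list(indices = indices, label = label), class = "atom_selection")
}

#' Build common atom selections from metadata
#'
#' @param x an `md_structure` or `md_trajectory`.
#' @param what `"all"`, `"calpha"` (atom name CA), `"heavy"` (element not H),
#'   or `"residues"` (restrict to `residues`).
#' @param residues integer residue ids used when `what = "residues"`.
#' @return An `atom_selection`.
#' @export
select_atoms <- function(x, what = c("all", "calpha", "heavy", "residues"),
                         residues = NULL) {
  what <- match.arg(what)
  atoms <- x$atoms
  idx <- switch(what,
    all = seq_len(nrow(atoms)),
    calpha = which(atoms$atom_name == "CA"),
    heavy = which(toupper(atoms$element) != "H"),
    residues = which(atoms$residue_id %in% as.integer(residues))
  )
  if (length(idx) == 0L) abort("selection is empty")
  atom_selection(idx, label = what)
}

## validate a selection against a structure/trajectory, return indices
sel_idx_ <- function(selection, x) {
  if (is.null(selection)) {
    return(seq_len(n_atoms(x)))
  }
  if (inherits(selection, "atom_selection")) {
    idx <- selection$indices
  } else {
    idx <- as.integer(selection)
  }
  if (length(idx) == 0L || any(idx < 1L) || any(idx > n_atoms(x))) {
    abort("selection out of bounds for this structure")
  }
  idx
}
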