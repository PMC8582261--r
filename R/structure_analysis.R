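## Structural observables along trajectories and MFEPs: per-element RMSD
## traces, geometric hydrogen-bond counts, Shrake-Rupley SASA, backbone
## dihedrals and pairwise RMSD maps.

#' Define a structural element by residue ranges
#'
#' @param name element label, e.g. `"A-loop"`, `"DFG"`, `"alphaC"`,
#'   `"P-loop"`.
#' @param residues integer residue ids (ranges can be given as
#'   `c(381:402)`).
#' @return An object of class `element_definition`.
#' @export
element_definition <- function(name, residues) {
  structure(list(name = name, residues = as.integer(residues)),
    class = "element_definition"
  )
}

element_idx_ <- function(x, element, mode = c("calpha", "heavy")) {
  mode <- match.arg(mode)
  atoms <- x$atoms
  in_res <- atoms$residue_id %in% element$residues
  idx <- if (mode == "calpha") {
    which(in_res & atoms$atom_name == "CA")
  } else {
    which(in_res & toupper(atoms$element) != "H")
  }
  if (length(idx) == 0L) {
    abort(sprintf("element '%s' selects no atoms", element$name))
  }
  idx
}

#' Per-frame RMSD of a structural element relative to a reference
#'
#' Each frame is fitted to the reference on the element's atoms
#' (mode-selected), then the RMSD over those same atoms is reported.
#'
#' @param traj an `md_trajectory`.
#' @param reference an `md_structure` (e.g. the target active state).
#' @param element an [element_definition()].
#' @param mode `"calpha"` or `"heavy"` atoms of the element.
#' @return Tibble with `frame`, `time_ps` (when available), `rmsd`
#'   (angstrom), and `element`.
#' @export
element_rmsd_trace <- function(traj, reference, element,
                               mode = c("calpha", "heavy")) {
  mode <- match.arg(mode)
  idx_t <- element_idx_(traj, element, mode)
  idx_r <- element_idx_(reference, element, mode)
  if (length(idx_t) != length(idx_r)) abort("element size mismatch with reference")
  ref <- reference$xyz[idx_r, , drop = FALSE]
  r <- vapply(seq_len(n_frames(traj)), function(i) {
    fitted_rmsd_(frame_xyz_(traj, i)[idx_t, , drop = FALSE], ref)
  }, 0)
  tibble(
    frame = seq_len(n_frames(traj)),
    time_ps = if (is.null(traj$times)) NA_real_ else traj$times,
    rmsd = r, element = element$name
  )
}

#' Geometric hydrogen-bond count
#'
#' Counts donor-acceptor pairs with donor-acceptor distance at most `d_max`
#' and hydrogen-donor-acceptor angle at most `angle_max` (the usual
#' 0.35 nm / 30 degree criterion). Hydrogens are located as H atoms within
#' 1.25 angstrom of a donor.
#'
#' @param structure an `md_structure` with explicit hydrogens on donors.
#' @param donors,acceptors `atom_selection`s of donor and acceptor heavy
#'   atoms.
#' @param d_max donor-acceptor cutoff in nm (default 0.35).
#' @param angle_max hydrogen-donor-acceptor cutoff in degrees (default 30).
#' @return Integer count of hydrogen bonds.
#' @export
hbond_count <- function(structure, donors, acceptors, d_max = 0.35,
                        angle_max = 30) {
  di <- sel_idx_(donors, structure)
  ai <- sel_idx_(acceptors, structure)
  xyz <- structure$xyz
  h_all <- which(toupper(structure$atoms$element) == "H")
  if (length(di) > 0L && length(h_all) == 0L) {
    abort("donor atoms have no hydrogens in the structure")
  }
  d_ang <- d_max * 10
  count <- 0L
  for (d in di) {
    hd <- h_all[sqrt(rowSums((xyz[h_all, , drop = FALSE] -
      matrix(xyz[d, ], length(h_all), 3L, byrow = TRUE))^2)) <= 1.25]
    if (length(hd) == 0L) {
      abort("donor atom has no attached hydrogen within 1.25 angstrom")
    }
    for (a in setdiff(ai, d)) {
      v_da <- xyz[a, ] - xyz[d, ]
      dist <- sqrt(sum(v_da^2))
      if (dist > d_ang) next
      for (h in hd) {
        v_dh <- xyz[h, ] - xyz[d, ]
        cosang <- sum(v_dh * v_da) / (sqrt(sum(v_dh^2)) * dist)
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        if (ang <= angle_max) {
          count <- count + 1L
          break
        }
      }
    }
  }
  count
}

## Bondi-style van der Waals radii (angstrom)
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)

## near-uniform unit sphere points (golden-section spiral)
sphere_points_ <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Dot-sphere SASA of the selected atoms computed in the context of the
#' full structure: each atom is covered with `n_points` near-uniform sphere
#' points at radius `r_vdw + probe`, and the accessible fraction (points
#' outside every other atom's probe-expanded sphere) is converted to area.
#'
#' @param structure an `md_structure` with element metadata.
#' @param selection atoms whose area is accumulated (default all).
#' @param probe probe radius in angstrom (default 1.4).
#' @param n_points dots per atom (default 960).
#' @return Total SASA of the selection in angstrom^2, with per-atom areas
#'   in attribute `per_atom` and the radius table name in attribute
#'   `radius_set`.
#' @export
sasa_shrake_rupley <- function(structure, selection = NULL, probe = 1.4,
                               n_points = 960L) {
  idx <- sel_idx_(selection, structure)
  el <- toupper(structure$atoms$element)
  unknown <- setdiff(unique(el), names(.vdw_radii))
  if (length(unknown) > 0L) {
    abort(sprintf("no van der Waals radius for element(s): %s", paste(unknown, collapse = ", ")))
  }
  rad <- .vdw_radii[el] + probe
  xyz <- structure$xyz
  n <- nrow(xyz)
  dots <- sphere_points_(n_points)
  per_atom <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    pts <- dots * rad[i] + matrix(xyz[i, ], n_points, 3L, byrow = TRUE)
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (dij >= rad[i] + rad[j]) next
      if (dij < 1e-9 && rad[j] >= rad[i]) {
        # coincident atom of equal/larger radius: do not bury the sphere
        if (j < i || rad[j] > rad[i]) exposed[] <- FALSE
        next
      }
      d2 <- rowSums((pts - matrix(xyz[j, ], n_points, 3L, byrow = TRUE))^2)
      exposed <- exposed & d2 >= rad[j]^2
      if (!any(exposed)) break
    }
    per_atom[k] <- 4 * pi * rad[i]^2 * sum(exposed) / n_points
  }
  out <- sum(per_atom)
  attr(out, "per_atom") <- per_atom
  attr(out, "radius_set") <- "Bondi"
  out
}

## signed dihedral of four points, IUPAC convention, (-180, 180]
dihedral_ <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(
    b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
    b1[1] * b2[2] - b1[2] * b2[1]
  )
  n2 <- c(
    b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
    b2[1] * b3[2] - b2[2] * b3[1]
  )
  m1 <- c(
    b2[2] * n1[3] - b2[3] * n1[2], b2[3] * n1[1] - b2[1] * n1[3],
    b2[1] * n1[2] - b2[2] * n1[1]
  ) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone dihedral angles phi and psi of one residue
#'
#' `phi = C(i-1)-N-CA-C`, `psi = N-CA-C-N(i+1)`; chain-terminal angles are
#' returned as `NA` rather than raising an error.
#'
#' @param structure an `md_structure` with N, CA, C backbone atoms.
#' @param residue residue id.
#' @return One-row tibble with `residue`, `phi`, `psi` in degrees,
#'   `(-180, 180]`.
#' @export
backbone_dihedrals <- function(structure, residue) {
  atoms <- structure$atoms
  get <- function(rid, name) {
    i <- which(atoms$residue_id == rid & atoms$atom_name == name)
    if (length(i) == 0L) NULL else structure$xyz[i[1L], ]
  }
  n_i <- get(residue, "N")
  ca <- get(residue, "CA")
  c_i <- get(residue, "C")
  if (is.null(n_i) || is.null(ca) || is.null(c_i)) {
    abort(sprintf("residue %d lacks backbone N/CA/C atoms", residue))
  }
  c_prev <- get(residue - 1L, "C")
  n_next <- get(residue + 1L, "N")
  phi <- if (is.null(c_prev)) NA_real_ else dihedral_(c_prev, n_i, ca, c_i)
  psi <- if (is.null(n_next)) NA_real_ else dihedral_(n_i, ca, c_i, n_next)
  tibble(residue = residue, phi = phi, psi = psi)
}

#' Pairwise fitted RMSD map between two frame sets
#'
#' Entry (i, j) is the fitted RMSD between frame i of `set_a` and frame j
#' of `set_b` over the selection; the per-row argmin identifies, for each
#' frame of `set_a`, its structurally closest partner in `set_b`.
#'
#' @param set_a,set_b `md_trajectory` objects (or single structures).
#' @param selection atoms used for the fit and RMSD.
#' @return Matrix of RMSDs (angstrom) with attribute `row_argmin`.
#' @export
pairwise_rmsd_map <- function(set_a, set_b, selection = NULL) {
  as_list <- function(x) {
    if (inherits(x, "md_structure")) {
      list(x$xyz[sel_idx_(selection, x), , drop = FALSE])
    } else {
      idx <- sel_idx_(selection, x)
      lapply(seq_len(n_frames(x)), function(i) frame_xyz_(x, i)[idx, , drop = FALSE])
    }
  }
  A <- as_list(set_a)
  B <- as_list(set_b)
  if (nrow(A[[1L]]) != nrow(B[[1L]])) abort("selection size mismatch between sets")
  flat <- function(L) do.call(rbind, lapply(L, function(co) as.vector(t(co))))
  M <- pairwise_fitted_rmsd(flat(A), flat(B), nrow(A[[1L]]), FALSE)
  attr(M, "row_argmin") <- apply(M, 1L, which.min)
  M
}
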