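## Optimal rigid-body superposition (Kabsch, via SVD) and displacement
## metrics. MSD is per-atom averaged (angstrom^2) so that the path smoothing
## parameter lambda (angstrom^-2) is dimensionally consistent; RMSD is its
## square root. This per-atom convention is used everywhere in the package.

## Rotation matrix R (column convention, x' = R %*% x) minimising
## || t(R %*% t(P)) - Q ||_F for centred point sets P, Q (rows = points).
kabsch_rotation_ <- function(P, Q) {
  H <- crossprod(P, Q) # 3 x 3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

## core fit: returns rotation R, centroids, rmsd over the fit set
kabsch_fit_ <- function(mob, ref) {
  cm <- colMeans(mob)
  cr <- colMeans(ref)
  P <- sweep(mob, 2L, cm)
  Q <- sweep(ref, 2L, cr)
  R <- kabsch_rotation_(P, Q)
  aligned <- P %*% t(R)
  msd <- sum((aligned - Q)^2) / nrow(mob)
  list(R = R, center_mobile = cm, center_ref = cr, msd = msd, aligned = aligned)
}

## fitted per-atom MSD between two N x 3 coordinate sets (compiled kernel)
fitted_msd_ <- function(a, b) fitted_msd_pair(a, b)

fitted_rmsd_ <- function(a, b) sqrt(fitted_msd_(a, b))

check_fit_atoms_ <- function(coords) {
  if (nrow(coords) < 3L) abort("superposition needs at least 3 fit atoms")
  ctr <- sweep(coords, 2L, colMeans(coords))
  s <- svd(ctr, nu = 0L, nv = 0L)$d
  if (s[2L] < 1e-8 * max(s[1L], 1)) {
    abort("degenerate fit: fit atoms are collinear")
  }
}

#' Superpose one structure onto another (Kabsch)
#'
#' Finds the proper rotation and translation of `mobile` that minimise the
#' RMSD over the fit selection, and applies it to all atoms of `mobile`.
#'
#' @param mobile,reference `md_structure` objects with matching fit atoms.
#' @param fit an `atom_selection` (or integer indices) of at least three
#'   non-collinear atoms used for the fit; default all atoms.
#' @return A list with `aligned` (transformed `md_structure`), `rotation`
#'   (3 x 3 proper rotation, column convention), and `rmsd` (angstrom, over
#'   the fit atoms).
#' @export
superpose_kabsch <- function(mobile, reference, fit = NULL) {
  idx <- sel_idx_(fit, mobile)
  idx_ref <- sel_idx_(fit, reference)
  if (length(idx) != length(idx_ref)) abort("fit selection size mismatch")
  mob <- mobile$xyz[idx, , drop = FALSE]
  ref <- reference$xyz[idx_ref, , drop = FALSE]
  check_fit_atoms_(mob)
  check_fit_atoms_(ref)
  f <- kabsch_fit_(mob, ref)
  all_centered <- sweep(mobile$xyz, 2L, f$center_mobile)
  new_xyz <- sweep(all_centered %*% t(f$R), 2L, f$center_ref, FUN = "+")
  aligned <- mobile
  aligned$xyz <- new_xyz
  list(aligned = aligned, rotation = f$R, rmsd = sqrt(f$msd))
}

#' RMSD and MSD between two structures
#'
#' MSD is the mean over selected atoms of the squared displacement (per-atom
#' convention, angstrom^2); RMSD is its square root. With `fit = TRUE` the
#' selected atoms are optimally superposed first.
#'
#' @param a,b `md_structure` objects.
#' @param selection atoms over which the displacement is measured (default
#'   all).
#' @param fit logical; superpose on `selection` before measuring.
#' @return Named list `(rmsd, msd)` in angstrom and angstrom^2.
#' @export
displacement_metrics <- function(a, b, selection = NULL, fit = FALSE) {
  ia <- sel_idx_(selection, a)
  ib <- sel_idx_(selection, b)
  if (length(ia) != length(ib)) abort("selection size mismatch between a and b")
  pa <- a$xyz[ia, , drop = FALSE]
  pb <- b$xyz[ib, , drop = FALSE]
  msd <- if (fit) fitted_msd_(pa, pb) else sum((pa - pb)^2) / length(ia)
  list(rmsd = sqrt(msd), msd = msd)
}

#' Fitted RMSD between two structures or coordinate frames
#'
#' Convenience wrapper around [displacement_metrics()] with `fit = TRUE`.
#'
#' @inheritParams displacement_metrics
#' @return RMSD in angstrom.
#' @export
rmsd_fitted <- function(a, b, selection = NULL) {
  displacement_metrics(a, b, selection = selection, fit = TRUE)$rmsd
}
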