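## Path collective variables. A reference path is an ordered set of N frames
## X_j (selected atoms, usually Calpha) plus a smoothing parameter lambda
## (angstrom^-2). For an instantaneous configuration X with fitted per-atom
## MSDs d_j^2 = ||X - X_j||^2 / M (optimal alignment per frame),
##
##   s(X) = sum_j j exp(-lambda d_j^2) / sum_j exp(-lambda d_j^2),  j = 1..N
##   z(X) = -(1/lambda) ln sum_j exp(-lambda d_j^2)
##   s_hat = (s - 1)/(N - 1)  in [0, 1]
##
## lambda = 2.3 / mean consecutive per-atom MSD, which gives lambda ~ 9.2
## A^-2 for ~0.5 A frame spacing. Both sums use a log-sum-exp shift.

#' Construct a reference path
#'
#' @param frames list of M x 3 coordinate matrices (or `md_structure`s), the
#'   ordered path frames over the path selection.
#' @param lambda smoothing parameter in angstrom^-2; computed from the mean
#'   consecutive MSD via [compute_lambda()] when `NULL`.
#' @param selection the `atom_selection` the frames were extracted with
#'   (kept for bookkeeping; may be `NULL` for standalone paths).
#' @param atoms atom metadata tibble for the path atoms (optional).
#' @param source_indices trajectory frame indices the path frames came from.
#' @return An object of class `reference_path` with fields `frames`,
#'   `lambda`, `spacing` (N-1 consecutive fitted RMSDs, angstrom),
#'   `selection`, `atoms`, `source_indices`.
#' @export
reference_path <- function(frames, lambda = NULL, selection = NULL,
                           atoms = NULL, source_indices = NULL) {
  frames <- lapply(frames, function(f) {
    if (inherits(f, "md_structure")) f$xyz else as.matrix(f)
  })
  if (length(frames) < 2L) abort("a reference path needs at least 2 frames")
  m <- nrow(frames[[1L]])
  if (any(vapply(frames, nrow, 0L) != m)) abort("path frames differ in atom count")
  spacing <- vapply(seq_len(length(frames) - 1L), function(j) {
    fitted_rmsd_(frames[[j + 1L]], frames[[j]])
  }, 0)
  if (is.null(atoms)) atoms <- md_structure(frames[[1L]])$atoms
  p <- structure(
    list(
      frames = frames, lambda = NA_real_, spacing = spacing,
      selection = selection, atoms = atoms, source_indices = source_indices
    ),
    class = "reference_path"
  )
  p$lambda <- if (is.null(lambda)) compute_lambda(p) else lambda
  if (p$lambda <= 0) abort("lambda must be positive")
  attr(p, "frames_cube") <- array(unlist(frames), dim = c(m, 3L, length(frames)))
  p
}

#' @export
print.reference_path <- function(x, ...) {
  cat(sprintf(
    "<reference_path> N = %d frames x %d atoms, lambda = %.4g A^-2, spacing %.3g-%.3g A\n",
    length(x$frames), nrow(x$frames[[1L]]), x$lambda,
    min(x$spacing), max(x$spacing)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.reference_path <- function(x, ...) {
  n <- length(x$frames)
  tibble(
    frame = seq_len(n),
    source_index = if (is.null(x$source_indices)) NA_integer_ else x$source_indices,
    spacing_prev = c(NA_real_, x$spacing)
  )
}

#' Smoothing parameter lambda from path spacing
#'
#' lambda = 2.3 divided by the mean consecutive per-atom MSD (angstrom^2).
#' For a uniformly 0.5-angstrom-spaced path this gives 2.3 / 0.25 = 9.2
#' angstrom^-2.
#'
#' @param path a `reference_path`.
#' @return lambda in angstrom^-2.
#' @export
compute_lambda <- function(path) {
  msd <- path$spacing^2
  if (any(msd <= 0)) abort("degenerate path: coincident consecutive frames")
  2.3 / mean(msd)
}

## internal: CV values and (optionally) gradients wrt the probe coordinates.
## xyz_sel: M x 3 probe coordinates over the path atoms.
path_cv_eval_ <- function(xyz_sel, path, grad = FALSE) {
  n <- length(path$frames)
  m <- nrow(xyz_sel)
  lambda <- path$lambda
  res <- fitted_msd_stack(xyz_sel, path_cube_(path), grad)
  d2 <- as.vector(res$d2)
  a <- -lambda * d2
  amax <- max(a)
  w <- exp(a - amax)
  sw <- sum(w)
  wn <- w / sw
  s <- sum(seq_len(n) * wn)
  z <- -(1 / lambda) * (log(sw) + amax)
  out <- list(
    s = s, s_hat = (s - 1) / (n - 1), z = z, d2 = d2, weights = wn
  )
  if (grad) {
    # gradients of the fitted MSDs (rotation/centroid terms vanish at the
    # Kabsch optimum), contracted with the softmin weights
    gm <- matrix(res$grad, m * 3L, n)
    coef_s <- -lambda * wn * (seq_len(n) - s)
    out$ds_dx <- matrix(gm %*% coef_s, m, 3L)
    out$dz_dx <- matrix(gm %*% wn, m, 3L)
  }
  out
}

## frames as an M x 3 x N array for the compiled kernel (cached)
path_cube_ <- function(path) {
  cube <- attr(path, "frames_cube")
  if (is.null(cube)) {
    m <- nrow(path$frames[[1L]])
    cube <- array(unlist(path$frames), dim = c(m, 3L, length(path$frames)))
  }
  cube
}

probe_xyz_ <- function(X, path) {
  xyz <- if (inherits(X, "md_structure")) X$xyz else as.matrix(X)
  m <- nrow(path$frames[[1L]])
  if (nrow(xyz) == m) {
    return(xyz)
  }
  if (!is.null(path$selection)) {
    idx <- path$selection$indices
    if (max(idx) <= nrow(xyz)) {
      return(xyz[idx, , drop = FALSE])
    }
  }
  abort("probe structure does not contain the path atoms")
}

#' Evaluate the path collective variables for one configuration
#'
#' Per-frame optimal alignment is applied before each displacement, and the
#' exponential sums are evaluated with a log-sum-exp shift.
#'
#' @param X an `md_structure` (full structure containing the path selection,
#'   or already reduced to the path atoms) or an M x 3 coordinate matrix.
#' @param path a `reference_path`.
#' @return One-row tibble with `s` (dimensionless, in (1, N)), `s_hat`
#'   (normalised progress in (0, 1)) and `z` (distance from the path,
#'   angstrom^2).
#' @export
evaluate_path_cvs <- function(X, path) {
  v <- path_cv_eval_(probe_xyz_(X, path), path)
  tibble(s = v$s, s_hat = v$s_hat, z = v$z)
}

#' Select reference-path frames from a trajectory
#'
#' Greedy forward scan: the first frame is kept; every later frame must be
#' strictly closer to the target than all previously kept frames
#' (topological consecutiveness) and is kept when its fitted RMSD from the
#' last kept frame first enters `[lo, hi]`. A frame jumping past `hi`
#' without any frame landing in the band is a path-gap error. The scan ends
#' at the trajectory frame closest to the target, which always terminates
#' the path.
#'
#' @param traj an `md_trajectory`.
#' @param target `md_structure` target state.
#' @param bounds numeric `(lo, hi)` spacing band in angstrom (default the
#'   0.44-0.60 band used for Calpha kinase paths).
#' @param selection atoms used for all RMSDs (default Calpha).
#' @return A `reference_path`.
#' @export
select_frames <- function(traj, target, bounds = c(0.44, 0.60),
                          selection = select_atoms(traj, "calpha")) {
  lo <- bounds[1L]
  hi <- bounds[2L]
  if (!(hi > lo && lo > 0)) abort("bounds must satisfy hi > lo > 0")
  idx <- sel_idx_(selection, traj)
  tgt <- target$xyz[sel_idx_(selection, target), , drop = FALSE]
  nf <- n_frames(traj)
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  sel_mat <- traj$xyz[, cols, drop = FALSE]
  coords <- lapply(seq_len(nf), function(i) {
    matrix(sel_mat[i, ], ncol = 3L, byrow = TRUE)
  })
  dist <- as.vector(pairwise_fitted_rmsd(
    sel_mat, matrix(as.vector(t(tgt)), nrow = 1L), length(idx), FALSE
  ))
  kept <- 1L
  min_kept <- dist[1L]
  closest <- which.min(dist)
  i <- 2L
  while (i <= closest) {
    if (dist[i] >= min_kept) {
      i <- i + 1L # not strictly closer to the target than every kept frame
      next
    }
    # frames within lo of the terminal frame are superseded by it
    if (i != closest &&
      fitted_rmsd_(coords[[i]], coords[[closest]]) < lo) {
      i <- i + 1L
      next
    }
    sp <- fitted_rmsd_(coords[[i]], coords[[kept[length(kept)]]])
    if (sp < lo) {
      i <- i + 1L
    } else if (sp <= hi) {
      kept <- c(kept, i)
      min_kept <- dist[i]
      i <- i + 1L
    } else if (i == closest) {
      break # the tail re-spacing below absorbs the terminal stretch
    } else {
      abort(sprintf(
        "path gap: no frame between %d and %d lands within [%.3g, %.3g] A (jump %.3g A)",
        kept[length(kept)], i, lo, hi, sp
      ))
    }
  }
  if (kept[length(kept)] != closest) {
    # terminate the path at the target-proximal frame; when the remaining
    # stretch does not fit the band, insert a penultimate in-band frame or
    # drop trailing kept frames until the tail can be re-spaced
    repeat {
      last <- kept[length(kept)]
      sp <- fitted_rmsd_(coords[[closest]], coords[[last]])
      if (sp >= lo && sp <= hi) {
        kept <- c(kept, closest)
        break
      }
      if (length(kept) == 1L) {
        if (sp > hi) {
          abort(sprintf(
            "path gap: closest-to-target frame %d is %.3g A from the last kept frame",
            closest, sp
          ))
        }
        kept <- c(kept, closest)
        break
      }
      if (sp < lo) {
        kept <- kept[-length(kept)]
        next
      }
      min_kept <- min(dist[kept])
      inserted <- FALSE
      for (j in (last + 1L):(closest - 1L)) {
        if (j <= last || j >= closest || dist[j] >= min_kept) next
        s1 <- fitted_rmsd_(coords[[j]], coords[[last]])
        if (s1 < lo || s1 > hi) next
        s2 <- fitted_rmsd_(coords[[j]], coords[[closest]])
        if (s2 < lo || s2 > hi) next
        kept <- c(kept, j)
        inserted <- TRUE
        break
      }
      if (!inserted) kept <- kept[-length(kept)]
    }
  }
  if (length(kept) < 2L) abort("fewer than 2 frames selected; widen the band")
  reference_path(
    frames = coords[kept],
    selection = if (inherits(selection, "atom_selection")) selection else atom_selection(idx),
    atoms = traj$atoms[idx, , drop = FALSE],
    source_indices = kept
  )
}

#' Diagnose spacing and topological consecutiveness of a path
#'
#' @param path a `reference_path`.
#' @param target `md_structure` (or coordinate matrix) target state.
#' @param bounds spacing band in angstrom.
#' @return List with `spacing_ok`, `topology_ok`, and `violations`, a tibble
#'   of offending frame indices and reasons.
#' @export
validate_path <- function(path, target, bounds = c(0.44, 0.60)) {
  tgt <- probe_xyz_(target, path)
  dist <- vapply(path$frames, function(f) fitted_rmsd_(f, tgt), 0)
  topo_bad <- which(diff(dist) >= 0) + 1L
  sp_bad <- which(path$spacing < bounds[1L] | path$spacing > bounds[2L]) + 1L
  violations <- dplyr::bind_rows(
    tibble(frame = as.integer(topo_bad), reason = "topology"),
    tibble(frame = as.integer(sp_bad), reason = "spacing")
  )
  list(
    spacing_ok = length(sp_bad) == 0L,
    topology_ok = length(topo_bad) == 0L,
    violations = violations
  )
}
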