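## Covariance analysis of trajectories (principal components / essential
## subspace) and GROMOS-style conformational clustering.

#' Principal components of trajectory fluctuations
#'
#' Frames are least-squares fitted (Kabsch) to the running mean over the
#' analysis selection (two fit/mean passes), the 3M x 3M covariance matrix
#' of the fitted coordinates is diagonalised, and eigenpairs are returned
#' in descending eigenvalue order with a deterministic sign convention
#' (first component of magnitude above 1e-8 is positive). The covariance
#' uses the population normalisation (divide by the frame count), so the
#' eigenvalue sum equals the total fitted fluctuation variance.
#'
#' @param traj an `md_trajectory` with at least two frames.
#' @param selection atoms entering the analysis (default heavy atoms).
#' @return An object of class `essential_subspace`: `mean` (M x 3 mean
#'   coordinates), `eigenvectors` (3M x K orthonormal columns),
#'   `eigenvalues` (variances, angstrom^2, descending), `atoms`, `selection`.
#' @export
covariance_modes <- function(traj, selection = select_atoms(traj, "heavy")) {
  if (n_frames(traj) < 2L) abort("covariance analysis needs at least 2 frames")
  idx <- sel_idx_(selection, traj)
  nf <- n_frames(traj)
  m <- length(idx)
  coords <- lapply(seq_len(nf), function(i) frame_xyz_(traj, i)[idx, , drop = FALSE])
  ref <- coords[[1L]]
  for (pass in 1:2) {
    fitted <- lapply(coords, function(co) {
      f <- kabsch_fit_(co, ref)
      sweep(f$aligned, 2L, f$center_ref, FUN = "+")
    })
    ref <- Reduce(`+`, fitted) / nf
  }
  X <- t(vapply(fitted, function(co) as.vector(t(co)), numeric(3L * m)))
  X <- sweep(X, 2L, colMeans(X))
  C <- crossprod(X) / nf
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  for (k in seq_len(ncol(vecs))) {
    lead <- which(abs(vecs[, k]) > 1e-8)
    if (length(lead) > 0L && vecs[lead[1L], k] < 0) vecs[, k] <- -vecs[, k]
  }
  structure(
    list(
      mean = ref, eigenvectors = vecs, eigenvalues = vals,
      atoms = traj$atoms[idx, , drop = FALSE],
      selection = if (inherits(selection, "atom_selection")) selection else atom_selection(idx)
    ),
    class = "essential_subspace"
  )
}

#' @export
print.essential_subspace <- function(x, ...) {
  cum <- cumsum(x$eigenvalues) / max(sum(x$eigenvalues), .Machine$double.eps)
  k90 <- which(cum >= 0.9)[1L]
  cat(sprintf(
    "<essential_subspace> %d atoms, %d modes; 90%% variance in %s modes\n",
    nrow(x$mean), length(x$eigenvalues), ifelse(is.na(k90), "NA", k90)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.essential_subspace <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  tibble(
    mode = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    cumulative_variance = if (tot > 0) cumsum(x$eigenvalues) / tot else NA_real_
  )
}

#' Export / import an essential subspace as plain text
#'
#' Mode-major labelled text format: a header with atom count and mode count,
#' the mean coordinates, then one block per mode (eigenvalue + 3M
#' components).
#'
#' @param subspace an `essential_subspace`.
#' @param file output path.
#' @return `file` (write) or an `essential_subspace` (read).
#' @export
write_subspace <- function(subspace, file) {
  con <- file(file, "w")
  on.exit(close(con))
  m <- nrow(subspace$mean)
  k <- ncol(subspace$eigenvectors)
  writeLines(sprintf("# essential_subspace atoms=%d modes=%d", m, k), con)
  writeLines("# mean", con)
  writeLines(sprintf("%.10g %.10g %.10g", subspace$mean[, 1], subspace$mean[, 2], subspace$mean[, 3]), con)
  for (j in seq_len(k)) {
    writeLines(sprintf("# mode %d eigenvalue %.10g", j, subspace$eigenvalues[j]), con)
    writeLines(sprintf("%.10g", subspace$eigenvectors[, j]), con)
  }
  invisible(file)
}

#' @rdname write_subspace
#' @export
read_subspace <- function(file) {
  lines <- readLines(file)
  hdr <- regmatches(lines[1L], regexec("atoms=(\\d+) modes=(\\d+)", lines[1L]))[[1L]]
  if (length(hdr) != 3L) abort("not a subspace file")
  m <- as.integer(hdr[2L])
  k <- as.integer(hdr[3L])
  mean_rows <- lines[3:(2L + m)]
  mean <- t(vapply(strsplit(mean_rows, "\\s+"), function(v) as.numeric(v), numeric(3)))
  pos <- 2L + m
  vecs <- matrix(0, 3L * m, k)
  vals <- numeric(k)
  for (j in seq_len(k)) {
    hdrj <- lines[pos + 1L]
    vals[j] <- as.numeric(sub(".*eigenvalue ", "", hdrj))
    vecs[, j] <- as.numeric(lines[(pos + 2L):(pos + 1L + 3L * m)])
    pos <- pos + 1L + 3L * m
  }
  structure(
    list(
      mean = mean, eigenvectors = vecs, eigenvalues = vals,
      atoms = md_structure(mean)$atoms, selection = NULL
    ),
    class = "essential_subspace"
  )
}

#' GROMOS conformational clustering
#'
#' Daura-style neighbour-count clustering: the frame with the most
#' neighbours (pairwise fitted RMSD at or below the cutoff) becomes a
#' cluster centroid; it and its neighbours are removed, and the procedure
#' repeats until no frames remain. Ties go to the lowest frame index.
#'
#' @param traj an `md_trajectory`.
#' @param selection atoms used for the pairwise fitted RMSD.
#' @param cutoff neighbour cutoff in nm (GROMOS convention; converted to
#'   angstrom internally). Default 0.15 nm.
#' @return An object of class `cluster_result` with `assignments` (tibble:
#'   frame, cluster), `centroids` (frame index per cluster) and `cutoff`.
#' @export
cluster_gromos <- function(traj, selection = select_atoms(traj, "all"),
                           cutoff = 0.15) {
  if (cutoff < 0) abort("cutoff must be non-negative")
  idx <- sel_idx_(selection, traj)
  nf <- n_frames(traj)
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  sel_mat <- traj$xyz[, cols, drop = FALSE]
  cutoff_ang <- cutoff * 10
  rmat <- pairwise_fitted_rmsd(sel_mat, sel_mat, length(idx), TRUE)
  adj <- rmat <= cutoff_ang
  remaining <- seq_len(nf)
  assignment <- integer(nf)
  centroids <- integer()
  cl <- 0L
  while (length(remaining) > 0L) {
    counts <- rowSums(adj[remaining, remaining, drop = FALSE])
    best <- remaining[which.max(counts)]
    members <- remaining[adj[best, remaining]]
    cl <- cl + 1L
    assignment[members] <- cl
    centroids <- c(centroids, best)
    remaining <- setdiff(remaining, members)
  }
  structure(
    list(
      assignments = tibble(frame = seq_len(nf), cluster = assignment),
      centroids = centroids, cutoff = cutoff
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %d frames in %d clusters (cutoff %.3g nm)\n",
    nrow(x$assignments), length(x$centroids), x$cutoff
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cluster_result <- function(x, ...) x$assignments
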