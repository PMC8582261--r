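# Shared helpers for the test suite: small random structures and an
# independent (plain, unoptimised) Kabsch/RMSD oracle used to cross-check
# the package implementation.

random_structure <- function(n = 8, seed = NULL, spread = 5) {
  if (!is.null(seed)) set.seed(seed)
  md_structure(matrix(rnorm(3 * n, sd = spread), ncol = 3))
}

rotation_about_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1),
    nrow = 3, byrow = TRUE
  )
}

# independent fitted-RMSD oracle: naive SVD Kabsch written from the textbook
# formula, no shared code with the package internals
oracle_fitted_rmsd <- function(a, b) {
  A <- sweep(a, 2, colMeans(a))
  B <- sweep(b, 2, colMeans(b))
  sv <- svd(t(A) %*% B)
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v) # A-side convention
  sqrt(sum((A %*% rot - B)^2) / nrow(a))
}

# helix-like test chain
test_chain <- function(n = 20) {
  th <- (seq_len(n) - 1) * 100 * pi / 180
  md_structure(
    cbind(2.3 * cos(th), 2.3 * sin(th), (seq_len(n) - 1) * 1.5),
    atom_names = "CA", residue_ids = seq_len(n), elements = "C"
  )
}

# radial expansion (breathing) mode: orthogonal to rigid translations and
# rotations at every amplitude, so fitted RMSDs between scaled copies are
# exact; normalised to unit per-atom rms
breathing_mode <- function(base) {
  ctr <- sweep(base, 2, colMeans(base))
  ctr / sqrt(mean(rowSums(ctr^2)))
}

# independent brute-force GROMOS clustering written from the algorithm
# description, using the naive Kabsch oracle for distances
oracle_gromos <- function(frames, cutoff_ang) {
  nf <- length(frames)
  d <- matrix(0, nf, nf)
  for (i in seq_len(nf)) {
    for (j in seq_len(nf)) {
      if (j > i) d[i, j] <- d[j, i] <- oracle_fitted_rmsd(frames[[i]], frames[[j]])
    }
  }
  assignment <- integer(nf)
  centroids <- integer()
  left <- seq_len(nf)
  cl <- 0L
  while (length(left) > 0L) {
    counts <- vapply(left, function(i) sum(d[i, left] <= cutoff_ang), 0L)
    best <- left[which.max(counts)]
    members <- left[d[best, left] <= cutoff_ang]
    cl <- cl + 1L
    assignment[members] <- cl
    centroids <- c(centroids, best)
    left <- setdiff(left, members)
  }
  list(assignment = assignment, centroids = centroids)
}
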