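# Covariance analysis, GROMOS clustering, and the EDS accept/project driver.

make_mode_trajectory <- function(n_atoms = 20, n_frames = 400, vars = c(4, 1),
                                 seed = 7) {
  # frames displaced along two orthonormal modes (orthogonal to the rigid
  # translations/rotations) with known population variances
  set.seed(seed)
  base <- test_chain(n_atoms)$xyz
  # rigid-motion basis at base: 3 translations + 3 infinitesimal rotations
  ctr <- sweep(base, 2, colMeans(base))
  rig <- cbind(
    rep(c(1, 0, 0), n_atoms), rep(c(0, 1, 0), n_atoms), rep(c(0, 0, 1), n_atoms),
    as.vector(t(cbind(-ctr[, 2], ctr[, 1], 0))),
    as.vector(t(cbind(ctr[, 3], 0, -ctr[, 1]))),
    as.vector(t(cbind(0, -ctr[, 3], ctr[, 2])))
  )
  Q <- qr.Q(qr(cbind(rig, matrix(rnorm(3 * n_atoms * 2), ncol = 2))))
  modes <- Q[, 7:8] # orthonormal, orthogonal to rigid motions
  amp <- cbind(rnorm(n_frames), rnorm(n_frames))
  amp <- sweep(amp, 2, colMeans(amp))
  amp <- sweep(amp, 2, apply(amp, 2, function(a) sqrt(mean(a^2))), "/")
  amp <- sweep(amp, 2, sqrt(vars), "*")
  frames <- lapply(seq_len(n_frames), function(i) {
    md_structure(base + matrix(modes %*% amp[i, ], ncol = 3, byrow = TRUE))
  })
  md_trajectory(frames)
}

test_that("rigid copies of one structure have no fluctuation modes", {
  s <- test_chain(10)
  frames <- lapply(seq(0, 1.5, length.out = 5), function(th) {
    out <- s
    out$xyz <- s$xyz %*% t(rotation_about_z(th)) +
      matrix(c(th, 2 * th, 0), 10, 3, byrow = TRUE)
    out
  })
  sub <- covariance_modes(md_trajectory(frames), select_atoms(s, "all"))
  expect_lt(max(sub$eigenvalues), 1e-10)
})

test_that("constructed modes are recovered with their variances", {
  traj <- make_mode_trajectory(vars = c(4, 1))
  sub <- covariance_modes(traj, select_atoms(traj, "all"))
  expect_equal(sub$eigenvalues[1], 4, tolerance = 0.02)
  expect_equal(sub$eigenvalues[2], 1, tolerance = 0.02)
  expect_lt(sub$eigenvalues[3], 0.01)
  # eigenvalue sum equals the total fitted fluctuation variance
  tot <- sum(sub$eigenvalues)
  expect_equal(tot, 4 + 1, tolerance = 0.05)
  # orthonormality and deterministic sign convention
  k <- ncol(sub$eigenvectors)
  expect_lt(max(abs(crossprod(sub$eigenvectors) - diag(k))), 1e-8)
  leads <- apply(sub$eigenvectors, 2, function(v) v[which(abs(v) > 1e-8)[1]])
  expect_true(all(leads > 0))
  # cumulative normalised variance reaches 1 at full rank
  expect_equal(max(tidy(sub)$cumulative_variance), 1, tolerance = 1e-12)
})

test_that("covariance analysis agrees with an independent PCA implementation", {
  skip_if_not_installed("bio3d")
  traj <- make_mode_trajectory(n_atoms = 8, n_frames = 100, vars = c(2, 0.5))
  sub <- covariance_modes(traj, select_atoms(traj, "all"))
  xyz <- traj$xyz
  fitted <- bio3d::fit.xyz(xyz[1, ], xyz,
    fixed.inds = seq_len(ncol(xyz)), mobile.inds = seq_len(ncol(xyz))
  )
  pc <- bio3d::pca.xyz(fitted)
  # bio3d normalises by (frames - 1); rescale to the population convention
  expect_equal(
    sub$eigenvalues[1:2], pc$L[1:2] * (nrow(xyz) - 1) / nrow(xyz),
    tolerance = 1e-2, ignore_attr = TRUE
  )
})

test_that("single-frame trajectories are rejected for covariance analysis", {
  traj <- md_trajectory(list(test_chain(6)))
  expect_error(covariance_modes(traj), "at least 2 frames")
})

test_that("GROMOS clustering handles the degenerate limits", {
  s <- test_chain(6)
  same <- md_trajectory(rep(list(s), 7))
  cl <- cluster_gromos(same, cutoff = 0.15)
  expect_equal(length(cl$centroids), 1L)
  expect_true(all(cl$assignments$cluster == 1L))

  set.seed(9)
  distinct <- md_trajectory(lapply(1:6, function(i) random_structure(6, seed = i)))
  cl0 <- cluster_gromos(distinct, cutoff = 0)
  expect_equal(length(cl0$centroids), 6L)
})

test_that("two well-separated bundles give two clusters with max-neighbour centroids", {
  set.seed(10)
  a <- test_chain(8)$xyz
  b <- a
  b[, 3] <- b[, 3] * 2.5 # a genuine shape change, not a rigid motion
  frames <- c(
    lapply(1:6, function(i) md_structure(a + matrix(rnorm(24, sd = 0.2), 8, 3))),
    lapply(1:5, function(i) md_structure(b + matrix(rnorm(24, sd = 0.2), 8, 3)))
  )
  traj <- md_trajectory(frames)
  cl <- cluster_gromos(traj, cutoff = 0.3)
  expect_equal(length(cl$centroids), 2L)
  want <- oracle_gromos(lapply(frames, `[[`, "xyz"), 3)
  expect_equal(cl$assignments$cluster, want$assignment)
  expect_equal(cl$centroids, want$centroids)
})

test_that("clustering matches brute force on random frame sets", {
  for (rep in 1:8) {
    set.seed(rep * 13)
    nf <- sample(10:30, 1)
    frames <- lapply(seq_len(nf), function(i) {
      md_structure(matrix(rnorm(12, sd = 2), 4, 3))
    })
    cutoff_ang <- runif(1, 1, 4)
    got <- cluster_gromos(md_trajectory(frames), cutoff = cutoff_ang / 10)
    want <- oracle_gromos(lapply(frames, `[[`, "xyz"), cutoff_ang)
    expect_equal(got$assignments$cluster, want$assignment)
    expect_equal(got$centroids, want$centroids)
  }
})

test_that("subspace round-trips through the plain-text format", {
  traj <- make_mode_trajectory(n_atoms = 6, n_frames = 50)
  sub <- covariance_modes(traj, select_atoms(traj, "all"))
  f <- withr::local_tempfile(fileext = ".txt")
  write_subspace(sub, f)
  back <- read_subspace(f)
  expect_equal(back$mean, sub$mean, tolerance = 1e-9)
  expect_equal(back$eigenvalues, sub$eigenvalues, tolerance = 1e-9)
  expect_equal(back$eigenvectors, sub$eigenvectors, tolerance = 1e-9)
})

test_that("accepted EDS trial steps that reduce the RMSD pass through unchanged", {
  sys <- make_two_state_system(12, 4, 4, seed = 4)
  tr <- make_interpolated_trajectory(sys$state_b, sys$state_b, 40, noise_sigma = 0.3, seed = 5)
  sub <- covariance_modes(tr, select_atoms(tr, "all"))
  params <- eds_params(subspace_size = 20, seed = 11)
  st <- eds_step(sys$state_a, NULL, sub, sys$state_b, sys$force_provider, params)
  expect_true(is.logical(st$accepted))
  r0 <- rmsd_fitted(sys$state_a, sys$state_b)
  expect_lte(st$rmsd, r0 + 1e-9)
})

test_that("EDS distance decays like the overdamped relaxation under a harmonic pull", {
  # harmonic provider centred on the target at near-zero temperature: the
  # deterministic overdamped decay rate is k * 100 / (mass * friction)
  sys <- make_two_state_system(10, 3, 4, seed = 6)
  k <- 2
  prov <- harmonic_force_provider(sys$state_b, k = k)
  tr <- make_interpolated_trajectory(sys$state_b, sys$state_b, 40, noise_sigma = 0.3, seed = 6)
  sub <- covariance_modes(tr, select_atoms(tr, "all"))
  params <- eds_params(
    subspace_size = 30, step_size = 0.002, temperature = 1e-8,
    friction = 50, mass = 12, seed = 3
  )
  run <- run_eds(sys$state_a, sys$state_b, sub, 400, prov, params)
  r <- c(rmsd_fitted(sys$state_a, sys$state_b), run$log$rmsd)
  rate_expected <- k * 100 / (params$mass * params$friction) # per ps
  t <- params$step_size * (seq_along(r) - 1)
  fit <- stats::lm(log(r) ~ t)
  expect_equal(unname(stats::coef(fit)[2]), -rate_expected, tolerance = 0.15)
})

test_that("the RMSD trace from run_eds is monotone and seeds reproduce exactly", {
  sys <- make_two_state_system(14, 4, 5, seed = 8)
  tr <- make_interpolated_trajectory(sys$state_b, sys$state_b, 40, noise_sigma = 0.3, seed = 9)
  sub <- covariance_modes(tr, select_atoms(tr, "all"))
  params <- eds_params(subspace_size = 30, seed = 21)
  run1 <- run_eds(sys$state_a, sys$state_b, sub, 300, sys$force_provider, params)
  run2 <- run_eds(sys$state_a, sys$state_b, sub, 300, sys$force_provider, params)
  expect_identical(run1$trajectory$xyz, run2$trajectory$xyz)
  expect_identical(run1$log$rmsd, run2$log$rmsd)
  expect_true(all(diff(run1$log$rmsd) <= 1e-6))

  # degenerate inputs
  expect_error(
    run_eds(sys$state_a, sys$state_b, sub, -1, sys$force_provider, params),
    "non-negative"
  )
  run0 <- run_eds(sys$state_a, sys$state_b, sub, 0, sys$force_provider, params)
  expect_equal(n_frames(run0$trajectory), 1L)
  expect_equal(frame_xyz <- get_frame(run0$trajectory, 1)$xyz, sys$state_a$xyz)
})

test_that("starting at the target keeps the RMSD at zero", {
  sys <- make_two_state_system(10, 3, 4, seed = 12)
  tr <- make_interpolated_trajectory(sys$state_b, sys$state_b, 30, noise_sigma = 0.3, seed = 13)
  sub <- covariance_modes(tr, select_atoms(tr, "all"))
  params <- eds_params(subspace_size = 20, seed = 5)
  run <- run_eds(sys$state_b, sys$state_b, sub, 100, sys$force_provider, params)
  # numerically zero: the fitted MSD loses ~1e-14 A^2 to cancellation, so
  # its square root can read as ~1e-7 A even for identical configurations
  expect_lt(max(run$log$rmsd), 1e-5)
})

test_that("non-finite forces abort the propagation", {
  sys <- make_two_state_system(8, 3, 4, seed = 14)
  tr <- make_interpolated_trajectory(sys$state_b, sys$state_b, 30, noise_sigma = 0.3, seed = 15)
  sub <- covariance_modes(tr, select_atoms(tr, "all"))
  bad <- function(xyz) list(energy = NaN, forces = xyz * NaN)
  expect_error(
    run_eds(sys$state_a, sys$state_b, sub, 10, bad, eds_params(10, seed = 1)),
    "non-finite"
  )
})
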