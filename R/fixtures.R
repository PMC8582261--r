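## Deterministic generators for every input class the toolkit needs:
## two-state bead-chain systems with a double-basin potential, interpolated
## trajectories with controlled frame spacing, analytic free-energy
## landscapes with known minima/valleys/barriers, and AR(1) series with
## known autocorrelation time. All generators are pure functions of
## (parameters, seed).

helix_chain_ <- function(n_beads, radius = 2.3, rise = 1.5, turn = 100) {
  th <- (seq_len(n_beads) - 1L) * turn * pi / 180
  z <- (seq_len(n_beads) - 1L) * rise
  cbind(radius * cos(th), radius * sin(th), z)
}

## smooth random low-frequency displacement field (3 Fourier modes/axis)
smooth_field_ <- function(n_beads) {
  t <- (seq_len(n_beads) - 1L) / (n_beads - 1L)
  D <- matrix(0, n_beads, 3L)
  for (ax in 1:3) {
    for (mode in 1:3) {
      D[, ax] <- D[, ax] + rnorm(1) * sin(pi * mode * t + runif(1, 0, 2 * pi))
    }
  }
  D / sqrt(mean(rowSums(D^2)))
}

#' Double-basin force provider anchored on two given conformations
#'
#' Exponential mix `V = -(1/beta*) ln(exp(-beta* V_A) + exp(-beta* V_B))` of
#' anisotropic harmonic wells about two reference conformations: soft along
#' the A-to-B displacement, stiff transverse to it. The soft force constant
#' is calibrated so the barrier along the inter-state line matches `barrier`
#' (kB T units at 300 K) within 10%.
#'
#' @param a,b reference conformations (`md_structure` or N x 3 matrices).
#' @param barrier barrier height in kB T units at 300 K.
#' @param k_stiff transverse force constant, kJ mol^-1 angstrom^-2.
#' @return List with `provider` (a force-provider function), `k_soft`,
#'   `beta_star`, and the realised `achieved_barrier_kbt`.
#' @export
two_state_force_provider <- function(a, b, barrier = 5, k_stiff = 5) {
  A <- if (inherits(a, "md_structure")) a$xyz else as.matrix(a)
  B <- if (inherits(b, "md_structure")) b$xyz else as.matrix(b)
  if (!all(dim(A) == dim(B))) abort("conformations differ in atom count")
  u <- (B - A) / sqrt(sum((B - A)^2)) # soft direction, unit 3N vector
  beta_star <- 1 / (.kB * 300)
  barrier_kj <- barrier * .kB * 300
  well <- function(xyz, ref, k_soft) {
    d <- xyz - ref
    cs <- sum(d * u)
    r2 <- sum(d^2)
    energy <- 0.5 * k_soft * cs^2 + 0.5 * k_stiff * (r2 - cs^2)
    gradient <- k_stiff * d + (k_soft - k_stiff) * cs * u
    list(energy = energy, gradient = gradient)
  }
  mix <- function(xyz, k_soft) {
    wa_ <- well(xyz, A, k_soft)
    wb_ <- well(xyz, B, k_soft)
    lo <- min(wa_$energy, wb_$energy)
    ea <- exp(-beta_star * (wa_$energy - lo))
    eb <- exp(-beta_star * (wb_$energy - lo))
    wa <- ea / (ea + eb)
    list(
      energy = lo - log(ea + eb) / beta_star,
      forces = -(wa * wa_$gradient + (1 - wa) * wb_$gradient)
    )
  }
  line_barrier <- function(k_soft) {
    ts <- seq(0, 1, length.out = 201L)
    v <- vapply(ts, function(t) mix((1 - t) * A + t * B, k_soft)$energy, 0)
    max(v) - v[1L]
  }
  k_soft <- uniroot(function(k) line_barrier(k) - barrier_kj,
    c(1e-6, 1e3),
    tol = 1e-10
  )$root
  list(
    provider = function(xyz) mix(xyz, k_soft),
    k_soft = k_soft, beta_star = beta_star,
    achieved_barrier_kbt = line_barrier(k_soft) / (.kB * 300)
  )
}

#' Two-state bead-chain system with a double-basin potential
#'
#' State A is an ideal Calpha helix; state B displaces it along a smooth
#' low-frequency deformation, scaled so the fitted RMSD between the states
#' matches `target_rmsd` within 5%. The potential is the exponential mix
#' `V = -(1/beta*) ln(exp(-beta* V_A) + exp(-beta* V_B))` of anisotropic
#' harmonic wells about each state: soft along the inter-state displacement
#' (the conformational mode) and stiff transverse to it, mimicking a folded
#' protein that fluctuates little off its transition pathway. The
#' soft-direction force constant is calibrated numerically so the barrier
#' along the inter-state line matches `barrier` (in kB T units at 300 K)
#' within 10%.
#'
#' @param n_beads number of beads (>= 4; default 30).
#' @param target_rmsd fitted RMSD between the states, angstrom (default 5).
#' @param barrier barrier height in kB T units at 300 K (default 5).
#' @param k_stiff transverse force constant, kJ mol^-1 angstrom^-2 per atom
#'   (default 5; sets the thermal distance-from-path scale z ~ 3 kT/k_stiff).
#' @param seed RNG seed for the deformation field.
#' @return An object of class `two_state_system`: `state_a`, `state_b`
#'   (`md_structure` Calpha chains), `force_provider`, `target_rmsd`,
#'   `achieved_rmsd`, and `calibration` (force constants, mixing beta*,
#'   achieved barrier).
#' @export
make_two_state_system <- function(n_beads = 30L, target_rmsd = 5,
                                  barrier = 5, k_stiff = 5, seed = 1L) {
  if (n_beads < 4L) abort("n_beads must be at least 4")
  with_seed_(seed, {
    A <- helix_chain_(n_beads)
    D <- smooth_field_(n_beads)
    f <- function(alpha) fitted_rmsd_(A + alpha * D, A) - target_rmsd
    hi <- 2
    while (f(hi) < 0 && hi < 1e4) hi <- hi * 2
    if (f(hi) < 0) abort("target_rmsd unreachable for this bead count")
    alpha <- uniroot(f, c(1e-6, hi), tol = 1e-10)$root
    B <- A + alpha * D
    achieved <- fitted_rmsd_(B, A)
    cal <- two_state_force_provider(A, B, barrier = barrier, k_stiff = k_stiff)
    provider <- cal$provider
    k_soft <- cal$k_soft
    structure(
      list(
        state_a = md_structure(A,
          atom_names = "CA", residue_names = "ALA",
          elements = "C", residue_ids = seq_len(n_beads)
        ),
        state_b = md_structure(B,
          atom_names = "CA", residue_names = "ALA",
          elements = "C", residue_ids = seq_len(n_beads)
        ),
        force_provider = provider,
        target_rmsd = target_rmsd, achieved_rmsd = achieved,
        calibration = list(
          k_soft = k_soft, k_stiff = k_stiff, beta_star = cal$beta_star,
          achieved_barrier_kbt = cal$achieved_barrier_kbt
        )
      ),
      class = "two_state_system"
    )
  })
}

#' @export
print.two_state_system <- function(x, ...) {
  cat(sprintf(
    "<two_state_system> %d beads, fitted rmsd %.3g A, barrier %.3g kBT\n",
    n_atoms(x$state_a), x$achieved_rmsd, x$calibration$achieved_barrier_kbt
  ))
  invisible(x)
}

#' Linearly interpolated trajectory between two structures
#'
#' Cartesian interpolation with optional isotropic Gaussian jitter;
#' endpoints are exact when `noise_sigma = 0`.
#'
#' @param a,b `md_structure`s with matching atoms.
#' @param n_frames number of frames (>= 2).
#' @param noise_sigma per-coordinate jitter standard deviation, angstrom.
#' @param seed RNG seed for the jitter.
#' @return An `md_trajectory`.
#' @export
make_interpolated_trajectory <- function(a, b, n_frames, noise_sigma = 0,
                                         seed = 1L) {
  if (n_frames < 2L) abort("n_frames must be at least 2")
  if (n_atoms(a) != n_atoms(b)) abort("structures differ in atom count")
  with_seed_(seed, {
    n <- n_atoms(a)
    xyz <- matrix(0, n_frames, 3L * n)
    for (i in seq_len(n_frames)) {
      t <- (i - 1) / (n_frames - 1)
      fr <- (1 - t) * a$xyz + t * b$xyz
      if (noise_sigma > 0) fr <- fr + matrix(rnorm(3L * n, sd = noise_sigma), ncol = 3L)
      xyz[i, ] <- as.vector(t(fr))
    }
    new_trajectory_(xyz, a$atoms)
  })
}

#' Analytic free-energy landscapes with known ground truth
#'
#' Three fixture kinds:
#' * `double_well_1d`: `V(x) = b ((x/x0)^2 - 1)^2 + (delta/2) (x/x0)`
#'   (kJ/mol), returned as a 1-dimensional `cv_potential` with numerically
#'   polished minima and barrier top.
#' * `curved_valley_2d`: `F(s_hat, z) = prof(s_hat) + kappa (z - g(s_hat))^2`
#'   in kcal/mol with valley `g(s_hat) = z0 + amp sin(pi s_hat)` and
#'   quadratic 1D profile; exposes the surface on a grid, the valley curve
#'   and the analytic 1D profile.
#' * `three_step_profile`: a 25-bin profile with two designed step barriers
#'   `(b1, b2)` followed by a downhill segment, mimicking a three-step
#'   activation.
#'
#' @param kind one of `"double_well_1d"`, `"curved_valley_2d"`,
#'   `"three_step_profile"`.
#' @param params named list overriding the defaults listed above.
#' @return A list whose content depends on `kind` (see Details); 1D and 2D
#'   kinds carry class `cv_potential` with `dim`, `energy`, `grad`, `x0`.
#' @export
make_analytic_fes <- function(kind = c(
                                "double_well_1d", "curved_valley_2d",
                                "three_step_profile"
                              ), params = list()) {
  kind <- match.arg(kind)
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  if (kind == "double_well_1d") {
    b <- p("barrier", 12) # kJ/mol
    delta <- p("delta", 4) # kJ/mol tilt
    x0 <- p("x0", 1)
    energy <- function(x) b * ((x / x0)^2 - 1)^2 + (delta / 2) * (x / x0)
    grad <- function(x) 4 * b * x * (x^2 / x0^2 - 1) / x0^2 + delta / (2 * x0)
    ml <- uniroot(grad, c(-2 * x0, -0.3 * x0), tol = 1e-12)$root
    mr <- uniroot(grad, c(0.3 * x0, 2 * x0), tol = 1e-12)$root
    top <- uniroot(grad, c(-0.3 * x0, 0.3 * x0), tol = 1e-12)$root
    return(structure(
      list(
        dim = 1L, energy = energy, grad = grad, x0 = ml,
        minima = c(ml, mr), barrier_top = top,
        barrier = energy(top) - energy(ml),
        delta_v = energy(mr) - energy(ml),
        domain = c(-2 * x0, 2 * x0), params = list(barrier = b, delta = delta, x0 = x0)
      ),
      class = "cv_potential"
    ))
  }
  if (kind == "curved_valley_2d") {
    z0 <- p("z0", 1.5)
    amp <- p("amp", 1.0)
    kappa <- p("kappa", 10) # kcal/mol/A^4
    a2 <- p("curvature", 8) # kcal/mol on (s_hat - 0.5)^2
    valley <- function(s_hat) z0 + amp * sin(pi * s_hat)
    prof <- function(s_hat) a2 * (s_hat - 0.5)^2
    fes_fn <- function(s_hat, z) prof(s_hat) + kappa * (z - valley(s_hat))^2
    on_grid <- function(n_s = 101L, n_z = 61L, z_lim = c(0, 3)) {
      s <- seq(0, 1, length.out = n_s)
      z <- seq(z_lim[1L], z_lim[2L], length.out = n_z)
      F <- outer(s, z, fes_fn)
      F <- F - min(F)
      structure(list(s_hat = s, z = z, F = F), class = "fes2d")
    }
    energy <- function(x) fes_fn(x[1L], x[2L]) * .kcal
    grad <- function(x) {
      g <- valley(x[1L])
      dg <- amp * pi * cos(pi * x[1L])
      c(
        2 * a2 * (x[1L] - 0.5) - 2 * kappa * (x[2L] - g) * dg,
        2 * kappa * (x[2L] - g)
      ) * .kcal
    }
    return(structure(
      list(
        dim = 2L, energy = energy, grad = grad, x0 = c(0, valley(0)),
        valley = valley, profile = prof, fes_fn = fes_fn, on_grid = on_grid,
        params = list(z0 = z0, amp = amp, kappa = kappa, curvature = a2)
      ),
      class = "cv_potential"
    ))
  }
  # three_step_profile
  b1 <- p("b1", 13.8)
  b2 <- p("b2", 7.5)
  v1 <- p("intermediate1", 1.2)
  v2 <- p("intermediate2", 0.3)
  drop <- p("drop", 3.4)
  knots_bin <- c(1, 2, 6, 11, 14, 17, 25)
  knots_val <- c(0.5, 0, b1, v1, v1 + b2, v2, v2 - drop)
  profile <- stats::approx(knots_bin, knots_val, xout = 1:25)$y
  list(
    kind = "three_step_profile",
    profile = profile,
    s_hat_centers = (1:25 - 0.5) / 25,
    truth = list(
      barriers = c(b1, b2),
      barrier_bins = c(6L, 14L),
      net = c(v1 - 0, (v2 - drop) - v1),
      rate_determining = max(b1, b2)
    )
  )
}

#' Stationary AR(1) series with known statistics
#'
#' `x_t = rho x_{t-1} + sqrt(1 - rho^2) sigma eps_t` starting from the
#' stationary distribution, with analytic autocorrelation time
#' `tau = -1/ln(rho)` and asymptotic standard error of the mean
#' `sigma sqrt((1 + rho) / ((1 - rho) n))`.
#'
#' @param n series length (>= 100).
#' @param rho lag-1 autocorrelation, `|rho| < 1`.
#' @param sigma stationary standard deviation.
#' @param seed RNG seed.
#' @return An object of class `ar1_series`: `series`, `rho`, `sigma`,
#'   `tau`, `sem`.
#' @export
make_ar1_series <- function(n, rho = 0.9, sigma = 1, seed = 1L) {
  if (abs(rho) >= 1) abort("|rho| must be below 1")
  if (n < 100L) abort("n must be at least 100")
  with_seed_(seed, {
    x <- numeric(n)
    x[1L] <- rnorm(1, sd = sigma)
    innov <- rnorm(n - 1L, sd = sigma * sqrt(1 - rho^2))
    for (t in 2:n) x[t] <- rho * x[t - 1L] + innov[t - 1L]
    structure(
      list(
        series = x, rho = rho, sigma = sigma,
        tau = if (rho > 0) -1 / log(rho) else NA_real_,
        sem = sigma * sqrt((1 + rho) / ((1 - rho) * n))
      ),
      class = "ar1_series"
    )
  })
}
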