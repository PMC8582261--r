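## Well-tempered metadynamics over the path CVs (s, z), or over the
## coordinates of an analytic CV-space potential. Gaussians of initial
## height w0 are deposited every `stride` steps with heights damped by
## exp(-V/(kB*DeltaT)), DeltaT = (gamma - 1) T; a one-sided harmonic wall
## ½ k (z - z_max)^2 restrains z from above. Gaussian widths sigma_s are in
## raw s (frame-index) units for molecular systems.

#' Parameters for well-tempered metadynamics
#'
#' Defaults follow common practice for kinase-scale path-CV runs: Gaussians
#' of 0.5 kJ/mol deposited every 500 steps, bias factor 30, widths 2.0 (raw
#' s units) and 0.005 angstrom^2, and a 10^4 kJ mol^-1 angstrom^-4 one-sided
#' wall beyond z = 3 angstrom^2.
#'
#' @param temperature K.
#' @param gamma bias factor (> 1).
#' @param w0 initial Gaussian height, kJ/mol.
#' @param stride steps between deposits.
#' @param sigma_s Gaussian width along s (raw frame-index units for
#'   molecular systems; the coordinate's own units for analytic potentials).
#' @param sigma_z Gaussian width along z, angstrom^2.
#' @param z_max upper wall position on z, angstrom^2.
#' @param wall_k wall force constant, kJ mol^-1 angstrom^-4 on (z - z_max)^2.
#' @param step_size,friction,mass Langevin propagator settings (ps, ps^-1,
#'   amu).
#' @param log_stride CV-log sampling interval in steps.
#' @param seed RNG seed.
#' @return A list of class `metad_params`.
#' @export
metad_params <- function(temperature = 300, gamma = 30, w0 = 0.5,
                         stride = 500L, sigma_s = 2.0, sigma_z = 0.005,
                         z_max = 3.0, wall_k = 1e4, step_size = 0.002,
                         friction = 5, mass = 12, log_stride = 1L,
                         seed = NULL) {
  if (gamma <= 1) abort("gamma must exceed 1")
  if (w0 <= 0 || sigma_s <= 0 || sigma_z <= 0) abort("heights and widths must be positive")
  if (stride < 1L) abort("stride must be at least 1")
  structure(
    list(
      temperature = temperature, gamma = gamma, w0 = w0,
      stride = as.integer(stride), sigma_s = sigma_s, sigma_z = sigma_z,
      z_max = z_max, wall_k = wall_k, step_size = step_size,
      friction = friction, mass = mass, log_stride = as.integer(log_stride),
      seed = seed
    ),
    class = "metad_params"
  )
}

#' Create an (initially empty) bias potential
#'
#' @param params a [metad_params()] object.
#' @param dim 1 (s only) or 2 (s and z).
#' @param n_path_frames number of reference-path frames when the s axis is
#'   in raw frame-index units (`NULL` when s is already the coordinate of an
#'   analytic potential).
#' @return An object of class `bias_potential` with a `hills` tibble
#'   (time, center_s, center_z, sigma_s, sigma_z, height).
#' @export
bias_potential <- function(params, dim = 2L, n_path_frames = NULL) {
  structure(
    list(
      hills = tibble(
        time = numeric(), center_s = numeric(), center_z = numeric(),
        sigma_s = numeric(), sigma_z = numeric(), height = numeric()
      ),
      params = params, dim = as.integer(dim), n_path_frames = n_path_frames
    ),
    class = "bias_potential"
  )
}

#' @export
print.bias_potential <- function(x, ...) {
  cat(sprintf(
    "<bias_potential> %d hills (dim %d), total deposited %.3g kJ/mol\n",
    nrow(x$hills), x$dim, sum(x$hills$height)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bias_potential <- function(x, ...) x$hills

## vectorised hill sum + gradient at a single point (6 sigma cutoff)
hills_eval_ <- function(hills, s, z, dim) {
  nh <- nrow(hills)
  if (nh == 0L) {
    return(list(energy = 0, grad_s = 0, grad_z = 0))
  }
  ds <- s - hills$center_s
  arg <- ds^2 / (2 * hills$sigma_s^2)
  if (dim >= 2L) {
    dz <- z - hills$center_z
    arg <- arg + dz^2 / (2 * hills$sigma_z^2)
  }
  keep <- arg < 34 # exp(-34) ~ 2e-15: truncation below double-precision noise
  if (!any(keep)) {
    return(list(energy = 0, grad_s = 0, grad_z = 0))
  }
  g <- hills$height[keep] * exp(-arg[keep])
  e <- sum(g)
  gs <- -sum(g * ds[keep] / hills$sigma_s[keep]^2)
  gz <- if (dim >= 2L) -sum(g * dz[keep] / hills$sigma_z[keep]^2) else 0
  list(energy = e, grad_s = gs, grad_z = gz)
}

wall_eval_ <- function(z, params) {
  if (is.null(params$wall_k) || params$wall_k <= 0 || z <= params$z_max) {
    return(list(energy = 0, grad_z = 0))
  }
  d <- z - params$z_max
  list(energy = 0.5 * params$wall_k * d^2, grad_z = params$wall_k * d)
}

#' Evaluate a bias potential (hills + wall) at a point
#'
#' @param bias a `bias_potential`.
#' @param at numeric `(s, z)` (or just `s` for 1-dimensional biases).
#' @param include_wall include the one-sided z wall (default `TRUE`).
#' @return List with `energy` (kJ/mol) and analytic gradients `grad_s`,
#'   `grad_z`.
#' @export
bias_value <- function(bias, at, include_wall = TRUE) {
  s <- at[1L]
  z <- if (length(at) >= 2L) at[2L] else 0
  if (!all(is.finite(c(s, z)))) abort("bias evaluation point must be finite")
  h <- hills_eval_(bias$hills, s, z, bias$dim)
  if (include_wall && bias$dim >= 2L) {
    w <- wall_eval_(z, bias$params)
    h$energy <- h$energy + w$energy
    h$grad_z <- h$grad_z + w$grad_z
  }
  h
}

#' Deposit one well-tempered Gaussian
#'
#' The new hill's height is `w0 * exp(-V(at) / (kB * DeltaT))` with
#' `DeltaT = (gamma - 1) * T` and `V` the already-deposited Gaussian bias
#' at the deposit point (the static wall does not temper the heights).
#'
#' @param bias a `bias_potential`.
#' @param at numeric `(s, z)` deposit centre.
#' @param params a [metad_params()]; defaults to the bias's own.
#' @param time deposit time stamp.
#' @return The updated `bias_potential`.
#' @export
deposit_gaussian <- function(bias, at, params = bias$params, time = NULL) {
  if (!all(is.finite(at))) abort("deposit point must be finite")
  s <- at[1L]
  z <- if (length(at) >= 2L) at[2L] else 0
  v <- hills_eval_(bias$hills, s, z, bias$dim)$energy
  dT <- (params$gamma - 1) * params$temperature
  h <- params$w0 * exp(-v / (.kB * dT))
  if (is.null(time)) {
    time <- if (nrow(bias$hills) > 0L) max(bias$hills$time) + 1 else 0
  }
  bias$hills <- dplyr::bind_rows(bias$hills, tibble(
    time = time, center_s = s, center_z = z,
    sigma_s = params$sigma_s, sigma_z = params$sigma_z, height = h
  ))
  bias
}

## fast engine-side hill store (preallocated), converted to tibble at the end
new_hill_store_ <- function(capacity) {
  list(
    n = 0L, time = numeric(capacity), cs = numeric(capacity),
    cz = numeric(capacity), h = numeric(capacity)
  )
}

store_eval_ <- function(st, s, z, sig_s, sig_z, dim) {
  if (st$n == 0L) {
    return(c(0, 0, 0))
  }
  i <- seq_len(st$n)
  ds <- s - st$cs[i]
  arg <- ds^2 / (2 * sig_s^2)
  if (dim >= 2L) {
    dz <- z - st$cz[i]
    arg <- arg + dz^2 / (2 * sig_z^2)
  }
  keep <- arg < 34
  if (!any(keep)) {
    return(c(0, 0, 0))
  }
  g <- st$h[i][keep] * exp(-arg[keep])
  e <- sum(g)
  gs <- -sum(g * ds[keep]) / sig_s^2
  gz <- if (dim >= 2L) -sum(g * dz[keep]) / sig_z^2 else 0
  c(e, gs, gz)
}

#' Run well-tempered metadynamics
#'
#' Two system kinds are supported:
#' * an analytic CV-space potential from [make_analytic_fes()] (class
#'   `cv_potential`): the particle's coordinates are the CVs themselves;
#' * a toy molecular system (class `two_state_system`) together with a
#'   [reference_path()]: atoms are propagated under the physical forces
#'   plus the bias/wall forces mapped through the analytic path-CV
#'   gradients, and hills live in raw `s` (frame-index) and `z`.
#'
#' Langevin (BAOAB) propagation; hills are deposited every
#' `params$stride` steps; a fixed `params$seed` makes the CV log and hill
#' list reproducible.
#'
#' @param system a `cv_potential` or `two_state_system`.
#' @param params a [metad_params()].
#' @param n_steps number of integration steps.
#' @param path `reference_path` (molecular systems only).
#' @param x0 optional initial state: CV coordinates, or an `md_structure`.
#' @return An object of class `metad_run`: `cv_log` (tibble: step, time,
#'   s, s_hat, z, bias), `bias` (`bias_potential`), `params`.
#' @export
run_wt_metad <- function(system, params, n_steps, path = NULL, x0 = NULL) {
  if (n_steps < 0) abort("n_steps must be non-negative")
  with_seed_(params$seed, {
    if (inherits(system, "cv_potential")) {
      run_metad_cv_(system, params, n_steps, x0)
    } else if (inherits(system, "two_state_system")) {
      if (is.null(path)) abort("molecular metadynamics needs a reference path")
      run_metad_mol_(system, params, n_steps, path, x0)
    } else {
      abort("unsupported system type")
    }
  })
}

finish_metad_ <- function(st, params, dim, n_path_frames, logd) {
  bias <- bias_potential(params, dim = dim, n_path_frames = n_path_frames)
  if (st$n > 0L) {
    i <- seq_len(st$n)
    bias$hills <- tibble(
      time = st$time[i], center_s = st$cs[i], center_z = st$cz[i],
      sigma_s = params$sigma_s, sigma_z = params$sigma_z, height = st$h[i]
    )
  }
  structure(
    list(cv_log = logd, bias = bias, params = params),
    class = "metad_run"
  )
}

run_metad_cv_ <- function(system, params, n_steps, x0) {
  dim <- system$dim
  x <- if (is.null(x0)) system$x0 else as.numeric(x0)
  v <- rnorm(dim, sd = sqrt(.kB * params$temperature * .kj_to_accel / params$mass))
  st <- new_hill_store_(max(1L, n_steps %/% params$stride + 1L))
  nlog <- n_steps %/% params$log_stride
  ls <- numeric(nlog)
  lz <- numeric(nlog)
  lb <- numeric(nlog)
  lt <- numeric(nlog)
  k <- 0L
  dT <- (params$gamma - 1) * params$temperature
  c1 <- exp(-params$friction * params$step_size)
  c2 <- sqrt(.kB * params$temperature * .kj_to_accel / params$mass * (1 - c1^2))
  inv_m <- .kj_to_accel / params$mass
  dt <- params$step_size
  total_force <- function(x) {
    g <- system$grad(x)
    bv <- store_eval_(st, x[1L], if (dim >= 2L) x[2L] else 0, params$sigma_s, params$sigma_z, dim)
    f <- -g
    f[1L] <- f[1L] - bv[2L]
    if (dim >= 2L) {
      w <- wall_eval_(x[2L], params)
      f[2L] <- f[2L] - bv[3L] - w$grad_z
    }
    list(f = f, bias_e = bv[1L])
  }
  tf <- total_force(x)
  for (i in seq_len(n_steps)) {
    v <- v + 0.5 * dt * tf$f * inv_m
    x <- x + 0.5 * dt * v
    v <- c1 * v + c2 * rnorm(dim)
    x <- x + 0.5 * dt * v
    if (!all(is.finite(x))) abort(sprintf("trajectory diverged at step %d", i))
    tf <- total_force(x)
    v <- v + 0.5 * dt * tf$f * inv_m
    if (i %% params$stride == 0L) {
      zc <- if (dim >= 2L) x[2L] else 0
      vb <- store_eval_(st, x[1L], zc, params$sigma_s, params$sigma_z, dim)[1L]
      st$n <- st$n + 1L
      st$time[st$n] <- i * dt
      st$cs[st$n] <- x[1L]
      st$cz[st$n] <- zc
      st$h[st$n] <- params$w0 * exp(-vb / (.kB * dT))
      tf <- total_force(x)
    }
    if (i %% params$log_stride == 0L) {
      k <- k + 1L
      lt[k] <- i * dt
      ls[k] <- x[1L]
      lz[k] <- if (dim >= 2L) x[2L] else 0
      lb[k] <- tf$bias_e
    }
  }
  logd <- tibble(
    step = params$log_stride * seq_len(k), time_ps = lt[seq_len(k)],
    s = ls[seq_len(k)], s_hat = rep(NA_real_, k), z = lz[seq_len(k)],
    bias = lb[seq_len(k)]
  )
  finish_metad_(st, params, dim, NULL, logd)
}

run_metad_mol_ <- function(system, params, n_steps, path, x0) {
  start <- if (is.null(x0)) system$state_a else x0
  x <- start$xyz
  n <- nrow(x)
  npf <- length(path$frames)
  sel <- if (is.null(path$selection)) seq_len(n) else sel_idx_(path$selection, start)
  v <- maxwell_velocities_(n, params$mass, params$temperature)
  st <- new_hill_store_(max(1L, n_steps %/% params$stride + 1L))
  nlog <- n_steps %/% params$log_stride
  ls <- numeric(nlog)
  lz <- numeric(nlog)
  lb <- numeric(nlog)
  lt <- numeric(nlog)
  k <- 0L
  dT <- (params$gamma - 1) * params$temperature
  c1 <- exp(-params$friction * params$step_size)
  c2 <- sqrt(.kB * params$temperature * .kj_to_accel / params$mass * (1 - c1^2))
  inv_m <- .kj_to_accel / params$mass
  dt <- params$step_size
  total_force <- function(x) {
    phys <- system$force_provider(x)
    cv <- path_cv_eval_(x[sel, , drop = FALSE], path, grad = TRUE)
    bv <- store_eval_(st, cv$s, cv$z, params$sigma_s, params$sigma_z, 2L)
    w <- wall_eval_(cv$z, params)
    f <- phys$forces
    f[sel, ] <- f[sel, , drop = FALSE] -
      bv[2L] * cv$ds_dx - (bv[3L] + w$grad_z) * cv$dz_dx
    list(f = f, cv = cv, bias_e = bv[1L] + w$energy)
  }
  tf <- total_force(x)
  for (i in seq_len(n_steps)) {
    v <- v + 0.5 * dt * tf$f * inv_m
    x <- x + 0.5 * dt * v
    v <- c1 * v + c2 * matrix(rnorm(3L * n), ncol = 3L)
    x <- x + 0.5 * dt * v
    if (!all(is.finite(x))) abort(sprintf("trajectory diverged at step %d", i))
    tf <- total_force(x)
    v <- v + 0.5 * dt * tf$f * inv_m
    if (i %% params$stride == 0L) {
      vb <- store_eval_(st, tf$cv$s, tf$cv$z, params$sigma_s, params$sigma_z, 2L)[1L]
      st$n <- st$n + 1L
      st$time[st$n] <- i * dt
      st$cs[st$n] <- tf$cv$s
      st$cz[st$n] <- tf$cv$z
      st$h[st$n] <- params$w0 * exp(-vb / (.kB * dT))
      tf <- total_force(x)
    }
    if (i %% params$log_stride == 0L) {
      k <- k + 1L
      lt[k] <- i * dt
      ls[k] <- tf$cv$s
      lz[k] <- tf$cv$z
      lb[k] <- tf$bias_e
    }
  }
  logd <- tibble(
    step = params$log_stride * seq_len(k), time_ps = lt[seq_len(k)],
    s = ls[seq_len(k)], s_hat = (ls[seq_len(k)] - 1) / (npf - 1),
    z = lz[seq_len(k)], bias = lb[seq_len(k)]
  )
  finish_metad_(st, params, 2L, npf, logd)
}

#' @export
print.metad_run <- function(x, ...) {
  cat(sprintf(
    "<metad_run> %d logged samples, %d hills, last height %.3g kJ/mol\n",
    nrow(x$cv_log), nrow(x$bias$hills),
    if (nrow(x$bias$hills) > 0) x$bias$hills$height[nrow(x$bias$hills)] else NA_real_
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.metad_run <- function(x, ...) x$cv_log

#' @exportS3Method generics::glance
glance.metad_run <- function(x, ...) {
  tibble(
    n_samples = nrow(x$cv_log), n_hills = nrow(x$bias$hills),
    total_bias = sum(x$bias$hills$height),
    s_range = diff(range(x$cv_log$s)),
    gamma = x$params$gamma
  )
}
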