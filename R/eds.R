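## Essential dynamics sampling (EDS). Trial moves from a Langevin propagator
## are accepted when the fitted RMSD to the target diminishes; otherwise the
## displacement component inside the retained principal-component subspace
## is radially corrected so the subspace distance to the target does not
## grow, motion in the orthogonal complement is kept, and the outward radial
## velocity component is removed.

#' Parameters for essential dynamics sampling
#'
#' @param subspace_size number of retained principal components.
#' @param selection atoms used for the acceptance RMSD to the target
#'   (`NULL`: the subspace's own selection).
#' @param step_size integration step in ps.
#' @param temperature bath temperature in K.
#' @param friction Langevin friction in ps^-1.
#' @param mass particle mass in amu.
#' @param seed RNG seed (`NULL`: use the current stream).
#' @return A list of class `eds_params`.
#' @export
eds_params <- function(subspace_size, selection = NULL, step_size = 0.004,
                       temperature = 300, friction = 20, mass = 12,
                       seed = NULL) {
  if (subspace_size < 1L) abort("subspace_size must be at least 1")
  structure(
    list(
      subspace_size = as.integer(subspace_size), selection = selection,
      step_size = step_size, temperature = temperature, friction = friction,
      mass = mass, seed = seed
    ),
    class = "eds_params"
  )
}

## cached geometry shared across steps of one run
eds_context_ <- function(current, target, subspace, params) {
  if (params$subspace_size > ncol(subspace$eigenvectors)) {
    abort("subspace_size exceeds the available number of modes")
  }
  sub_idx <- if (is.null(subspace$selection)) {
    if (nrow(subspace$mean) != n_atoms(current)) {
      abort("subspace selection missing and atom counts differ")
    }
    seq_len(n_atoms(current))
  } else {
    sel_idx_(subspace$selection, current)
  }
  acc_sel <- if (is.null(params$selection)) sub_idx else sel_idx_(params$selection, current)
  V <- subspace$eigenvectors[, seq_len(params$subspace_size), drop = FALSE]
  tgt_sub <- target$xyz[sub_idx, , drop = FALSE]
  ft <- kabsch_fit_(tgt_sub, subspace$mean)
  tgt_aligned <- sweep(ft$aligned, 2L, ft$center_ref, FUN = "+")
  p_target <- as.vector(crossprod(V, as.vector(t(tgt_aligned)) - as.vector(t(subspace$mean))))
  list(
    sub_idx = sub_idx, acc_sel = acc_sel, V = V, p_target = p_target,
    tgt_acc = target$xyz[acc_sel, , drop = FALSE], mean = subspace$mean
  )
}

## project selected coordinates into subspace coords (relative to target)
eds_project_ <- function(xyz, ctx) {
  sub <- xyz[ctx$sub_idx, , drop = FALSE]
  f <- kabsch_fit_(sub, ctx$mean)
  aligned <- sweep(f$aligned, 2L, f$center_ref, FUN = "+")
  p <- as.vector(crossprod(ctx$V, as.vector(t(aligned)) - as.vector(t(ctx$mean))))
  list(p = p, R = f$R)
}

eds_step_ <- function(x, v, forces, provider, ctx, params) {
  rmsd_cur <- fitted_rmsd_(x[ctx$acc_sel, , drop = FALSE], ctx$tgt_acc)
  st <- baoab_step_(
    x, v, forces, provider, params$step_size, params$mass,
    params$friction, params$temperature
  )
  rmsd_trial <- fitted_rmsd_(st$x[ctx$acc_sel, , drop = FALSE], ctx$tgt_acc)
  if (rmsd_trial <= rmsd_cur + 1e-12) {
    return(list(x = st$x, v = st$v, forces = st$forces, accepted = TRUE, rmsd = rmsd_trial))
  }
  # radial correction in subspace coordinates
  prj_cur <- eds_project_(x, ctx)
  prj_tri <- eds_project_(st$x, ctx)
  d_cur <- prj_cur$p - ctx$p_target
  d_tri <- prj_tri$p - ctx$p_target
  r_cur <- sqrt(sum(d_cur^2))
  r_tri <- sqrt(sum(d_tri^2))
  x_new <- st$x
  v_new <- st$v
  if (r_tri > r_cur && r_tri > 0) {
    d_corr <- d_tri * (r_cur / r_tri)
    dp <- d_corr - d_tri
    delta_aligned <- matrix(as.vector(ctx$V %*% dp), ncol = 3L, byrow = TRUE)
    x_new[ctx$sub_idx, ] <- x_new[ctx$sub_idx, , drop = FALSE] +
      delta_aligned %*% prj_tri$R
    u <- if (r_cur > 0) d_cur / r_cur else d_tri / r_tri
    v_sub <- v_new[ctx$sub_idx, , drop = FALSE] %*% t(prj_tri$R)
    p_v <- as.vector(crossprod(ctx$V, as.vector(t(v_sub))))
    rv <- sum(p_v * u)
    if (rv > 0) {
      dv_aligned <- matrix(as.vector(ctx$V %*% (-rv * u)), ncol = 3L, byrow = TRUE)
      v_new[ctx$sub_idx, ] <- v_new[ctx$sub_idx, , drop = FALSE] +
        dv_aligned %*% prj_tri$R
    }
  }
  rmsd_new <- fitted_rmsd_(x_new[ctx$acc_sel, , drop = FALSE], ctx$tgt_acc)
  if (rmsd_new > rmsd_cur + 1e-9) {
    # motion outside the retained subspace would still move away from the
    # target: hold the coordinates, keep the corrected velocities
    x_new <- x
    rmsd_new <- rmsd_cur
  }
  fr <- provider(x_new)
  list(x = x_new, v = v_new, forces = fr$forces, accepted = FALSE, rmsd = rmsd_new)
}

#' One essential-dynamics-sampling step
#'
#' @param current `md_structure`, the current configuration.
#' @param velocity N x 3 velocity matrix (angstrom/ps); `NULL` draws
#'   Maxwell-Boltzmann velocities.
#' @param subspace an [covariance_modes()] `essential_subspace` of the
#'   target state.
#' @param target `md_structure` target configuration.
#' @param force_provider `function(xyz) -> list(energy, forces)`.
#' @param params an [eds_params()] object.
#' @return List with `next_structure`, `velocity`, `accepted`, and `rmsd`
#'   (fitted RMSD to the target after the step).
#' @export
eds_step <- function(current, velocity, subspace, target, force_provider,
                     params) {
  ctx <- eds_context_(current, target, subspace, params)
  if (is.null(velocity)) {
    velocity <- with_seed_(params$seed, maxwell_velocities_(
      n_atoms(current), params$mass, params$temperature
    ))
  }
  fr <- force_provider(current$xyz)
  st <- eds_step_(current$xyz, velocity, fr$forces, force_provider, ctx, params)
  nxt <- current
  nxt$xyz <- st$x
  list(next_structure = nxt, velocity = st$v, accepted = st$accepted, rmsd = st$rmsd)
}

#' Run an essential dynamics sampling simulation
#'
#' Propagates from `initial` towards `target` with [eds_step()] dynamics.
#' The fitted RMSD to the target along the returned states is monotonically
#' non-increasing by construction.
#'
#' @inheritParams eds_step
#' @param initial starting `md_structure`.
#' @param n_steps number of steps (>= 0).
#' @param save_every store every k-th state in the returned trajectory
#'   (the RMSD/acceptance log is always per step).
#' @return An object of class `eds_run`: `trajectory` (`md_trajectory` of
#'   the initial state plus saved states), `log` (tibble: step, time_ps,
#'   rmsd, accepted), `params`.
#' @export
run_eds <- function(initial, target, subspace, n_steps, force_provider,
                    params, save_every = 1L) {
  if (n_steps < 0) abort("n_steps must be non-negative")
  ctx <- eds_context_(initial, target, subspace, params)
  with_seed_(params$seed, {
    x <- initial$xyz
    v <- maxwell_velocities_(n_atoms(initial), params$mass, params$temperature)
    fr <- force_provider(x)
    saved <- list(x)
    log_rmsd <- numeric(n_steps)
    log_acc <- logical(n_steps)
    forces <- fr$forces
    for (i in seq_len(n_steps)) {
      st <- eds_step_(x, v, forces, force_provider, ctx, params)
      x <- st$x
      v <- st$v
      forces <- st$forces
      log_rmsd[i] <- st$rmsd
      log_acc[i] <- st$accepted
      if (i %% save_every == 0L) saved[[length(saved) + 1L]] <- x
    }
    xyz_mat <- do.call(rbind, lapply(saved, function(co) as.vector(t(co))))
    traj <- new_trajectory_(
      xyz_mat, initial$atoms,
      times = params$step_size * save_every * (seq_along(saved) - 1L)
    )
    structure(
      list(
        trajectory = traj,
        log = tibble(
          step = seq_len(n_steps),
          time_ps = params$step_size * seq_len(n_steps),
          rmsd = log_rmsd, accepted = log_acc
        ),
        params = params
      ),
      class = "eds_run"
    )
  })
}

#' @export
print.eds_run <- function(x, ...) {
  fin <- if (nrow(x$log) > 0) x$log$rmsd[nrow(x$log)] else NA_real_
  cat(sprintf(
    "<eds_run> %d steps, final rmsd to target %.3g A, %.1f%% accepted\n",
    nrow(x$log), fin, 100 * mean(x$log$accepted)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.eds_run <- function(x, ...) x$log

#' @exportS3Method generics::glance
glance.eds_run <- function(x, ...) {
  tibble(
    n_steps = nrow(x$log),
    final_rmsd = if (nrow(x$log) > 0) x$log$rmsd[nrow(x$log)] else NA_real_,
    acceptance_rate = mean(x$log$accepted),
    n_frames = n_frames(x$trajectory)
  )
}
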