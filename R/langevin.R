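## Internal Langevin (BAOAB) propagator on toy force providers.
## A force provider is a function(xyz) returning list(energy = kJ/mol,
## forces = N x 3 in kJ/mol/angstrom). Masses in amu, times in ps;
## 1 kJ/mol = 100 amu A^2 ps^-2.

maxwell_velocities_ <- function(n, mass, temperature) {
  vsd <- sqrt(.kB * temperature * .kj_to_accel / mass)
  matrix(rnorm(3L * n, sd = vsd), ncol = 3L)
}

## one BAOAB step; forces_cur = provider(x)$forces already evaluated
baoab_step_ <- function(x, v, forces_cur, provider, dt, mass, friction,
                        temperature) {
  inv_m <- .kj_to_accel / mass
  c1 <- exp(-friction * dt)
  c2 <- sqrt(.kB * temperature * .kj_to_accel / mass * (1 - c1^2))
  v <- v + 0.5 * dt * forces_cur * inv_m
  x <- x + 0.5 * dt * v
  v <- c1 * v + c2 * matrix(rnorm(length(v)), ncol = 3L)
  x <- x + 0.5 * dt * v
  fr <- provider(x)
  if (!all(is.finite(fr$forces))) abort("force provider returned non-finite forces")
  v <- v + 0.5 * dt * fr$forces * inv_m
  list(x = x, v = v, forces = fr$forces, energy = fr$energy)
}

#' Harmonic force provider centred on a reference structure
#'
#' V = k/2 * sum_i |x_i - x0_i|^2, a convenience provider for tests and
#' demonstrations.
#'
#' @param reference `md_structure` or N x 3 matrix, the well centre.
#' @param k force constant in kJ mol^-1 angstrom^-2.
#' @return A force-provider function.
#' @export
harmonic_force_provider <- function(reference, k = 10) {
  x0 <- if (inherits(reference, "md_structure")) reference$xyz else as.matrix(reference)
  function(xyz) {
    d <- xyz - x0
    list(energy = 0.5 * k * sum(d^2), forces = -k * d)
  }
}
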