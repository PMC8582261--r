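## Free-energy reconstruction from the deposited bias, minimum-free-energy
## path extraction on a binned s_hat axis, constant-final-bias reweighting,
## and block-averaging error estimation.

## hills-only bias energy at many points, chunked to bound memory
bias_on_points_ <- function(bias, s, z, include_wall = FALSE) {
  out <- numeric(length(s))
  hills <- bias$hills
  nh <- nrow(hills)
  if (nh > 0L) {
    chunk <- max(1L, 2e6 %/% nh)
    for (lo in seq(1L, length(s), by = chunk)) {
      hi <- min(lo + chunk - 1L, length(s))
      ds <- outer(s[lo:hi], hills$center_s, "-")
      arg <- sweep(ds^2, 2L, 2 * hills$sigma_s^2, "/")
      if (bias$dim >= 2L) {
        dz <- outer(z[lo:hi], hills$center_z, "-")
        arg <- arg + sweep(dz^2, 2L, 2 * hills$sigma_z^2, "/")
      }
      out[lo:hi] <- as.vector(exp(-arg) %*% hills$height)
    }
  }
  if (include_wall && bias$dim >= 2L) {
    k <- bias$params$wall_k
    zm <- bias$params$z_max
    out <- out + ifelse(z > zm, 0.5 * k * (z - zm)^2, 0)
  }
  out
}

#' Free-energy surface from a converged well-tempered bias
#'
#' Under well-tempered damping the deposited bias converges to
#' `-(gamma - 1)/gamma` times the free energy, so
#' `F = -(gamma/(gamma - 1)) * V_bias` (hills only; the static wall is
#' excluded). The result is converted to kcal/mol and shifted so the global
#' minimum is zero.
#'
#' @param bias a `bias_potential` with at least one hill.
#' @param s_grid grid along s. For biases built on a reference path this is
#'   interpreted as the normalised s_hat axis in `[0, 1]` and mapped to raw
#'   frame-index units internally; defaults to 101 points on `[0, 1]` (or
#'   the hill range for analytic coordinates).
#' @param z_grid grid along z (2-dimensional biases); defaults to 61 points
#'   from 0 to the wall position.
#' @return For 2-dimensional biases an object of class `fes2d` (fields
#'   `s_hat`, `z`, `F` matrix in kcal/mol); for 1-dimensional biases a
#'   `fes1d` (fields `x`, `F`).
#' @export
fes_from_bias <- function(bias, s_grid = NULL, z_grid = NULL) {
  if (nrow(bias$hills) == 0L) abort("empty bias: no hills deposited")
  gamma <- bias$params$gamma
  fac <- gamma / (gamma - 1) / .kcal
  if (bias$dim == 1L) {
    if (is.null(s_grid)) {
      r <- range(bias$hills$center_s)
      pad <- 3 * max(bias$hills$sigma_s)
      s_grid <- seq(r[1L] - pad, r[2L] + pad, length.out = 201L)
    }
    v <- bias_on_points_(bias, s_grid, rep(0, length(s_grid)))
    F <- -fac * v
    F <- F - min(F)
    return(structure(list(x = s_grid, F = F), class = "fes1d"))
  }
  npf <- bias$n_path_frames
  if (is.null(s_grid)) {
    s_grid <- if (!is.null(npf)) {
      seq(0, 1, length.out = 101L)
    } else {
      seq(min(bias$hills$center_s), max(bias$hills$center_s), length.out = 101L)
    }
  }
  if (is.null(z_grid)) {
    zhi <- if (!is.null(bias$params$z_max)) bias$params$z_max else max(bias$hills$center_z)
    z_grid <- seq(0, zhi, length.out = 61L)
  }
  s_raw <- if (!is.null(npf)) 1 + s_grid * (npf - 1) else s_grid
  pts <- expand.grid(s = s_raw, z = z_grid)
  v <- bias_on_points_(bias, pts$s, pts$z)
  F <- matrix(-fac * v, nrow = length(s_grid))
  F <- F - min(F)
  structure(list(s_hat = s_grid, z = z_grid, F = F), class = "fes2d")
}

#' @export
print.fes2d <- function(x, ...) {
  cat(sprintf(
    "<fes2d> %d x %d grid, F range 0-%.3g kcal/mol\n",
    length(x$s_hat), length(x$z), max(x$F)
  ))
  invisible(x)
}

#' @export
print.fes1d <- function(x, ...) {
  cat(sprintf(
    "<fes1d> %d grid points, F range 0-%.3g kcal/mol\n",
    length(x$x), max(x$F)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fes2d <- function(x, ...) {
  tibble(
    s_hat = rep(x$s_hat, times = length(x$z)),
    z = rep(x$z, each = length(x$s_hat)),
    F = as.vector(x$F)
  )
}

#' @exportS3Method generics::tidy
tidy.fes1d <- function(x, ...) {
  grid <- x[["x"]]
  fvals <- x[["F"]]
  tibble(x = grid, F = fvals)
}

## first strict local minimum (boundaries count)
first_local_min_ <- function(F) {
  n <- length(F)
  for (i in seq_len(n)) {
    left_ok <- i == 1L || F[i] < F[i - 1L]
    right_ok <- i == n || F[i] <= F[i + 1L]
    if (left_ok && right_ok) {
      return(i)
    }
  }
  which.min(F)
}

#' Extract the minimum free energy path from a 2D surface
#'
#' The s_hat axis is divided into `n_bins` bins of equal width; within each
#' bin the grid node of lowest free energy (over z and within-bin s_hat) is
#' taken. The profile is referenced to its first local minimum (the
#' starting-basin bin).
#'
#' @param fes a `fes2d`.
#' @param n_bins number of bins (default 25).
#' @return An object of class `mfep_profile`: a tibble with `bin`,
#'   `s_hat_center`, `z_at_min` (angstrom^2) and `F` (kcal/mol, referenced),
#'   with attributes `reference` (subtracted value) and `n_bins`.
#' @export
extract_mfep <- function(fes, n_bins = 25L) {
  if (min(fes$s_hat) > 1e-9 || max(fes$s_hat) < 1 - 1e-9) {
    abort("FES grid must cover s_hat in [0, 1]")
  }
  edges <- seq(0, 1, length.out = n_bins + 1L)
  binF <- numeric(n_bins)
  binz <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    inbin <- which(fes$s_hat >= edges[b] - 1e-12 &
      (fes$s_hat < edges[b + 1L] | (b == n_bins & fes$s_hat <= 1 + 1e-12)))
    if (length(inbin) == 0L) {
      abort(sprintf("bin %d contains no grid nodes: refine the s_hat grid", b))
    }
    sub <- fes$F[inbin, , drop = FALSE]
    w <- arrayInd(which.min(sub), dim(sub))
    binF[b] <- sub[w]
    binz[b] <- fes$z[w[2L]]
  }
  ref_bin <- first_local_min_(binF)
  ref <- binF[ref_bin]
  out <- tibble(
    bin = seq_len(n_bins),
    s_hat_center = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
    z_at_min = binz,
    F = binF - ref
  )
  attr(out, "reference") <- ref
  attr(out, "n_bins") <- n_bins
  class(out) <- c("mfep_profile", class(out))
  out
}

#' Step barriers along an MFEP profile
#'
#' Locates interior local maxima of the binned profile; each ascending
#' segment defines a step with `barrier` = maximum minus the preceding
#' minimum and `delta_F` = following minimum minus preceding minimum. The
#' rate-determining step is the one with the largest barrier.
#'
#' @param profile an `mfep_profile` (or a numeric free-energy profile).
#' @return Tibble with one row per step (`step`, `barrier_bin`, `barrier`,
#'   `delta_F`, kcal/mol) and attribute `rate_determining` (0 when the
#'   profile has no ascending segment).
#' @export
profile_barriers <- function(profile) {
  F <- if (is.numeric(profile)) profile else profile$F
  n <- length(F)
  maxima <- which(vapply(seq_len(n), function(i) {
    i > 1L && i < n && F[i] > F[i - 1L] && F[i] > F[i + 1L]
  }, TRUE))
  steps <- tibble(
    step = integer(), barrier_bin = integer(),
    barrier = numeric(), delta_F = numeric()
  )
  if (length(maxima) > 0L) {
    bounds <- c(1L, maxima, n)
    for (k in seq_along(maxima)) {
      m <- maxima[k]
      prec <- min(F[bounds[k]:m])
      foll <- min(F[m:bounds[k + 2L]])
      steps <- dplyr::bind_rows(steps, tibble(
        step = k, barrier_bin = m, barrier = F[m] - prec, delta_F = foll - prec
      ))
    }
  }
  attr(steps, "rate_determining") <- if (nrow(steps) > 0L) max(steps$barrier) else 0
  steps
}

#' Constant-final-bias unbiasing weights
#'
#' Weights proportional to `exp(+V_final(s_i, z_i) / kB T)`, treating the
#' final bias (deposited hills plus the static wall) as constant throughout
#' the run; a max-shift guards the exponentiation and weights are
#' normalised to sum to one.
#'
#' @param cv_log tibble with `s` and `z` columns (e.g. a `metad_run`'s
#'   `cv_log`).
#' @param final_bias the `bias_potential` at the end of the run.
#' @param temperature K.
#' @return Numeric weights summing to 1, one per log row.
#' @export
reweight_series <- function(cv_log, final_bias, temperature = 300) {
  if (nrow(cv_log) == 0L) abort("empty CV log")
  z <- if ("z" %in% names(cv_log)) cv_log$z else rep(0, nrow(cv_log))
  v <- bias_on_points_(final_bias, cv_log$s, z, include_wall = TRUE)
  a <- v / (.kB * temperature)
  w <- exp(a - max(a))
  w / sum(w)
}

#' Weighted block standard error of a series mean
#'
#' Splits the series into contiguous blocks (dropping the remainder),
#' computes the weighted mean per block, and reports the standard error of
#' the block means for each block size. For correlated data the curve grows
#' with block size until the blocks exceed the correlation time, where it
#' plateaus at the true standard error of the mean.
#'
#' @param x numeric series.
#' @param block_sizes integer block sizes (each at most `length(x)`).
#' @param weights optional per-sample weights (default uniform).
#' @return Tibble with `block_size`, `stderr`, `n_blocks`.
#' @export
block_stderr <- function(x, block_sizes = seq(10L, 500L, by = 10L),
                         weights = NULL) {
  m <- length(x)
  if (any(block_sizes > m)) abort("block size exceeds sample count")
  if (is.null(weights)) weights <- rep(1, m)
  out <- lapply(block_sizes, function(B) {
    nb <- m %/% B
    idx <- seq_len(nb * B)
    blk <- rep(seq_len(nb), each = B)
    wsum <- tapply(weights[idx], blk, sum)
    means <- tapply(weights[idx] * x[idx], blk, sum) / wsum
    tibble(
      block_size = B,
      stderr = if (nb >= 2L) sd(means) / sqrt(nb) else NA_real_,
      n_blocks = nb
    )
  })
  dplyr::bind_rows(out)
}

#' Block-averaging error of binned free energies
#'
#' Samples are discretised into `n_bins` equal bins on s_hat. For each
#' block size the weighted bin population is computed per contiguous block;
#' the free-energy error per bin is `kB T` times the standard error of the
#' block populations divided by their mean, and the mean over occupied bins
#' is reported (unoccupied bins are excluded, not counted as zero).
#'
#' @param cv_log tibble with an `s_hat` column (falls back to rescaling
#'   `s`), e.g. a `metad_run`'s `cv_log`.
#' @param weights per-sample unbiasing weights from [reweight_series()]
#'   (default uniform).
#' @param n_bins number of s_hat bins (default 25).
#' @param block_sizes block sizes to scan (default 10 to 500 in steps of
#'   10).
#' @param temperature K.
#' @return An object of class `block_error_scan`: tibble with `block_size`,
#'   `mean_error` (kcal/mol), `n_blocks`, `n_occupied`.
#' @export
block_error_scan <- function(cv_log, weights = NULL, n_bins = 25L,
                             block_sizes = seq(10L, 500L, by = 10L),
                             temperature = 300) {
  s_hat <- if ("s_hat" %in% names(cv_log) && !all(is.na(cv_log$s_hat))) {
    cv_log$s_hat
  } else {
    s <- cv_log$s
    (s - min(s)) / max(max(s) - min(s), .Machine$double.eps)
  }
  m <- length(s_hat)
  if (any(block_sizes > m)) abort("block size exceeds sample count")
  if (is.null(weights)) weights <- rep(1 / m, m)
  bins <- pmin(pmax(floor(s_hat * n_bins) + 1L, 1L), n_bins)
  kT <- .kB * temperature / .kcal # kcal/mol
  out <- lapply(block_sizes, function(B) {
    nb <- m %/% B
    if (nb < 2L) {
      return(tibble(
        block_size = B, mean_error = NA_real_, n_blocks = nb,
        n_occupied = NA_integer_
      ))
    }
    idx <- seq_len(nb * B)
    blk <- rep(seq_len(nb), each = B)
    wblk <- tapply(weights[idx], blk, sum)
    pop <- matrix(0, nb, n_bins)
    agg <- tapply(weights[idx], list(blk, bins[idx]), sum)
    pop[, as.integer(colnames(agg))] <- ifelse(is.na(agg), 0, agg)
    pop <- pop / as.vector(wblk)
    mean_p <- colMeans(pop)
    occupied <- which(mean_p > 0)
    err <- vapply(occupied, function(k) {
      kT * (sd(pop[, k]) / sqrt(nb)) / mean_p[k]
    }, 0)
    tibble(
      block_size = B, mean_error = mean(err), n_blocks = nb,
      n_occupied = length(occupied)
    )
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("block_error_scan", class(res))
  res
}

#' Basin free-energy difference on a 1D surface
#'
#' Boltzmann-integrates `exp(-F/kB T)` over the two sides of `split` and
#' returns the right-minus-left basin free-energy difference.
#'
#' @param fes a `fes1d` (kcal/mol) or list with `x` and `F`.
#' @param split dividing point between the basins.
#' @param temperature K.
#' @return Delta F in kcal/mol.
#' @export
fes_delta_f <- function(fes, split, temperature = 300) {
  kT <- .kB * temperature / .kcal
  basin <- function(side) {
    i <- if (side == "left") which(fes$x <= split) else which(fes$x >= split)
    x <- fes$x[i]
    p <- exp(-fes$F[i] / kT)
    -kT * log(sum((p[-1] + p[-length(p)]) / 2 * diff(x)))
  }
  basin("right") - basin("left")
}

#' Barrier between the two basins of a 1D surface
#'
#' @inheritParams fes_delta_f
#' @return `F` at the maximum between the two basin minima minus `F` at the
#'   left minimum, kcal/mol.
#' @export
fes_barrier <- function(fes, split) {
  left <- which(fes$x <= split)
  right <- which(fes$x >= split)
  i1 <- left[which.min(fes$F[left])]
  i2 <- right[which.min(fes$F[right])]
  max(fes$F[i1:i2]) - fes$F[i1]
}
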