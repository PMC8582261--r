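# FES reconstruction, MFEP extraction, step-barrier decomposition,
# reweighting, and block-averaging error estimation.

test_that("the FES is the rescaled negative bias, invariant to constant shifts", {
  p <- metad_params(gamma = 30, sigma_s = 1, sigma_z = 0.3)
  b <- bias_potential(p, dim = 2L, n_path_frames = 26L)
  b$hills <- tibble::tibble(
    time = 1, center_s = 13, center_z = 1, sigma_s = 1, sigma_z = 0.3,
    height = 2
  )
  fes <- fes_from_bias(b,
    s_grid = seq(0, 1, length.out = 51),
    z_grid = seq(0, 2, length.out = 41)
  )
  # minimum at the hill centre: s_hat = 12/25
  w <- arrayInd(which.min(fes$F), dim(fes$F))
  expect_equal(fes$s_hat[w[1]], 12 / 25, tolerance = 0.021)
  expect_equal(fes$z[w[2]], 1, tolerance = 0.026)
  expect_equal(min(fes$F), 0)
  # pointwise closed form: F = (gamma/(gamma-1)) * h * (max gauss - gauss)
  s_raw <- 1 + fes$s_hat * 25
  gauss <- outer(s_raw, fes$z, function(s, z) {
    2 * exp(-(s - 13)^2 / 2 - (z - 1)^2 / (2 * 0.09))
  })
  want <- (30 / 29) * (max(gauss) - gauss) / 4.184
  expect_equal(fes$F, want, tolerance = 1e-10)

  # adding a constant to all hills only shifts the reference
  b2 <- b
  b2$hills <- dplyr::bind_rows(b2$hills, tibble::tibble(
    time = 2, center_s = 13, center_z = 1, sigma_s = 1e4, sigma_z = 1e4,
    height = 5
  ))
  fes2 <- fes_from_bias(b2,
    s_grid = seq(0, 1, length.out = 51),
    z_grid = seq(0, 2, length.out = 41)
  )
  expect_equal(fes2$F, fes$F, tolerance = 1e-6)
  # empty bias is an error
  expect_error(fes_from_bias(bias_potential(p, dim = 2L)), "empty bias")
})

test_that("MFEP extraction recovers an analytic curved valley", {
  cv <- make_analytic_fes("curved_valley_2d")
  fes <- cv$on_grid(n_s = 201, n_z = 161, z_lim = c(0, 3))
  prof <- extract_mfep(fes, n_bins = 25)
  expect_equal(nrow(prof), 25L)
  dz <- diff(fes$z)[1]
  edges <- seq(0, 1, length.out = 26)
  # within each bin the analytic minimiser (over the same s_hat grid) is
  # where the 1D profile is lowest; the recovered z must be the valley there
  # to within one z grid step
  for (b in seq_len(25)) {
    inbin <- which(fes$s_hat >= edges[b] - 1e-12 &
      (fes$s_hat < edges[b + 1] | b == 25))
    sstar <- fes$s_hat[inbin][which.min(cv$profile(fes$s_hat[inbin]))]
    expect_lt(abs(prof$z_at_min[b] - cv$valley(sstar)), dz + 1e-9)
  }
  # profile check: referenced profiles agree within discretisation error
  ref <- attr(prof, "reference")
  shift <- min(vapply(seq_len(25), function(b) {
    inbin <- which(fes$s_hat >= edges[b] - 1e-12 &
      (fes$s_hat < edges[b + 1] | b == 25))
    min(cv$profile(fes$s_hat[inbin]))
  }, 0))
  for (b in seq_len(25)) {
    inbin <- which(fes$s_hat >= edges[b] - 1e-12 &
      (fes$s_hat < edges[b + 1] | b == 25))
    want <- min(cv$profile(fes$s_hat[inbin])) - shift
    expect_lt(abs(prof$F[b] - want), cv$params$kappa * dz^2 + 1e-6)
  }
  # bin minimum is a true minimum over the grid nodes inside the bin
  for (b in c(1, 7, 25)) {
    inbin <- which(fes$s_hat >= edges[b] - 1e-12 &
      (fes$s_hat < edges[b + 1] | b == 25))
    expect_lte(prof$F[b] + ref, min(fes$F[inbin, ]) + 1e-9)
  }
})

test_that("a z-independent surface reduces the MFEP to the binned 1D minimum", {
  s <- seq(0, 1, length.out = 101)
  z <- seq(0, 2, length.out = 21)
  F1 <- 3 * (s - 0.3)^2
  fes <- structure(
    list(s_hat = s, z = z, F = matrix(F1, 101, 21) - min(F1)),
    class = "fes2d"
  )
  prof <- extract_mfep(fes, n_bins = 25)
  for (b in c(2, 10, 20)) {
    inbin <- which(s >= (b - 1) / 25 - 1e-12 & s < b / 25)
    expect_equal(prof$F[b] + attr(prof, "reference"), min(fes$F[inbin, 1]),
      tolerance = 1e-12
    )
  }
  # a grid too coarse for the requested bins is an error
  coarse <- structure(
    list(
      s_hat = seq(0, 1, length.out = 11), z = z,
      F = matrix(0, 11, 21)
    ),
    class = "fes2d"
  )
  expect_error(extract_mfep(coarse, n_bins = 25), "refine")
})

test_that("step decomposition recovers designed barriers exactly", {
  fx <- make_analytic_fes("three_step_profile",
    params = list(b1 = 13.8, b2 = 7.5, drop = 3.4)
  )
  steps <- profile_barriers(fx$profile)
  expect_equal(nrow(steps), 2L)
  expect_equal(steps$barrier, fx$truth$barriers, tolerance = 1e-12)
  expect_equal(steps$delta_F, fx$truth$net, tolerance = 1e-12)
  expect_equal(attr(steps, "rate_determining"), 13.8, tolerance = 1e-12)
  expect_equal(steps$barrier_bin, fx$truth$barrier_bins)

  # monotone decreasing profile: no steps, rate-determining barrier 0
  none <- profile_barriers(seq(5, 0, length.out = 25))
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "rate_determining"), 0)

  # single-max profile: one step, barrier = max - F(first bin)
  single <- c(seq(0, 6, length.out = 10), seq(5.5, -2, length.out = 15))
  st <- profile_barriers(single)
  expect_equal(nrow(st), 1L)
  expect_equal(st$barrier, 6)
})

test_that("reweighting inverts a known biased distribution", {
  p <- metad_params(gamma = 30)
  # zero bias -> uniform weights
  b0 <- bias_potential(p, dim = 1L)
  log0 <- tibble::tibble(s = rnorm(40), z = 0)
  expect_equal(reweight_series(log0, b0), rep(1 / 40, 40))

  # one sample with V = kB T ln 2 has twice the weight of the others
  kT <- kB() * 300
  b1 <- bias_potential(p, dim = 1L)
  b1$hills <- tibble::tibble(
    time = 0, center_s = 0, center_z = 0, sigma_s = 0.1, sigma_z = 0.1,
    height = kT * log(2)
  )
  log1 <- tibble::tibble(s = c(0, 5, 5, 5), z = 0)
  w <- reweight_series(log1, b1, temperature = 300)
  expect_equal(w[1] / w[2], 2, tolerance = 1e-9)

  # sampling oracle: draw from the biased density exp(-(U + V)/kT) on a
  # grid, reweight by exp(+V/kT), compare to the unbiased density
  set.seed(8)
  xg <- seq(-3, 3, length.out = 61)
  U <- 0.5 * 4 * xg^2 / 10 # kJ/mol
  Vb <- 3 * exp(-xg^2 / 0.5) # a bias lump at the origin
  pb <- exp(-(U + Vb) / kT)
  pb <- pb / sum(pb)
  idx <- sample(seq_along(xg), 2e4, replace = TRUE, prob = pb)
  bias <- bias_potential(p, dim = 1L)
  bias$hills <- tibble::tibble(
    time = 0, center_s = 0, center_z = 0, sigma_s = 0.5, sigma_z = 0.1,
    height = 3
  )
  logd <- tibble::tibble(s = xg[idx], z = 0)
  w2 <- reweight_series(logd, bias, temperature = 300)
  # V of the hill: 3*exp(-x^2/(2*0.25)) = 3*exp(-x^2/0.5): matches Vb
  est <- vapply(split(w2, idx), sum, 0)
  dens <- exp(-U / kT)
  dens <- dens / sum(dens)
  hit <- as.integer(names(est))
  # multinomial 3 sigma check on the well-populated cells
  big <- hit[dens[hit] > 0.01]
  for (k in big) {
    p_true <- dens[k]
    se <- sqrt(p_true * (1 - p_true) / 2e4) * 3 + 0.15 * p_true
    expect_lt(abs(est[as.character(k)] - p_true), se + 0.01)
  }
})

test_that("block standard error plateaus at the analytic AR(1) value", {
  ar <- make_ar1_series(60000, rho = 0.9, sigma = 1, seed = 3)
  scan <- block_stderr(ar$series, block_sizes = seq(10, 500, by = 10))
  plateau <- mean(scan$stderr[scan$block_size >= 300])
  expect_lt(abs(plateau - ar$sem) / ar$sem, 0.2)
  # small blocks underestimate the error for positively correlated data
  expect_lt(scan$stderr[1], plateau)

  # i.i.d. data: flat curve at sigma/sqrt(n)
  iid <- make_ar1_series(60000, rho = 0, sigma = 2, seed = 4)
  scan0 <- block_stderr(iid$series, block_sizes = seq(10, 500, by = 10))
  expect_lt(diff(range(scan0$stderr)) / mean(scan0$stderr), 0.35)
  expect_lt(abs(mean(scan0$stderr) - iid$sem) / iid$sem, 0.2)

  expect_error(block_stderr(rnorm(50), block_sizes = 100), "exceeds")
})

test_that("binned free-energy errors scale like sigma/sqrt(n_blocks) for i.i.d. samples", {
  set.seed(5)
  m <- 20000
  logd <- tibble::tibble(s_hat = runif(m), s = runif(m))
  scan <- block_error_scan(logd,
    n_bins = 25,
    block_sizes = seq(10, 500, by = 10)
  )
  expect_s3_class(scan, "block_error_scan")
  # flat in block size for independent samples (within 25%)
  expect_lt(diff(range(scan$mean_error)) / mean(scan$mean_error), 0.5)
  # closed form: per-bin relative error of a multinomial population
  # p = 1/25: kT * sqrt((1-p)/(p*m)) in kcal/mol
  kT <- kB() * 300 / 4.184
  p <- 1 / 25
  want <- kT * sqrt((1 - p) / (p * m))
  expect_equal(mean(scan$mean_error), want, tolerance = 0.2)
  expect_error(block_error_scan(logd, block_sizes = m + 1), "exceeds")
})

test_that("error curves are non-decreasing to a plateau for correlated CV logs", {
  ar <- make_ar1_series(30000, rho = 0.95, sigma = 1, seed = 11)
  s_hat <- stats::pnorm(ar$series) # monotone map into [0, 1]
  logd <- tibble::tibble(s_hat = s_hat, s = s_hat)
  scan <- block_error_scan(logd, block_sizes = seq(10, 500, by = 10))
  sm <- scan$mean_error
  # averaged over the scan, the curve rises then flattens
  expect_gt(mean(sm[scan$block_size >= 300]), 1.3 * sm[1])
  late <- sm[scan$block_size >= 200]
  expect_lt(stats::sd(late) / mean(late), 0.25)
})
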