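test_that("amplitude filtering is inclusive at the threshold", {
  ae <- ae_series(c(10, 20, 30), c(44.9, 45.0, 60))
  expect_message(f <- filter_hits(ae), "kept 2 of 3")
  expect_equal(nrow(f$hits), 2)
  expect_equal(f$hits$amplitude_db, c(45, 60))
  # threshold 0 is the identity
  expect_equal(suppressMessages(filter_hits(ae, 0))$hits, ae$hits)
  # large stream agrees with a linear-scan count
  big <- poisson_hits(1000, 120, seed = 21)
  kept <- suppressMessages(filter_hits(big, 50))
  expect_equal(nrow(kept$hits), sum(big$hits$amplitude_db >= 50))
})

test_that("activity is hits per minute in a centered truncated window", {
  # one hit per minute -> exactly 1 hit/min at every grid point, interior
  # and boundary alike (truncation divides by the actual width)
  ae <- uniform_hits(60)
  r <- compute_rate_series(ae)
  expect_equal(r$grid_times_min, 0:60)
  expect_true(all(abs(r$raw_rate[9:53] - 1) < 1e-12))
  # no hits -> identically zero
  none <- ae_series(numeric(0), numeric(0), t_end_s = 3600)
  expect_warning(r0 <- compute_rate_series(none), "no hits")
  expect_true(all(r0$raw_rate == 0))
  # recording shorter than the window
  short <- ae_series(c(60, 120), c(50, 50), t_end_s = 300)
  expect_error(compute_rate_series(short), "shorter window")
})

test_that("rate computation matches the brute-force counting oracle", {
  for (seed in c(4, 17, 99)) {
    ae <- poisson_hits(500, 200, seed = seed)
    r <- compute_rate_series(ae)
    idx <- seq(10, 190, by = 9)  # 21 interior grid points
    expect_equal(r$raw_rate[idx + 1], rate_oracle(ae, idx, 15),
                 tolerance = 1e-12)
  }
})

test_that("window averaging conserves total hit count on the interior", {
  # every hit far from the boundaries falls in exactly window_min
  # one-minute-spaced windows, so summed window counts = 15 * n_hits
  set.seed(8)
  tt <- runif(300, 50 * 60, 150 * 60)  # keep hits away from edges
  ae <- ae_series(tt, rep(60, 300), t_end_s = 200 * 60)
  r <- compute_rate_series(ae)
  counts <- r$raw_rate * 15  # interior windows have full width
  expect_equal(sum(counts[r$grid_times_min >= 8 &
                            r$grid_times_min <= 192]),
               15 * 300)
})

test_that("Savitzky-Golay smoothing preserves polynomials up to its order", {
  r <- compute_rate_series(uniform_hits(120))
  # constants are reproduced exactly
  r$raw_rate <- rep(3.7, length(r$raw_rate))
  expect_equal(smooth_rates(r)$smoothed_rate, r$raw_rate,
               tolerance = 1e-10)
  # a degree-5 polynomial passes through unchanged
  tt <- r$grid_times_min / 60
  r$raw_rate <- 5 + tt + 0.5 * tt^3 + 0.1 * tt^5
  expect_equal(smooth_rates(r, 5, 7)$smoothed_rate, r$raw_rate,
               tolerance = 1e-8)
  expect_error(smooth_rates(r, sg_order = 5, sg_window = 6), "odd")
  short <- compute_rate_series(uniform_hits(16))
  expect_error(smooth_rates(short, 5, 21), "shorter")
})

test_that("smoothing a delta spike matches the convolution-weight oracle", {
  r <- compute_rate_series(uniform_hits(60))
  raw <- rep(0, length(r$raw_rate))
  raw[30] <- 10
  r$raw_rate <- raw
  sm <- smooth_rates(r, 5, 7)$smoothed_rate
  # oracle: central SG kernel row applied as a convolution, then the same
  # flooring at zero; valid on the interior (away from edge transients)
  kern <- signal::sgolay(p = 5, n = 7)[4, ]
  conv <- stats::filter(raw, rev(kern), sides = 2)
  interior <- 5:57
  expect_equal(sm[interior], pmax(as.numeric(conv[interior]), 0),
               tolerance = 1e-10)
  # the kernel is total-preserving before flooring
  expect_equal(sum(as.numeric(conv[interior])), 10, tolerance = 1e-10)
})

test_that("the activity peak is located with an earliest-tie rule", {
  r <- compute_rate_series(uniform_hits(120))
  n <- length(r$raw_rate)
  tri <- pmax(0, 20 - abs(r$grid_times_min - 40))
  r$smoothed_rate <- tri
  r$sg_order <- 5L; r$sg_window <- 7L
  expect_equal(find_max_rate_time(r), 40)
  # two equal maxima: earliest wins
  two <- rep(0, n); two[c(31, 91)] <- 5
  r$smoothed_rate <- two
  expect_equal(find_max_rate_time(r), 30)
  r$smoothed_rate <- rep(0, n)
  expect_error(find_max_rate_time(r), "no acoustic activity")
  # randomized streams agree with an exhaustive argmax oracle
  for (seed in c(2, 5)) {
    set.seed(seed)
    r$smoothed_rate <- runif(n)
    expect_equal(find_max_rate_time(r),
                 r$grid_times_min[which.max(r$smoothed_rate)])
  }
})

test_that("Psi interpolation is linear, bracketed and QC-flagged", {
  psi <- psi_series(c(0, 100) * 60, c(-1.0, -3.0))
  out <- interpolate_psi(psi, 50)
  expect_equal(out$psi_mpa, -2.0)
  expect_false(out$qc_within_tol)  # 1.0 MPa from the nearest reading
  expect_equal(nrow(out$bracketing), 2)
  # coinciding with a reading returns it exactly
  at0 <- interpolate_psi(psi, 0)
  expect_equal(at0$psi_mpa, -1.0)
  expect_true(at0$qc_within_tol)
  expect_error(interpolate_psi(psi, 101), "outside")
  expect_error(interpolate_psi(psi, -1), "outside")

  # dense readings on a smooth trajectory: matches approx() and QC passes
  tt <- seq(0, 300, by = 10)
  vals <- -0.3 - 0.01 * tt - 1e-5 * tt^2
  dense <- psi_series(tt * 60, vals)
  set.seed(12)
  for (t in runif(20, 1, 299)) {
    out <- interpolate_psi(dense, t)
    expect_equal(out$psi_mpa,
                 stats::approx(tt, vals, xout = t)$y, tolerance = 1e-12)
    expect_true(out$qc_within_tol)
    expect_true(out$psi_mpa <= max(out$bracketing$psi_mpa) &&
                  out$psi_mpa >= min(out$bracketing$psi_mpa))
  }
})

test_that("Pmaxrate is Psi-shift equivariant and time-rescale invariant", {
  cfg <- sim_config(seed = 31, noise_rate_max = 0, trajectory = "linear",
                    n_conduits = 4000)
  sim <- simulate_dehydration(cfg)
  base <- suppressMessages(estimate_pmaxrate(sim$ae, sim$psi))

  shifted <- sim$psi
  shifted$psi_mpa <- shifted$psi_mpa - 1.0
  res_sh <- suppressMessages(estimate_pmaxrate(sim$ae, shifted))
  expect_equal(res_sh$pmaxrate_mpa, base$pmaxrate_mpa - 1.0,
               tolerance = 1e-10)
  expect_equal(res_sh$t_max_min, base$t_max_min)

  # doubling all times (slower drying, same Psi course) leaves Pmaxrate
  # unchanged up to grid resolution
  ae2 <- ae_series(sim$ae$hits$time_s * 2, sim$ae$hits$amplitude_db,
                   sample_id = sim$ae$sample_id,
                   t_end_s = sim$ae$t_end_s * 2)
  psi2 <- psi_series(sim$psi$time_s * 2, sim$psi$psi_mpa)
  res2 <- suppressMessages(estimate_pmaxrate(ae2, psi2))
  expect_equal(res2$pmaxrate_mpa, base$pmaxrate_mpa, tolerance = 0.1)
})

test_that("a late low-amplitude noise burst does not move the peak", {
  cfg_clean <- sim_config(seed = 77, noise_rate_max = 0,
                          trajectory = "linear", n_conduits = 5000)
  cfg_noisy <- sim_config(seed = 77, trajectory = "linear",
                          n_conduits = 5000)  # default late-stage noise
  clean <- simulate_dehydration(cfg_clean)
  noisy <- simulate_dehydration(cfg_noisy)
  expect_gt(noisy$truth$n_noise_hits, 0)
  r_clean <- suppressMessages(estimate_pmaxrate(clean$ae, clean$psi))
  r_noisy <- suppressMessages(estimate_pmaxrate(noisy$ae, noisy$psi))
  expect_lte(abs(r_noisy$t_max_min - r_clean$t_max_min), 1)
})

test_that("pipeline errors carry their stage name", {
  ae <- ae_series(c(10, 20), c(40, 41), t_end_s = 3600)
  psi <- psi_series(c(0, 3600), c(-0.5, -3))
  expect_error(suppressMessages(estimate_pmaxrate(ae, psi)),
               "\\[filter\\].*45 dB")
})
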