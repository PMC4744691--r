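test_that("the reparameterized Weibull pins PLC and slope at Px", {
  for (x in c(12, 50, 88)) {
    expect_equal(weibull_plc(-3.5, -3.5, 30, x), x, tolerance = 1e-12)
  }
  expect_equal(weibull_plc(0, -3.5, 30), 0)
  # slope at Px equals Sx: finite-difference oracle in tension magnitude
  for (par in list(c(-3.5, 30), c(-1.8, 55), c(-6.4, 12))) {
    h <- 1e-6
    num <- (weibull_plc(par[1] - h, par[1], par[2]) -
              weibull_plc(par[1] + h, par[1], par[2])) / (2 * h)
    expect_equal(num, par[2], tolerance = 1e-6)
  }
  # strictly increasing with tension magnitude
  psi <- seq(-0.1, -10, by = -0.1)
  expect_true(all(diff(weibull_plc(psi, -3.5, 30)) > 0))
  expect_error(weibull_plc(1, -3.5, 30), "signed")
  expect_error(weibull_plc(-1, -3.5, -1), "sx")
  expect_error(weibull_plc(-1, -3.5, 30, x = 100), "x must")
})

test_that("Px/Sx and classic b/c parameterizations are equivalent", {
  set.seed(6)
  for (i in 1:20) {
    px <- -runif(1, 0.5, 8); sx <- runif(1, 5, 120)
    x <- sample(c(12, 50, 88), 1)
    cl <- weibull_to_classic(px, sx, x)
    back <- classic_to_weibull(cl$b, cl$c, x)
    expect_equal(back$px_mpa, px, tolerance = 1e-9)
    expect_equal(back$sx, sx, tolerance = 1e-9)
    # both forms give the same curve
    psi <- seq(-0.5, -9, length.out = 30)
    expect_equal(weibull_plc(psi, px, sx, x),
                 100 * (1 - exp(-(abs(psi) / cl$b)^cl$c)),
                 tolerance = 1e-9)
  }
})

test_that("noiseless vulnerability data are refit exactly", {
  psi <- seq(-0.5, -7, length.out = 12)
  d <- data.frame(psi_mpa = psi,
                  plc_percent = weibull_plc(psi, -3.5, 30))
  f <- fit_vulnerability(d)
  expect_equal(f$px_mpa, -3.5, tolerance = 1e-6)
  expect_equal(f$sx, 30, tolerance = 1e-5)
  expect_lt(f$residual_sse, 1e-8)
  # PLC(Px) = x exactly under the fitted model, and the curve is monotone
  expect_equal(weibull_plc(f$px_mpa, f$px_mpa, f$sx, f$x), f$x)
  curve <- weibull_plc(seq(-0.1, -10, by = -0.1), f$px_mpa, f$sx)
  expect_true(all(diff(curve) > 0))
})

test_that("noisy fits recover the generating P50", {
  d <- simulate_hydraulic_dataset(sim_config(seed = 14), n_per_level = 4,
                                  plc_noise_sd = 5)
  f <- fit_vulnerability(d)
  expect_lt(abs(f$px_mpa - (-3.5)), 0.15)
  # RMSE shrinks as replication grows (8 seeds each)
  err <- function(nrep) {
    vapply(1:8, function(s) {
      di <- simulate_hydraulic_dataset(sim_config(seed = 100 + s),
                                       n_per_level = nrep)
      fit_vulnerability(di)$px_mpa + 3.5
    }, numeric(1))
  }
  expect_lt(sqrt(mean(err(8)^2)), sqrt(mean(err(1)^2)))
})

test_that("degenerate vulnerability designs are flagged", {
  shallow <- data.frame(psi_mpa = seq(-0.2, -1, length.out = 6),
                        plc_percent = c(0, 1, 0, 2, 1, 3))
  expect_warning(try(fit_vulnerability(shallow), silent = TRUE),
                 "bracket")
  expect_error(fit_vulnerability(data.frame(psi_mpa = -1:-3,
                                            plc_percent = c(1, 2, 3))),
               "at least 4")
})

test_that("psi_at_plc inverts the fitted curve", {
  psi <- seq(-0.5, -7, length.out = 12)
  f <- fit_vulnerability(data.frame(
    psi_mpa = psi, plc_percent = weibull_plc(psi, -3.5, 30)))
  p12 <- psi_at_plc(f, 12); p88 <- psi_at_plc(f, 88)
  expect_equal(weibull_plc(p12, f$px_mpa, f$sx), 12, tolerance = 1e-9)
  expect_equal(weibull_plc(p88, f$px_mpa, f$sx), 88, tolerance = 1e-9)
  expect_true(p88 < f$px_mpa && f$px_mpa < p12)
  expect_equal(psi_at_plc(f, 50), f$px_mpa, tolerance = 1e-9)
})

test_that("bootstrap CIs are deterministic under seed and collapse at zero noise", {
  psi <- seq(-0.5, -7, length.out = 12)
  clean <- data.frame(psi_mpa = psi,
                      plc_percent = weibull_plc(psi, -3.5, 30))
  f0 <- bootstrap_ci(clean, n_boot = 49, seed = 9)
  expect_lt(f0$ci_hi - f0$ci_lo, 1e-6)
  expect_equal(f0$ci_lo, f0$px_mpa, tolerance = 1e-6)

  noisy <- simulate_hydraulic_dataset(sim_config(seed = 2))
  a <- bootstrap_ci(noisy, n_boot = 99, seed = 4)
  b <- bootstrap_ci(noisy, n_boot = 99, seed = 4)
  expect_identical(attr(a, "boot_px"), attr(b, "boot_px"))
  expect_identical(c(a$ci_lo, a$ci_hi), c(b$ci_lo, b$ci_hi))
  expect_true(a$ci_lo <= a$px_mpa && a$px_mpa <= a$ci_hi)
  expect_equal(a$method, "pooled_bootstrap")
})

test_that("mean_ci implements mean +/- 1.96 SE with the n < 3 rule", {
  # values constructed to have mean 0 and SE exactly 1
  a <- sqrt(3)
  z <- mean_ci(c(a, a, -a, -a))
  expect_equal(z$mean, 0)
  expect_equal(z$se, 1)
  expect_equal(c(z$ci_lo, z$ci_hi), c(-1.96, 1.96))
  # hand-computed case
  h <- mean_ci(c(1, 2, 3))
  expect_equal(h$mean, 2)
  expect_equal(h$se, 0.57735, tolerance = 1e-4)
  expect_equal(c(h$ci_lo, h$ci_hi), c(0.8684, 3.1316), tolerance = 1e-3)
  # no CI below n = 3
  two <- mean_ci(c(-2.5, -2.56))
  expect_equal(two$mean, -2.53)
  expect_true(is.na(two$ci_lo) && is.na(two$ci_hi))
  expect_error(mean_ci(numeric(0)), "no non-missing")
})

test_that("per-sample fits aggregate by mean with a normal-theory CI", {
  mk <- function(px) {
    psi <- seq(-0.5, -7, length.out = 12)
    fit_vulnerability(data.frame(psi_mpa = psi,
                                 plc_percent = weibull_plc(psi, px, 30)))
  }
  same <- aggregate_fits(list(mk(-3.5), mk(-3.5), mk(-3.5)))
  expect_equal(same$px_mpa, -3.5, tolerance = 1e-6)
  expect_lt(same$ci_hi - same$ci_lo, 1e-5)

  agg <- aggregate_fits(list(mk(-3.0), mk(-3.5), mk(-4.0)))
  expect_equal(agg$px_mpa, -3.5, tolerance = 1e-6)
  se <- 0.5 / sqrt(3)
  expect_equal(agg$ci_lo, -3.5 - 1.96 * se, tolerance = 1e-4)
  expect_equal(agg$ci_hi, -3.5 + 1.96 * se, tolerance = 1e-4)
  expect_equal(agg$method, "per_sample_mean")

  two <- aggregate_fits(list(mk(-3.0), mk(-4.0)))
  expect_true(is.na(two$ci_lo))
})
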