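# Synthetic dehydration experiments with known ground truth.
#
# The generative model mirrors how AE arises during benchtop drying:
# each cavitation-capable conduit carries a tension threshold drawn from
# the distribution implied by the species' vulnerability curve (the PLC
# curve, scaled to [0,1], IS the threshold CDF), and emits exactly one
# hit when the declining water potential first crosses its threshold.
# A second, non-cavitation AE source switches on late in dehydration
# (fibre and ray cavitation, shrinkage microfractures) and is modeled as
# an inhomogeneous Poisson process with a logistic onset in Psi.

#' Configuration for the dehydration simulator
#'
#' Collects the generative parameters of a simulated benchtop-drying
#' experiment. Defaults describe a mid-range temperate angiosperm drying
#' over roughly a day.
#'
#' @param p50_true_mpa,sx_true Generating Weibull vulnerability parameters
#'   (signed P50, slope in % per MPa at P50).
#' @param n_conduits Number of cavitation-capable conduits; each emits
#'   one hit.
#' @param psi0_mpa,psi_min_mpa Initial water potential and the asymptotic
#'   (driest) value of the trajectory, signed MPa.
#' @param tau_min Time constant (minutes) of the exponential-plateau
#'   trajectory `Psi(t) = psi_min + (psi0 - psi_min) * exp(-t / tau)`.
#' @param trajectory `"exponential"` (drying decelerates, the default for
#'   benchtop experiments) or `"linear"` (constant-rate decline from
#'   `psi0_mpa`, used for analytic checks).
#' @param rate_mpa_per_min Drying rate for the linear trajectory
#'   (positive; MPa of tension gained per minute).
#' @param noise_rate_max Asymptotic late-stage noise intensity, hits/min.
#'   Set 0 to disable the noise source.
#' @param noise_onset_mpa Signed Psi at which the noise intensity reaches
#'   half its maximum.
#' @param noise_width_mpa Width (MPa) of the logistic onset.
#' @param amp_mean_db,amp_sd_db Hit amplitude model: Normal, truncated to
#'   `[35, 99]` dB.
#' @param psi_reading_interval_min Interval between simulated
#'   pressure-chamber readings, minutes.
#' @param psi_reading_sd_mpa Gaussian reading noise, MPa.
#' @param t_end_min Recording duration in minutes, or NULL to run until
#'   the trajectory has crossed the 99th percentile of the threshold
#'   distribution (plus a margin of one reading interval).
#' @param seed Optional integer seed; fixed seeds give bit-identical
#'   output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(p50_true_mpa = -3.5, sx_true = 30,
                       n_conduits = 5000,
                       psi0_mpa = -0.3, psi_min_mpa = -9, tau_min = 1200,
                       trajectory = c("exponential", "linear"),
                       rate_mpa_per_min = 0.005,
                       noise_rate_max = 2, noise_onset_mpa = -6.5,
                       noise_width_mpa = 0.3,
                       amp_mean_db = 55, amp_sd_db = 10,
                       psi_reading_interval_min = 30,
                       psi_reading_sd_mpa = 0.05,
                       t_end_min = NULL, seed = NULL) {
  trajectory <- match.arg(trajectory)
  if (p50_true_mpa >= 0) stop("p50_true_mpa must be < 0 (signed)")
  if (sx_true <= 0) stop("sx_true must be > 0")
  if (!(psi_min_mpa < psi0_mpa && psi0_mpa <= 0))
    stop("need psi_min_mpa < psi0_mpa <= 0")
  if (tau_min <= 0) stop("tau_min must be > 0")
  if (n_conduits < 0) stop("n_conduits must be >= 0")
  if (noise_rate_max < 0 || noise_width_mpa <= 0 || rate_mpa_per_min <= 0)
    stop("rates and widths must be positive")
  structure(list(p50_true_mpa = p50_true_mpa, sx_true = sx_true,
                 n_conduits = n_conduits, psi0_mpa = psi0_mpa,
                 psi_min_mpa = psi_min_mpa, tau_min = tau_min,
                 trajectory = trajectory,
                 rate_mpa_per_min = rate_mpa_per_min,
                 noise_rate_max = noise_rate_max,
                 noise_onset_mpa = noise_onset_mpa,
                 noise_width_mpa = noise_width_mpa,
                 amp_mean_db = amp_mean_db, amp_sd_db = amp_sd_db,
                 psi_reading_interval_min = psi_reading_interval_min,
                 psi_reading_sd_mpa = psi_reading_sd_mpa,
                 t_end_min = t_end_min, seed = seed),
            class = "sim_config")
}

# signed Psi(t), t in minutes
.psi_traj <- function(cfg, t_min) {
  if (cfg$trajectory == "exponential") {
    cfg$psi_min_mpa + (cfg$psi0_mpa - cfg$psi_min_mpa) *
      exp(-t_min / cfg$tau_min)
  } else {
    pmax(cfg$psi_min_mpa, cfg$psi0_mpa - cfg$rate_mpa_per_min * t_min)
  }
}

# first time (minutes) at which tension magnitude reaches T; NA if never
.crossing_time <- function(cfg, T_mag) {
  m0 <- abs(cfg$psi0_mpa); mmin <- abs(cfg$psi_min_mpa)
  if (cfg$trajectory == "exponential") {
    # clamp the log argument: rows with T_mag >= mmin are NA'd anyway
    arg <- pmax((mmin - T_mag) / (mmin - m0), 1e-300)
    out <- ifelse(T_mag <= m0, 0,
                  ifelse(T_mag >= mmin, NA_real_,
                         -cfg$tau_min * log(arg)))
  } else {
    out <- ifelse(T_mag <= m0, 0,
                  ifelse(T_mag > mmin, NA_real_,
                         (T_mag - m0) / cfg$rate_mpa_per_min))
  }
  out
}

# truncated-normal draws via inverse CDF (deterministic under seed)
.rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Simulate a dehydration experiment
#'
#' Generates an AE hit stream and a sparse Psi series for one sample from
#' a [sim_config()], together with a ground-truth record. Cavitation hits
#' arise one per conduit at the first crossing of the conduit's tension
#' threshold (thresholds sampled by inverse CDF from the generating
#' vulnerability curve); late-stage noise hits come from an inhomogeneous
#' Poisson process with logistic onset in Psi, simulated by thinning;
#' amplitudes are truncated-normal.
#'
#' @param config A [sim_config()].
#' @return A list with `ae` ([ae_series]), `psi` ([psi_series]) and
#'   `truth`: generating parameters plus `threshold_mode_mpa` (the signed
#'   mode of the cavitation-threshold density — the Psi at which most
#'   cavitation occurs per unit tension, i.e. what a rate-based analysis
#'   under constant-rate drying should recover), `n_cavitation_hits`,
#'   `n_noise_hits` and `t_end_min`.
#' @examples
#' sim <- simulate_dehydration(sim_config(seed = 7))
#' sim$truth$threshold_mode_mpa
#' @export
simulate_dehydration <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cl <- weibull_to_classic(cfg$p50_true_mpa, cfg$sx_true, 50)
  # mode of the Weibull threshold density (c > 1: interior mode)
  mode_mag <- if (cl$c > 1) cl$b * ((cl$c - 1) / cl$c)^(1 / cl$c) else 0
  # recording duration: cover the 99th percentile of thresholds
  q99 <- cl$b * (-log(1 - 0.99))^(1 / cl$c)
  t99 <- .crossing_time(cfg, q99)
  if (is.na(t99))
    warning("incomplete dehydration: trajectory never reaches the 99th ",
            "percentile of cavitation thresholds")
  t_end <- cfg$t_end_min %||%
    ((if (is.na(t99)) .crossing_time(cfg, abs(cfg$psi_min_mpa) * 0.99) else
        t99) + cfg$psi_reading_interval_min)

  # cavitation hits: one per conduit at its threshold crossing.
  # Amplitudes are drawn per source immediately after its event times, so
  # the cavitation component is bit-identical whether or not the noise
  # source is switched on.
  t_cav <- numeric(0)
  amp_cav <- numeric(0)
  if (cfg$n_conduits > 0) {
    u <- stats::runif(cfg$n_conduits)
    thr <- cl$b * (-log(1 - u))^(1 / cl$c)
    t_cav <- .crossing_time(cfg, thr)
    t_cav <- t_cav[!is.na(t_cav) & t_cav <= t_end]
    amp_cav <- .rtnorm(length(t_cav), cfg$amp_mean_db, cfg$amp_sd_db,
                       35, 99)
  }

  # noise hits: thinning of a homogeneous process at noise_rate_max
  t_noise <- numeric(0)
  amp_noise <- numeric(0)
  if (cfg$noise_rate_max > 0) {
    n_cand <- stats::rpois(1, cfg$noise_rate_max * t_end)
    cand <- sort(stats::runif(n_cand, 0, t_end))
    lam <- cfg$noise_rate_max *
      stats::plogis((cfg$noise_onset_mpa - .psi_traj(cfg, cand)) /
                      cfg$noise_width_mpa)
    t_noise <- cand[stats::runif(n_cand) < lam / cfg$noise_rate_max]
    amp_noise <- .rtnorm(length(t_noise), cfg$amp_mean_db, cfg$amp_sd_db,
                         35, 99)
  }

  ae <- ae_series(c(t_cav, t_noise) * 60, c(amp_cav, amp_noise),
                  sample_id = "simulated", t_end_s = t_end * 60)

  t_read <- unique(c(seq(0, t_end, by = cfg$psi_reading_interval_min),
                     t_end))
  psi_read <- pmin(0, .psi_traj(cfg, t_read) +
                     stats::rnorm(length(t_read), 0,
                                  cfg$psi_reading_sd_mpa))
  psi <- psi_series(t_read * 60, psi_read,
                    se_mpa = rep(cfg$psi_reading_sd_mpa, length(t_read)))

  list(ae = ae, psi = psi,
       truth = list(p50_true_mpa = cfg$p50_true_mpa, sx_true = cfg$sx_true,
                    weibull_b = cl$b, weibull_c = cl$c,
                    threshold_mode_mpa = -mode_mag,
                    n_cavitation_hits = length(t_cav),
                    n_noise_hits = length(t_noise),
                    t_end_min = t_end))
}

#' Simulate a destructive hydraulic vulnerability dataset
#'
#' Emulates benchtop-drying reference data: PLC measured at a set of
#' target water potentials, with Gaussian measurement noise, generated
#' from the same vulnerability curve as the AE simulator.
#'
#' @param config A [sim_config()] (only the vulnerability parameters and
#'   seed are used).
#' @param psi_levels Signed target Psi levels (MPa); default 12 levels
#'   spanning the curve.
#' @param n_per_level Replicate measurements per level (default 4).
#' @param plc_noise_sd SD of the Gaussian PLC noise, percent (default 5).
#' @return A `vuln_table` data.frame with columns `psi_mpa` and
#'   `plc_percent` (clipped to `[0, 100]`).
#' @export
simulate_hydraulic_dataset <- function(config,
                                       psi_levels = seq(-0.5, -7,
                                                        length.out = 12),
                                       n_per_level = 4, plc_noise_sd = 5) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(psi_levels)) stop("psi_levels must be nonempty")
  if (!is.null(config$seed)) set.seed(config$seed)
  psi <- rep(psi_levels, each = n_per_level)
  plc <- weibull_plc(psi, config$p50_true_mpa, config$sx_true, 50)
  if (plc_noise_sd > 0)
    plc <- plc + stats::rnorm(length(plc), 0, plc_noise_sd)
  out <- data.frame(psi_mpa = psi, plc_percent = pmin(100, pmax(0, plc)))
  class(out) <- c("vuln_table", "data.frame")
  out
}

#' Simulate a species panel for the cross-method comparison
#'
#' Generates a species summary table with a known linear relation between
#' the acoustic and hydraulic vulnerability estimates, for end-to-end
#' testing of [compare_methods()]: per-species |P50| is uniform over a
#' range, and |Pmaxrate| = a * |P50| + b + Gaussian noise.
#'
#' @param n_species Number of species (>= 3).
#' @param p50_range Signed P50 range, e.g. `c(-6.4, -1.5)`.
#' @param a,b Offset-model coefficients in magnitude space.
#' @param noise_sd SD of the Pmaxrate noise, MPa.
#' @param seed Optional integer seed.
#' @return A `species_summary` data.frame (CIs are synthetic normal-theory
#'   intervals; sample sizes are drawn from 3-8).
#' @export
simulate_species_panel <- function(n_species = 18,
                                   p50_range = c(-6.4, -1.5),
                                   a = 1.19, b = -0.11, noise_sd = 0.5,
                                   seed = NULL) {
  if (n_species < 3) stop("n_species must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  p50_mag <- stats::runif(n_species, min(abs(p50_range)),
                          max(abs(p50_range)))
  pmax_mag <- a * p50_mag + b + stats::rnorm(n_species, 0, noise_sd)
  pmax_mag <- pmax(pmax_mag, 0.1)
  n_pmax <- sample(3:8, n_species, replace = TRUE)
  se <- stats::runif(n_species, 0.1, 0.3)
  out <- data.frame(species = sprintf("sim_species_%02d",
                                      seq_len(n_species)),
                    clade = "angiosperm",
                    p50_mpa = -p50_mag,
                    p50_ci_lo = -p50_mag - 1.96 * se,
                    p50_ci_hi = -p50_mag + 1.96 * se,
                    n_p50 = sample(3:5, n_species, replace = TRUE),
                    pmaxrate_mpa = -pmax_mag,
                    pmax_ci_lo = -pmax_mag - 1.96 * se,
                    pmax_ci_hi = -pmax_mag + 1.96 * se,
                    n_pmax = n_pmax)
  class(out) <- c("species_summary", "data.frame")
  out
}
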