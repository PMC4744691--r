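# Hydraulic vulnerability curves: reparameterized Weibull fitting, Px
# extraction, bootstrap and normal-theory confidence intervals.

# The sigmoidal vulnerability curve is the classic Weibull
#   relK(P) = exp(-(P/b)^c),   PLC = 100 * (1 - relK),
# in tension magnitude P = |Psi|, reparameterized so that the curve is
# indexed directly by Px (the tension at x% loss) and Sx (the slope of
# PLC at Px, in % per MPa):
#   relK(P) = (1 - x/100)^((P/Px)^((Px*Sx)/V)),  V = (x - 100)*ln(1 - x/100).
# By construction PLC(Px) = x and dPLC/dP at Px equals Sx.

.weibull_V <- function(x) (x - 100) * log(1 - x / 100)

#' Reparameterized Weibull vulnerability curve
#'
#' Percent loss of conductivity (PLC) as a function of water potential for
#' the Weibull vulnerability curve parameterized by `Px` (the Psi at x%
#' loss) and `Sx` (the slope of the PLC curve at `Px`, percent per MPa).
#' The curve passes through PLC = x at `Px` exactly, with slope `Sx`
#' there exactly; these are the defining properties of the
#' reparameterization.
#'
#' @param psi_mpa Water potential, signed (MPa, <= 0). Positive inputs are
#'   rejected to avoid silent sign confusion; use negative Psi.
#' @param px_mpa Psi at x% loss, signed (< 0).
#' @param sx Slope at `px_mpa`, in percent PLC per MPa (> 0).
#' @param x Target loss percentage, in (0, 100); default 50.
#' @return PLC in percent, in `[0, 100]`. Vectorized over `psi_mpa`.
#' @examples
#' weibull_plc(-3.5, px_mpa = -3.5, sx = 30)  # exactly 50
#' @export
weibull_plc <- function(psi_mpa, px_mpa, sx, x = 50) {
  if (any(psi_mpa > 0)) stop("psi_mpa must be signed (<= 0)")
  if (px_mpa >= 0) stop("px_mpa must be < 0 (signed convention)")
  if (sx <= 0) stop("sx must be > 0")
  if (x <= 0 || x >= 100) stop("x must lie in (0, 100)")
  .plc_mag(abs(psi_mpa), abs(px_mpa), sx, x)
}

# internal: PLC on tension magnitudes (P >= 0, Px > 0)
.plc_mag <- function(P, Px, Sx, x) {
  V <- .weibull_V(x)
  100 * (1 - (1 - x / 100)^((P / Px)^((Px * Sx) / V)))
}

#' Convert between the Px/Sx and classic b/c Weibull parameterizations
#'
#' The classic two-parameter Weibull curve is
#' `relK(P) = exp(-(P/b)^c)` in tension magnitude P. The pair (Px, Sx)
#' maps to `c = Px*Sx/V` and `b = Px * (-log(1 - x/100))^(-1/c)` with
#' `V = (x-100)*log(1 - x/100)`; the inverse recovers (Px, Sx). Round
#' trips are exact to floating-point accuracy.
#'
#' @param px_mpa,sx Reparameterized parameters (signed Px, positive Sx).
#' @param b,c Classic Weibull scale (MPa, > 0) and shape (> 0).
#' @param x Loss percentage the (Px, Sx) pair refers to; default 50.
#' @return `weibull_to_classic`: list with `b` and `c`;
#'   `classic_to_weibull`: list with `px_mpa` (signed) and `sx`.
#' @name weibull_param
#' @export
weibull_to_classic <- function(px_mpa, sx, x = 50) {
  Px <- abs(px_mpa)
  V <- .weibull_V(x)
  cc <- (Px * sx) / V
  b <- Px * (-log(1 - x / 100))^(-1 / cc)
  list(b = b, c = cc)
}

#' @rdname weibull_param
#' @export
classic_to_weibull <- function(b, c, x = 50) {
  Px <- b * (-log(1 - x / 100))^(1 / c)
  V <- .weibull_V(x)
  list(px_mpa = -Px, sx = c * V / Px)
}

#' Psi at a given percent loss on a fitted curve
#'
#' Inverts a fitted vulnerability curve to report the water potential at
#' any loss percentage (e.g. P12, P88) from a curve fitted at x = 50.
#'
#' @param fit A `vc_fit` from [fit_vulnerability()].
#' @param x Loss percentage in (0, 100).
#' @return Signed Psi (MPa) at x% loss.
#' @examples
#' \donttest{
#' d <- simulate_hydraulic_dataset(sim_config(seed = 1))
#' f <- fit_vulnerability(d)
#' psi_at_plc(f, 12)   # P12
#' psi_at_plc(f, 88)   # P88
#' }
#' @export
psi_at_plc <- function(fit, x) {
  stopifnot(inherits(fit, "vc_fit"))
  if (x <= 0 || x >= 100) stop("x must lie in (0, 100)")
  cl <- weibull_to_classic(fit$px_mpa, fit$sx, fit$x)
  -cl$b * (-log(1 - x / 100))^(1 / cl$c)
}

#' Fit a Weibull vulnerability curve
#'
#' Unweighted nonlinear least squares of PLC on Psi with the
#' reparameterized Weibull curve, returning the Psi at x% loss (`px_mpa`)
#' and the slope there (`sx`). Starting values are taken from the data:
#' `Px` from the measurement whose PLC is nearest x, and `Sx` from a local
#' linear fit of PLC on tension around that point.
#'
#' @param data A data.frame with columns `psi_mpa` (signed) and
#'   `plc_percent` (e.g. from [read_vuln_table()] or
#'   [simulate_hydraulic_dataset()]).
#' @param x Target loss percentage (default 50, i.e. P50).
#' @param quiet Suppress the extrapolation warning (used internally by the
#'   bootstrap).
#' @return An object of class `vc_fit`: a list with `x`, `px_mpa` (signed),
#'   `sx` (% per MPa), `residual_sse`, `n_points`, `ci_lo`/`ci_hi`
#'   (NA until [bootstrap_ci()] or [aggregate_fits()]), `method` and
#'   `converged`.
#' @export
fit_vulnerability <- function(data, x = 50, quiet = FALSE) {
  data <- as.data.frame(data)
  if (!all(c("psi_mpa", "plc_percent") %in% names(data)))
    stop("data needs columns psi_mpa and plc_percent")
  if (nrow(data) < 4) stop("at least 4 measurements are required")
  P <- abs(data$psi_mpa)
  plc <- data$plc_percent
  if (!quiet && (all(plc < x) || all(plc > x)))
    warning("PLC data do not bracket ", x, "%; Px is an extrapolation")
  # starting values from the data
  i0 <- which.min(abs(plc - x))
  Px0 <- max(P[i0], 0.2)
  near <- order(abs(P - Px0))[seq_len(min(6, length(P)))]
  Sx0 <- if (length(unique(P[near])) > 1)
    unname(stats::coef(stats::lm(plc[near] ~ P[near]))[2]) else NA_real_
  if (!is.finite(Sx0) || Sx0 <= 0) Sx0 <- 50 / Px0
  df <- data.frame(P = P, plc = plc)
  fit <- tryCatch(
    minpack.lm::nlsLM(plc ~ .plc_mag(P, Px, Sx, x), data = df,
                      start = list(Px = Px0, Sx = Sx0),
                      lower = c(0.05, 0.1), upper = c(50, 2000),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("vulnerability fit did not converge (start Px = ",
           sprintf("%.2f", Px0), ", Sx = ", sprintf("%.1f", Sx0), "): ",
           conditionMessage(e), call. = FALSE))
  est <- stats::coef(fit)
  structure(list(x = x,
                 px_mpa = -unname(est["Px"]),
                 sx = unname(est["Sx"]),
                 residual_sse = sum(stats::residuals(fit)^2),
                 n_points = nrow(df),
                 ci_lo = NA_real_, ci_hi = NA_real_,
                 method = "pooled_fit",
                 converged = fit$convInfo$isConv %||% TRUE),
            class = "vc_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("Weibull vulnerability curve (n = %d, %s)\n", x$n_points,
              x$method))
  cat(sprintf("  P%g = %.2f MPa", x$x, x$px_mpa))
  if (!is.na(x$ci_lo))
    cat(sprintf("  [95%% CI %.2f, %.2f]", x$ci_lo, x$ci_hi))
  cat(sprintf("\n  S%g = %.1f %% per MPa\n", x$x, x$sx))
  invisible(x)
}

#' Bootstrap confidence interval for Px
#'
#' Percentile bootstrap CI for the Px of a pooled vulnerability fit:
#' measurements are case-resampled with replacement, the curve is refit
#' to each replicate, and the 2.5/97.5 percentiles of the converged
#' replicate Px values form the interval. Non-converged replicates are
#' dropped and counted.
#'
#' @param data As in [fit_vulnerability()].
#' @param x Loss percentage (default 50).
#' @param n_boot Number of bootstrap replicates (default 999).
#' @param seed Optional integer seed for reproducibility.
#' @return The full-data `vc_fit` with `ci_lo`/`ci_hi` filled in,
#'   `method = "pooled_bootstrap"`, and attributes `n_boot_failed` and
#'   `boot_px` (the replicate Px values).
#' @export
bootstrap_ci <- function(data, x = 50, n_boot = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_vulnerability(data, x = x)
  data <- as.data.frame(data)
  n <- nrow(data)
  px_boot <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(
      suppressWarnings(fit_vulnerability(data[idx, , drop = FALSE], x = x,
                                         quiet = TRUE)),
      error = function(e) NULL)
    if (!is.null(fb)) px_boot[b] <- fb$px_mpa
  }
  ok <- !is.na(px_boot)
  if (sum(!ok) > 0.10 * n_boot)
    warning(sum(!ok), " of ", n_boot, " bootstrap replicates failed to ",
            "converge; CI may be unreliable")
  qs <- stats::quantile(px_boot[ok], c(0.025, 0.975), names = FALSE,
                        type = 7)
  fit$ci_lo <- qs[1]
  fit$ci_hi <- qs[2]
  fit$method <- "pooled_bootstrap"
  attr(fit, "n_boot_failed") <- sum(!ok)
  attr(fit, "boot_px") <- px_boot[ok]
  fit
}

#' Normal-theory confidence interval of a sample mean
#'
#' The 95% CI of a sample mean as mean +/- 1.96 * SE with SE = sd/sqrt(n).
#' No CI is reported for n < 3, where the SE is not meaningfully
#' estimable; the mean alone is returned.
#'
#' @param values Numeric vector (NAs dropped).
#' @return A list with `mean`, `se`, `ci_lo`, `ci_hi` and `n`; `se` and
#'   the CI are NA when n < 3.
#' @examples
#' mean_ci(c(1, 2, 3))  # mean 2, CI (0.868, 3.132)
#' @export
mean_ci <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("no non-missing values")
  m <- mean(values)
  if (n < 3)
    return(list(mean = m, se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                n = n))
  se <- stats::sd(values) / sqrt(n)
  list(mean = m, se = se, ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se,
       n = n)
}

#' Aggregate per-sample vulnerability fits to a species-level estimate
#'
#' For techniques that yield one complete curve per sample (e.g.
#' centrifuge measurements), the species-level Px is the mean of the
#' per-sample Px values, with a normal-theory CI via [mean_ci()]
#' (absent when fewer than 3 samples were fit).
#'
#' @param fits A list of `vc_fit` objects for samples of one species.
#' @return A `vc_fit` with `method = "per_sample_mean"`; `sx` is likewise
#'   the mean of per-sample slopes, `n_points` the number of samples.
#' @export
aggregate_fits <- function(fits) {
  if (!length(fits) || !all(vapply(fits, inherits, logical(1), "vc_fit")))
    stop("fits must be a nonempty list of vc_fit objects")
  xs <- vapply(fits, `[[`, numeric(1), "x")
  if (length(unique(xs)) != 1) stop("fits target different x values")
  px <- vapply(fits, `[[`, numeric(1), "px_mpa")
  ci <- mean_ci(px)
  structure(list(x = xs[1],
                 px_mpa = ci$mean,
                 sx = mean(vapply(fits, `[[`, numeric(1), "sx")),
                 residual_sse = NA_real_,
                 n_points = length(fits),
                 ci_lo = ci$ci_lo, ci_hi = ci$ci_hi,
                 method = "per_sample_mean",
                 converged = TRUE),
            class = "vc_fit")
}
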