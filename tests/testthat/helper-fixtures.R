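# Shared fixture builders for the test suite. All synthetic data are
# generated in code under fixed seeds.

table2 <- function() {
  read_species_summary(system.file("extdata", "species_summary.csv",
                                   package = "cavitrace"))
}

# hit stream with exactly one hit per minute (at 30 s past each minute)
uniform_hits <- function(n_min = 60, amp = 60) {
  tt <- (seq_len(n_min) - 0.5) * 60
  ae_series(tt, rep(amp, n_min), t_end_s = n_min * 60)
}

# homogeneous-Poisson hit stream
poisson_hits <- function(n, dur_min, seed) {
  set.seed(seed)
  tt <- sort(runif(n, 0, dur_min * 60))
  ae_series(tt, runif(n, 40, 80), t_end_s = dur_min * 60)
}

# brute-force rate oracle: count hits in the centered, truncated window
rate_oracle <- function(series, grid_min, window_min) {
  t_min <- series$hits$time_s / 60
  dur <- series$t_end_s / 60
  vapply(grid_min, function(g) {
    lo <- max(g - window_min / 2, 0)
    hi <- min(g + window_min / 2, dur)
    sum(t_min >= lo & t_min < hi) / (hi - lo)
  }, numeric(1))
}

# leverage / Cook's distance oracle by explicit hat matrix and
# leave-one-out refits
influence_oracle <- function(x, y) {
  n <- length(x)
  X <- cbind(1, x)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  h <- diag(H)
  fit <- lm(y ~ x)
  s2 <- sum(residuals(fit)^2) / (n - 2)
  cooks <- vapply(seq_len(n), function(i) {
    fit_i <- lm(y[-i] ~ x[-i])
    yhat_full <- fitted(fit)
    yhat_i <- cbind(1, x) %*% coef(fit_i)
    sum((yhat_full - yhat_i)^2) / (2 * s2)
  }, numeric(1))
  list(leverage = h, cooks_d = cooks)
}

write_tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
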