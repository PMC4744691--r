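# Cross-method comparison: least-squares regression of the acoustic
# vulnerability estimate (Pmaxrate) on the hydraulic reference (P50)
# across species, with influence diagnostics.

#' Regress Pmaxrate on P50 across species
#'
#' Ordinary least squares of |Pmaxrate| on |P50| in tension magnitudes
#' (MPa) across a species summary table, with R-squared, two-sided t-tests
#' on both coefficients, hat-value leverages, Cook's distances, and a 95%
#' confidence band on a prediction grid.
#'
#' The regression is computed in magnitude space, where the intercept has
#' its conventional sign for this comparison (a positive intercept means
#' acoustic estimates exceed hydraulic ones at low tension). The slope and
#' R-squared are identical in signed space; only the intercept changes
#' sign, and both are reported.
#'
#' @param summaries A `species_summary` data.frame (see
#'   [read_species_summary()] or [simulate_species_panel()]).
#' @return An object of class `method_comparison`: a list with `slope`,
#'   `intercept` (magnitude space), `intercept_signed`, `r2`, `p_slope`,
#'   `p_intercept`, `se_slope`, `se_intercept`, `n`, `species`,
#'   `leverages`, `cooks_d`, `ci_band` (data.frame `p50_mag`, `fit`,
#'   `lwr`, `upr`) and the underlying `lm` fit.
#' @examples
#' path <- system.file("extdata", "species_summary.csv", package = "cavitrace")
#' reg <- compare_methods(read_species_summary(path))
#' reg$slope; reg$r2
#' @export
compare_methods <- function(summaries) {
  df <- as.data.frame(summaries)
  if (!all(c("p50_mpa", "pmaxrate_mpa") %in% names(df)))
    stop("summaries need columns p50_mpa and pmaxrate_mpa")
  df <- df[stats::complete.cases(df[c("p50_mpa", "pmaxrate_mpa")]), ,
           drop = FALSE]
  if (nrow(df) < 3)
    stop("at least 3 species with both P50 and Pmaxrate are required")
  dat <- data.frame(p50_mag = abs(df$p50_mpa),
                    pmax_mag = abs(df$pmaxrate_mpa))
  fit <- stats::lm(pmax_mag ~ p50_mag, data = dat)
  sm <- summary(fit)
  co <- sm$coefficients
  grid <- data.frame(p50_mag = seq(min(dat$p50_mag), max(dat$p50_mag),
                                   length.out = 50))
  band <- stats::predict(fit, newdata = grid, interval = "confidence",
                         level = 0.95)
  structure(list(slope = unname(co["p50_mag", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 intercept_signed = -unname(co["(Intercept)", "Estimate"]),
                 r2 = sm$r.squared,
                 p_slope = unname(co["p50_mag", "Pr(>|t|)"]),
                 p_intercept = unname(co["(Intercept)", "Pr(>|t|)"]),
                 se_slope = unname(co["p50_mag", "Std. Error"]),
                 se_intercept = unname(co["(Intercept)", "Std. Error"]),
                 n = nrow(dat),
                 species = if ("species" %in% names(df)) df$species else
                   as.character(seq_len(nrow(df))),
                 leverages = unname(stats::hatvalues(fit)),
                 cooks_d = unname(stats::cooks.distance(fit)),
                 ci_band = data.frame(p50_mag = grid$p50_mag,
                                      fit = band[, "fit"],
                                      lwr = band[, "lwr"],
                                      upr = band[, "upr"]),
                 lm_fit = fit),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Pmaxrate ~ P50 regression (tension magnitudes, n = %d)\n",
              x$n))
  cat(sprintf("  slope     %6.3f  (SE %.3f, p = %.2g)\n", x$slope,
              x$se_slope, x$p_slope))
  cat(sprintf("  intercept %6.3f  (SE %.3f, p = %.2g)\n", x$intercept,
              x$se_intercept, x$p_intercept))
  cat(sprintf("  R-squared %6.3f\n", x$r2))
  invisible(x)
}

#' Refit the cross-method regression without influential points
#'
#' Sensitivity analysis for [compare_methods()]: drops the species flagged
#' by a rule — highest leverage, highest Cook's distance, species with
#' fewer than 3 Pmaxrate samples, or an explicit list — refits, and
#' reports coefficient changes.
#'
#' @param summaries As in [compare_methods()].
#' @param drop_rule One of `"max_leverage"`, `"max_cooks_d"`, `"n_lt_3"`,
#'   or a character vector of species names to drop.
#' @return A list with `fit` (the refit `method_comparison`),
#'   `dropped_species`, and `delta` (named numeric: changes in slope,
#'   intercept and r2 relative to the full fit).
#' @export
sensitivity_refit <- function(summaries, drop_rule) {
  full <- compare_methods(summaries)
  df <- as.data.frame(summaries)
  df <- df[stats::complete.cases(df[c("p50_mpa", "pmaxrate_mpa")]), ,
           drop = FALSE]
  sp <- if ("species" %in% names(df)) df$species else
    as.character(seq_len(nrow(df)))
  drop <- if (length(drop_rule) == 1 && drop_rule == "max_leverage") {
    sp[which.max(full$leverages)]
  } else if (length(drop_rule) == 1 && drop_rule == "max_cooks_d") {
    sp[which.max(full$cooks_d)]
  } else if (length(drop_rule) == 1 && drop_rule == "n_lt_3") {
    if (!"n_pmax" %in% names(df))
      stop("drop_rule 'n_lt_3' needs an n_pmax column")
    sp[df$n_pmax < 3]
  } else {
    drop_rule
  }
  keep <- !sp %in% drop
  if (sum(keep) < 3) stop("dropping would leave fewer than 3 species")
  refit <- compare_methods(df[keep, , drop = FALSE])
  list(fit = refit,
       dropped_species = sp[!keep],
       delta = c(slope = refit$slope - full$slope,
                 intercept = refit$intercept - full$intercept,
                 r2 = refit$r2 - full$r2))
}

#' Summary statistics of a species table
#'
#' Range, mean and standard error of P50 and Pmaxrate across species, and
#' the counts of species in which the acoustic estimate is less negative
#' (higher Psi) than the hydraulic one, split by clade. In angiosperms the
#' acoustic peak tends to fall below P50 (large early-cavitating vessels
#' dominate the conductivity loss but are few), while conifers tend to
#' show the peak above P50 (many small vulnerable tracheids emit early).
#'
#' @param summaries A `species_summary` data.frame.
#' @return A list with components `p50` and `pmaxrate` (each: `min`,
#'   `max`, `mean`, `se`, `n`; SE is NA for a single species), and
#'   `offset_counts`: a data.frame per clade with the number of species
#'   whose Pmaxrate is less negative / more negative than P50.
#' @export
summarize_table <- function(summaries) {
  df <- as.data.frame(summaries)
  if (!nrow(df)) stop("empty summary table")
  stat <- function(v) {
    v <- v[!is.na(v)]
    list(min = min(v), max = max(v), mean = mean(v),
         se = if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else
           NA_real_,
         n = length(v))
  }
  both <- stats::complete.cases(df[c("p50_mpa", "pmaxrate_mpa")])
  less_neg <- df$pmaxrate_mpa > df$p50_mpa  # acoustic above hydraulic
  clades <- if ("clade" %in% names(df)) df$clade else
    rep("unknown", nrow(df))
  counts <- do.call(rbind, lapply(unique(clades), function(cl) {
    i <- both & clades == cl
    data.frame(clade = cl,
               n = sum(i),
               pmax_less_negative = sum(less_neg[i]),
               pmax_more_negative = sum(!less_neg[i]))
  }))
  list(p50 = stat(df$p50_mpa),
       pmaxrate = stat(df$pmaxrate_mpa),
       offset_counts = counts)
}
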