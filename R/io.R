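#' @keywords internal
"_PACKAGE"

# ---- domain constructors -----------------------------------------------

#' Construct an AE hit series
#'
#' An `ae_series` holds the timestamped ultrasonic acoustic-emission (AE)
#' hits recorded from the xylem of one dehydrating sample: one row per hit,
#' with the time since the start of recording (seconds) and the peak
#' amplitude (dB). Hits are stored sorted by time.
#'
#' @param time_s Numeric vector of hit times in seconds since recording
#'   start. Must be non-negative.
#' @param amplitude_db Numeric vector of peak amplitudes in dB, in
#'   `[0, 120]`.
#' @param energy Optional numeric vector of hit energies (arbitrary units).
#' @param sample_id Label for the sample.
#' @param t_end_s Recording end time in seconds; defaults to the last hit
#'   time. Must not precede the last hit.
#' @return An object of class `ae_series`: a list with elements `hits`
#'   (data.frame with columns `time_s`, `amplitude_db` and optionally
#'   `energy`), `sample_id` and `t_end_s`.
#' @examples
#' ae <- ae_series(c(10, 65, 30), c(52, 61, 47))
#' ae$hits$time_s  # sorted
#' @export
ae_series <- function(time_s, amplitude_db, energy = NULL,
                      sample_id = "sample", t_end_s = NULL) {
  if (length(time_s) != length(amplitude_db))
    stop("time_s and amplitude_db must have equal length")
  if (any(!is.finite(time_s)) || any(!is.finite(amplitude_db)))
    stop("hit times and amplitudes must be finite")
  if (any(time_s < 0))
    stop("hit times must be >= 0 (seconds since recording start)")
  if (any(amplitude_db < 0 | amplitude_db > 120))
    stop("amplitudes must lie in [0, 120] dB")
  ord <- order(time_s)
  hits <- data.frame(time_s = time_s[ord], amplitude_db = amplitude_db[ord])
  if (!is.null(energy)) {
    if (length(energy) != length(time_s))
      stop("energy must match the number of hits")
    hits$energy <- energy[ord]
  }
  if (is.null(t_end_s)) t_end_s <- if (nrow(hits)) max(hits$time_s) else 0
  if (nrow(hits) && t_end_s < max(hits$time_s))
    stop("t_end_s precedes the last hit time")
  structure(list(hits = hits, sample_id = as.character(sample_id),
                 t_end_s = as.numeric(t_end_s)),
            class = "ae_series")
}

#' @export
print.ae_series <- function(x, ...) {
  cat(sprintf("AE hit series '%s': %d hits over %.1f min", x$sample_id,
              nrow(x$hits), x$t_end_s / 60))
  if (nrow(x$hits))
    cat(sprintf(", amplitudes %.0f-%.0f dB", min(x$hits$amplitude_db),
                max(x$hits$amplitude_db)))
  cat("\n")
  invisible(x)
}

#' Construct a water-potential series
#'
#' Sparse pressure-chamber readings of xylem water potential (Psi, MPa)
#' taken during a dehydration experiment, on the same clock as the AE
#' recording. The canonical convention is signed Psi: values are negative,
#' more negative meaning stronger tension.
#'
#' @param time_s Reading times in seconds since recording start
#'   (nondecreasing).
#' @param psi_mpa Water potential in MPa. Under the default signed
#'   convention all values must be <= 0; with
#'   `convention = "magnitude"` positive tension magnitudes are accepted
#'   and stored negated.
#' @param se_mpa Optional per-reading standard error (MPa).
#' @param convention Either `"signed"` (default) or `"magnitude"`.
#' @return An object of class `psi_series`: a data.frame with columns
#'   `time_s`, `psi_mpa` and optionally `se_mpa`.
#' @examples
#' psi_series(c(0, 3600), c(0.5, 2.1), convention = "magnitude")
#' @export
psi_series <- function(time_s, psi_mpa, se_mpa = NULL,
                       convention = c("signed", "magnitude")) {
  convention <- match.arg(convention)
  if (length(time_s) != length(psi_mpa))
    stop("time_s and psi_mpa must have equal length")
  if (is.unsorted(time_s))
    stop("psi reading times must be nondecreasing")
  if (convention == "magnitude") {
    if (any(psi_mpa < 0))
      stop("magnitude convention requires nonnegative tension values")
    psi_mpa <- -psi_mpa
  } else if (any(psi_mpa > 0)) {
    stop("signed convention requires psi_mpa <= 0 ",
         "(use convention = \"magnitude\" for tension magnitudes)")
  }
  out <- data.frame(time_s = as.numeric(time_s), psi_mpa = as.numeric(psi_mpa))
  if (!is.null(se_mpa)) {
    if (length(se_mpa) != length(time_s))
      stop("se_mpa must match the number of readings")
    out$se_mpa <- as.numeric(se_mpa)
  }
  class(out) <- c("psi_series", "data.frame")
  out
}

#' @export
print.psi_series <- function(x, ...) {
  cat(sprintf("Water-potential series: %d readings, %.2f to %.2f MPa\n",
              nrow(x), max(x$psi_mpa), min(x$psi_mpa)))
  invisible(x)
}

#' View water potentials as tension magnitudes
#'
#' Returns the positive tension magnitudes (|Psi|, MPa) of a signed
#' quantity. Public outputs of the package use signed Psi (negative MPa);
#' the Weibull vulnerability-curve mathematics and the cross-method
#' regression operate on magnitudes, and this helper makes the conversion
#' explicit.
#'
#' @param psi_mpa Signed water potentials (MPa, <= 0), or a `psi_series`.
#' @return Nonnegative tension magnitudes, same shape as the input (for a
#'   `psi_series`, the `psi_mpa` column is returned as magnitudes).
#' @export
tension_magnitude <- function(psi_mpa) {
  if (inherits(psi_mpa, "psi_series")) psi_mpa <- psi_mpa$psi_mpa
  abs(psi_mpa)
}

# ---- readers -----------------------------------------------------------

.read_delim_checked <- function(path, required, optional = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (cl in intersect(c(required, optional), names(df)))
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  bad <- which(!stats::complete.cases(df[required]))
  if (length(bad)) {
    # +1 for the header: report physical line numbers in the file
    warning("dropping ", length(bad), " malformed row(s) in ", basename(path),
            " (line ", paste(utils::head(bad + 1, 5), collapse = ", "),
            if (length(bad) > 5) ", ..." else "", ")")
    df <- df[-bad, , drop = FALSE]
  }
  df
}

#' Read an AE hit log
#'
#' Reads a delimited hit log (CSV with a header) as exported by AE
#' acquisition software: one row per hit with a timestamp and a peak
#' amplitude in dB, plus an optional energy column. Column names are
#' declared, not positional, because export schemas vary between setups.
#'
#' @param path Path to the CSV file.
#' @param time_col,amp_col,energy_col Column names for time, amplitude and
#'   (optionally) energy. `energy_col = NULL` skips energy.
#' @param time_unit Unit of the time column: `"s"` (default) or `"min"`.
#'   Times are normalized to seconds internally.
#' @param sample_id Label for the sample; defaults to the file name.
#' @param tol_s Timestamps may jitter backwards by up to this many seconds
#'   (acquisition clock granularity); larger order violations are an error
#'   naming the first offending row.
#' @return An [ae_series].
#' @export
read_hits <- function(path, time_col = "time", amp_col = "amplitude_db",
                      energy_col = NULL, time_unit = c("s", "min"),
                      sample_id = NULL, tol_s = 1) {
  time_unit <- match.arg(time_unit)
  req <- c(time_col, amp_col)
  df <- .read_delim_checked(path, req, optional = energy_col)
  tt <- df[[time_col]]
  if (time_unit == "min") tt <- tt * 60
  backstep <- which(diff(tt) < -tol_s)
  if (length(backstep))
    stop("non-monotonic timestamps in ", basename(path), ": data row ",
         backstep[1] + 1, " precedes row ", backstep[1],
         " by more than the ", tol_s, " s tolerance")
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  ae_series(tt, df[[amp_col]],
            energy = if (!is.null(energy_col)) df[[energy_col]],
            sample_id = sample_id)
}

#' Read a water-potential series
#'
#' @param path CSV with columns for time and Psi (and optionally a
#'   per-reading SE).
#' @param time_col,psi_col,se_col Column names; `se_col = NULL` skips SE.
#' @param time_unit `"s"` or `"min"`.
#' @param convention Sign convention of the Psi column: `"signed"`
#'   (negative MPa) or `"magnitude"` (positive tensions). A column mixing
#'   both signs is refused: the convention cannot be guessed.
#' @return A [psi_series] in the canonical signed representation.
#' @export
read_psi <- function(path, time_col = "time", psi_col = "psi_mpa",
                     se_col = NULL, time_unit = c("s", "min"),
                     convention = c("signed", "magnitude")) {
  time_unit <- match.arg(time_unit)
  convention <- match.arg(convention)
  df <- .read_delim_checked(path, c(time_col, psi_col), optional = se_col)
  psi <- df[[psi_col]]
  if (any(psi > 0) && any(psi < 0))
    stop("Psi column in ", basename(path), " mixes positive and negative ",
         "values; declare the sign convention and fix the data")
  tt <- df[[time_col]]
  if (time_unit == "min") tt <- tt * 60
  psi_series(tt, psi, se_mpa = if (!is.null(se_col)) df[[se_col]],
             convention = convention)
}

#' Percent loss of conductivity from flow measurements
#'
#' PLC = 100 * (1 - k_native / k_max), the standard loss measure from a
#' conductivity measurement before (`k_native`) and after (`k_max`)
#' flushing out embolism. Noisy flow ratios can stray outside `[0, 100]`;
#' such values are clipped with a warning, since curve fitting requires
#' bounded PLC.
#'
#' @param k_native Conductivity before flushing (>= 0).
#' @param k_max Conductivity after flushing (> 0).
#' @return PLC in percent, clipped to `[0, 100]`. Vectorized.
#' @examples
#' plc_from_conductivity(2, 8)  # 75
#' @export
plc_from_conductivity <- function(k_native, k_max) {
  if (any(k_max <= 0)) stop("k_max must be > 0")
  if (any(k_native < 0)) stop("k_native must be >= 0")
  plc <- 100 * (1 - k_native / k_max)
  n_clip <- sum(plc < 0 | plc > 100)
  if (n_clip)
    warning(n_clip, " PLC value(s) outside [0, 100] clipped ",
            "(noisy flow ratio)")
  pmin(100, pmax(0, plc))
}

#' Read a hydraulic vulnerability table
#'
#' Accepts either direct PLC data (`psi_mpa`, `plc_percent`) or raw
#' conductivities (`psi_mpa`, `k_native`, `k_max`), in which case PLC is
#' computed via [plc_from_conductivity()]. An optional `sample_id` column
#' carries per-sample grouping for the per-sample fitting workflow.
#'
#' @param path CSV path.
#' @param convention Sign convention of the Psi column (see [read_psi()]).
#' @return A data.frame of class `vuln_table` with columns `psi_mpa`
#'   (signed), `plc_percent` and, if present in the file, `sample_id`.
#' @export
read_vuln_table <- function(path, convention = c("signed", "magnitude")) {
  convention <- match.arg(convention)
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"psi_mpa" %in% names(df))
    stop("file ", path, " is missing required column: psi_mpa")
  psi <- as.numeric(df$psi_mpa)
  if (any(psi > 0) && any(psi < 0))
    stop("Psi column mixes signs; declare the convention")
  if (convention == "magnitude") {
    if (any(psi < 0)) stop("magnitude convention requires nonnegative Psi")
    psi <- -psi
  } else if (any(psi > 0)) {
    stop("signed convention requires psi_mpa <= 0")
  }
  if ("plc_percent" %in% names(df)) {
    plc <- as.numeric(df$plc_percent)
    if (any(plc < 0 | plc > 100)) {
      warning("PLC values outside [0, 100] clipped")
      plc <- pmin(100, pmax(0, plc))
    }
  } else if (all(c("k_native", "k_max") %in% names(df))) {
    plc <- plc_from_conductivity(as.numeric(df$k_native),
                                 as.numeric(df$k_max))
  } else {
    stop("file ", path, " needs either plc_percent or k_native + k_max")
  }
  out <- data.frame(psi_mpa = psi, plc_percent = plc)
  if ("sample_id" %in% names(df)) out$sample_id <- as.character(df$sample_id)
  class(out) <- c("vuln_table", "data.frame")
  out
}

#' Read a species summary table
#'
#' Reads a table of species-level vulnerability parameters: hydraulic P50
#' with 95% CI and sample size, and the water potential at maximum AE
#' activity (Pmaxrate) with its CI and sample size, plus the clade
#' (angiosperm or gymnosperm). A copy of the published 18-species summary
#' ships with the package; see the example.
#'
#' @param path CSV with columns `species`, `clade`, `p50_mpa`, `p50_ci_lo`,
#'   `p50_ci_hi`, `n_p50`, `pmaxrate_mpa`, `pmax_ci_lo`, `pmax_ci_hi`,
#'   `n_pmax`. CI columns may contain NA where no CI was computed (n < 3).
#' @return A data.frame of class `species_summary`.
#' @examples
#' path <- system.file("extdata", "species_summary.csv", package = "cavitrace")
#' summaries <- read_species_summary(path)
#' nrow(summaries)  # 18
#' @export
read_species_summary <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "clade", "p50_mpa", "p50_ci_lo", "p50_ci_hi", "n_p50",
            "pmaxrate_mpa", "pmax_ci_lo", "pmax_ci_hi", "n_pmax")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  num <- setdiff(need, c("species", "clade"))
  for (cl in num) df[[cl]] <- as.numeric(df[[cl]])
  if (!all(df$clade %in% c("angiosperm", "gymnosperm")))
    stop("clade must be 'angiosperm' or 'gymnosperm'")
  for (pre in c("p50", "pmax")) {
    lo <- df[[paste0(pre, "_ci_lo")]]; hi <- df[[paste0(pre, "_ci_hi")]]
    mid <- df[[if (pre == "p50") "p50_mpa" else "pmaxrate_mpa"]]
    ok <- is.na(lo) | is.na(hi) | (lo <= mid & mid <= hi)
    if (!all(ok))
      stop("CI bounds do not bracket the mean for row(s): ",
           paste(which(!ok), collapse = ", "))
  }
  class(df) <- c("species_summary", "data.frame")
  df
}

# ---- writers (round-trip support) --------------------------------------

#' Write package tables to CSV
#'
#' Writers matching the readers, so that a write-then-read round trip
#' reproduces every field. Times are written in seconds and Psi in the
#' canonical signed convention.
#'
#' @param x Object to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
write_hits <- function(x, path) {
  stopifnot(inherits(x, "ae_series"))
  df <- x$hits
  names(df)[names(df) == "time_s"] <- "time"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
write_psi <- function(x, path) {
  stopifnot(inherits(x, "psi_series"))
  df <- as.data.frame(x)
  names(df)[names(df) == "time_s"] <- "time"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
write_vuln_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
write_species_summary <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
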