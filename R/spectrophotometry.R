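# Spectrophotometry: cuvette readings, temperature-corrected net optical
# density at the 25 C reference, replicate averaging and blank QC.

.ROLE_LEVELS <- c("irradiated", "control", "water_blank")

#' Construct and validate a single cuvette reading
#'
#' One absorbance measurement at 304 nm of an irradiated, control
#' (non-irradiated Fricke) or pure-water cuvette.
#'
#' @param cuvette_id Identifier of the physical cuvette.
#' @param role One of `"irradiated"`, `"control"`, `"water_blank"`.
#' @param od Optical density (absorbance units), non-negative.
#' @param path_length Optical path length in cm; values outside the
#'   plausibility band [0.9, 1.1] cm around the nominal 1.0 cm warn.
#' @param t_read Solution temperature during the reading, degrees C,
#'   within [10, 40].
#' @param run_id Irradiation run the reading belongs to.
#' @param timestamp Optional reading time, kept for audit only (no
#'   fading correction is applied).
#' @return A one-row data.frame of class `cuvette_reading`.
#' @export
cuvette_reading <- function(cuvette_id, role, od, path_length = 1.0,
                            t_read = 25, run_id = "run1", timestamp = NA) {
  role <- match.arg(role, .ROLE_LEVELS)
  if (!is.numeric(od) || is.na(od) || od < 0) {
    stop("optical density must be non-negative")
  }
  if (!is.numeric(path_length) || is.na(path_length) || path_length <= 0) {
    stop("path length must be positive (cm)")
  }
  if (path_length < 0.9 || path_length > 1.1) {
    warning(sprintf(
      "path length %.4f cm is outside the plausibility band [0.9, 1.1] cm",
      path_length))
  }
  if (!is.numeric(t_read) || is.na(t_read) || t_read < 10 || t_read > 40) {
    stop("reading temperature must lie within [10, 40] C")
  }
  structure(
    data.frame(run_id = run_id, cuvette_id = cuvette_id, role = role,
               od = od, path_length_cm = path_length, t_read_c = t_read,
               timestamp = as.character(timestamp),
               stringsAsFactors = FALSE),
    class = c("cuvette_reading", "data.frame"))
}

#' Construct and validate an irradiation record
#'
#' @param run_id Run identifier.
#' @param t_irr Solution temperature during irradiation, degrees C.
#' @param duration Irradiation time in hours, positive.
#' @param nominal_dose Intended dose in Gy; values outside the Fricke
#'   operating band [5, 400] Gy warn.
#' @param s_k Air-kerma strength of the source in U (cGy cm^2/h), or
#'   `NA` when no ionometric reference is attached.
#' @return A one-row data.frame of class `irradiation_record`.
#' @export
irradiation_record <- function(run_id, t_irr = 25, duration = 0.05,
                               nominal_dose = 20, s_k = NA_real_) {
  if (!is.numeric(t_irr) || is.na(t_irr) || t_irr < 10 || t_irr > 40) {
    stop("irradiation temperature must lie within [10, 40] C")
  }
  if (!is.numeric(duration) || is.na(duration) || duration <= 0) {
    stop("irradiation duration must be positive (hours)")
  }
  if (!is.na(nominal_dose) && (nominal_dose < 5 || nominal_dose > 400)) {
    warning(sprintf(
      "nominal dose %.1f Gy is outside the Fricke operating band [5, 400] Gy",
      nominal_dose))
  }
  if (!is.na(s_k) && s_k <= 0) stop("air-kerma strength must be positive (U)")
  structure(
    data.frame(run_id = run_id, t_irr_c = t_irr, duration_h = duration,
               nominal_dose_gy = nominal_dose, s_k_u = s_k,
               stringsAsFactors = FALSE),
    class = c("irradiation_record", "data.frame"))
}

#' Temperature-corrected net optical density (25 C reference)
#'
#' The dose-induced absorbance increase is the irradiated minus control
#' reading, divided by one multiplicative factor per temperature:
#' \deqn{\Delta OD = \frac{OD_i - OD_c}{[1 + c_i (T_i - 25)][1 + c_r (T_r - 25)]}}
#' where \eqn{T_i} is the solution temperature during irradiation and
#' \eqn{T_r} during the spectrophotometer reading. At 25 C both factors
#' are unity and the net OD passes through unchanged.
#'
#' @param od_i Absorbance of the irradiated solution.
#' @param od_c Absorbance of the control (non-irradiated) solution.
#' @param t_irr,t_read Temperatures in degrees C, within [10, 40].
#' @param coeff_irr,coeff_read Fractional temperature coefficients per
#'   degree C; defaults are the packaged literature values (0.0012 for
#'   irradiation, 0.0069 for reading).
#' @return Corrected net optical density (dimensionless). Negative
#'   values are returned with a warning, never clamped, so swapped
#'   irradiated/control labels stay visible to QC.
#' @export
delta_od <- function(od_i, od_c, t_irr = 25, t_read = 25,
                     coeff_irr = default_constants()$temperature_coefficients$irradiation_per_C,
                     coeff_read = default_constants()$temperature_coefficients$reading_per_C) {
  for (t in c(t_irr, t_read)) {
    if (!is.numeric(t) || is.na(t) || t < 10 || t > 40) {
      stop("temperatures must lie within [10, 40] C")
    }
  }
  denom <- (1 + coeff_irr * (t_irr - 25)) * (1 + coeff_read * (t_read - 25))
  if (denom <= 0) {
    stop("temperature correction factor is non-positive; ",
         "check the coefficients and temperatures")
  }
  out <- (od_i - od_c) / denom
  if (any(out < 0)) {
    warning("corrected net OD is negative; irradiated and control readings ",
            "may be swapped")
  }
  out
}

#' Average replicate cuvette readings into one net optical density
#'
#' Applies [delta_od()] to each irradiated replicate against the shared
#' control reading, then averages. The Type A component is the sample
#' (n-1) standard deviation of the mean, expressed in percent of the
#' mean; with a single replicate it is `NA`, with identical replicates
#' it is exactly 0.
#'
#' @param readings `cuvette_reading` rows (or a data.frame in the same
#'   schema) with role `"irradiated"`, all from one run.
#' @param control A single `cuvette_reading` with role `"control"`.
#' @param irr The run's [irradiation_record()] (supplies the
#'   irradiation temperature).
#' @param coeff_irr,coeff_read Temperature coefficients per degree C.
#' @return An object of class `net_od` with fields `value`,
#'   `path_length` (mean of replicate paths, cm), `n_replicates`,
#'   `type_a_percent` and `flagged` (TRUE when the mean is not
#'   positive).
#' @export
average_replicates <- function(readings, control, irr,
                               coeff_irr = default_constants()$temperature_coefficients$irradiation_per_C,
                               coeff_read = default_constants()$temperature_coefficients$reading_per_C) {
  readings <- as.data.frame(readings)
  control <- as.data.frame(control)
  if (nrow(readings) == 0) stop("need at least one irradiated replicate")
  if (!all(readings$role == "irradiated")) {
    stop("all replicate readings must have role 'irradiated'")
  }
  if (nrow(control) != 1 || control$role != "control") {
    stop("`control` must be a single reading with role 'control'")
  }
  if (length(unique(readings$run_id)) != 1) {
    stop("replicates must all belong to one run")
  }
  corrected <- vapply(seq_len(nrow(readings)), function(i) {
    delta_od(readings$od[i], control$od, irr$t_irr_c, readings$t_read_c[i],
             coeff_irr, coeff_read)
  }, numeric(1))
  n <- length(corrected)
  m <- mean(corrected)
  type_a <- if (n >= 2) {
    100 * (stats::sd(corrected) / sqrt(n)) / abs(m)
  } else {
    NA_real_
  }
  flagged <- m <= 0
  if (flagged) {
    warning("mean corrected net OD is not positive; the derived dose will be flagged")
  }
  structure(list(value = m,
                 path_length = mean(readings$path_length_cm),
                 n_replicates = n,
                 type_a_percent = type_a,
                 flagged = flagged),
            class = "net_od")
}

#' @export
print.net_od <- function(x, ...) {
  cat(sprintf("Net OD (25 C ref): %.5f over %d replicate(s), L = %.4f cm",
              x$value, x$n_replicates, x$path_length))
  if (!is.na(x$type_a_percent)) cat(sprintf(", Type A %.3f%%", x$type_a_percent))
  if (isTRUE(x$flagged)) cat("  [FLAGGED: non-positive]")
  cat("\n")
  invisible(x)
}

#' Spectrophotometer blank and control quality check
#'
#' Verifies, before dose processing, that the pure-water blank reads
#' near zero absorbance and that the non-irradiated control has not
#' drifted above its expected baseline. Both checks use a strict `<`
#' comparison against the threshold: a reading exactly at the threshold
#' fails.
#'
#' @param blank A `cuvette_reading` with role `"water_blank"`.
#' @param control A `cuvette_reading` with role `"control"`.
#' @param threshold Absorbance threshold, default 0.01 AU (the
#'   photometric accuracy of a bench spectrophotometer).
#' @param control_baseline Expected control absorbance; drift is
#'   `|od - baseline|`. Default 0 means the raw control OD itself is
#'   compared (conservative).
#' @return A list of class `blank_qc` with the measured values, the
#'   per-check verdicts and an overall `pass` flag. Never throws.
#' @export
blank_qc <- function(blank, control, threshold = 0.01, control_baseline = 0) {
  stopifnot(threshold > 0)
  blank <- as.data.frame(blank)
  control <- as.data.frame(control)
  if (blank$role != "water_blank" || control$role != "control") {
    stop("`blank` must have role 'water_blank' and `control` role 'control'")
  }
  drift <- abs(control$od - control_baseline)
  blank_ok <- blank$od < threshold
  control_ok <- drift < threshold
  structure(list(
    blank_od = blank$od,
    control_od = control$od,
    control_drift = drift,
    threshold = threshold,
    blank_pass = blank_ok,
    control_pass = control_ok,
    pass = blank_ok && control_ok
  ), class = "blank_qc")
}

#' @export
print.blank_qc <- function(x, ...) {
  verdict <- function(ok) if (ok) "pass" else "FAIL"
  cat(sprintf("Blank QC (threshold %.3f AU):\n", x$threshold))
  cat(sprintf("  water blank OD %.4f  -> %s\n", x$blank_od, verdict(x$blank_pass)))
  cat(sprintf("  control drift  %.4f  -> %s\n", x$control_drift, verdict(x$control_pass)))
  cat("  overall:", verdict(x$pass), "\n")
  invisible(x)
}

#' Read cuvette readings from CSV
#'
#' Schema (header required): `run_id, cuvette_id, role, od,
#' path_length_cm, t_read_c` with role one of `irradiated`, `control`,
#' `water_blank`. Each row is validated through [cuvette_reading()].
#'
#' @param path CSV file path.
#' @return data.frame of validated readings.
#' @export
read_cuvette_readings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "cuvette_id", "role", "od", "path_length_cm", "t_read_c")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("readings CSV is missing columns: ", paste(missing, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    cuvette_reading(df$cuvette_id[i], df$role[i], df$od[i],
                    df$path_length_cm[i], df$t_read_c[i], df$run_id[i],
                    timestamp = if ("timestamp" %in% names(df)) df$timestamp[i] else NA)
  })
  do.call(rbind, rows)
}

#' Read irradiation records from CSV
#'
#' Schema (header required): `run_id, t_irr_c, duration_h,
#' nominal_dose_gy` with optional `s_k_u`.
#'
#' @param path CSV file path.
#' @return data.frame of validated records.
#' @export
read_irradiation_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "t_irr_c", "duration_h", "nominal_dose_gy")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("irradiation CSV is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!"s_k_u" %in% names(df)) df$s_k_u <- NA_real_
  rows <- lapply(seq_len(nrow(df)), function(i) {
    irradiation_record(df$run_id[i], df$t_irr_c[i], df$duration_h[i],
                       df$nominal_dose_gy[i], df$s_k_u[i])
  })
  do.call(rbind, rows)
}
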