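# Dose chain: net OD -> dose to the Fricke solution -> dose to water,
# the TG-43 ionometric reference, method comparison and the end-to-end
# run processor.

#' Fricke solution constants entering the OD-to-dose conversion
#'
#' @param epsilon Molar linear absorption coefficient of Fe3+ at 304 nm,
#'   L/(mol cm).
#' @param rho Solution density at 25 C, g/cm^3 (numerically equal to
#'   kg/L, the unit the dose equation needs); plausibility band
#'   [1.00, 1.05].
#' @param g A [g_value()] or a bare number in mol/J.
#' @return Object of class `fricke_constants`. Defaults reproduce the
#'   packaged values (2174, 1.023, 1.555e-6).
#' @export
fricke_constants <- function(epsilon = default_constants()$fricke$epsilon_L_per_mol_cm,
                             rho = default_constants()$fricke$density_g_per_cm3,
                             g = NULL) {
  if (is.null(g)) {
    g <- g_value(default_constants()$fricke$g_value_mol_per_J,
                 default_constants()$fricke$g_value_u_mol_per_J,
                 method = "energy_weighted")
  } else if (!inherits(g, "g_value")) {
    g <- g_value(as.numeric(g))
  }
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be positive")
  if (!is.numeric(rho) || rho < 1.00 || rho > 1.05) {
    stop("density must lie within [1.00, 1.05] g/cm^3")
  }
  structure(list(epsilon = epsilon, rho = rho, g_value = g),
            class = "fricke_constants")
}

#' Dose-to-water correction factors
#'
#' The four multiplicative corrections taking the dose in the Fricke
#' solution to the dose in water at the reference point: Fricke-to-water
#' medium conversion `f`, vessel wall perturbation `p_wall`,
#' volume-averaging `f_h` and dose-profile non-uniformity `k_dd`. Each
#' carries a standard uncertainty. Defaults are the packaged Monte Carlo
#' values 1.004(3), 0.999(4), 0.996(3), 1.000(2).
#'
#' @param f,p_wall,f_h,k_dd Central values, each within [0.9, 1.1].
#' @param u_f,u_p_wall,u_f_h,u_k_dd Standard uncertainties (absolute).
#' @return Object of class `correction_factors`.
#' @export
correction_factors <- function(f = NULL, p_wall = NULL, f_h = NULL, k_dd = NULL,
                               u_f = NULL, u_p_wall = NULL, u_f_h = NULL,
                               u_k_dd = NULL) {
  d <- default_constants()$correction_factors
  vals <- list(f = f %||% d$f$value, p_wall = p_wall %||% d$p_wall$value,
               f_h = f_h %||% d$f_h$value, k_dd = k_dd %||% d$k_dd$value)
  us <- list(f = u_f %||% d$f$u, p_wall = u_p_wall %||% d$p_wall$u,
             f_h = u_f_h %||% d$f_h$u, k_dd = u_k_dd %||% d$k_dd$u)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || v < 0.9 || v > 1.1) {
      stop(sprintf("correction factor %s = %g is outside [0.9, 1.1]", nm, v))
    }
    if (us[[nm]] < 0) stop("factor uncertainties must be non-negative")
  }
  structure(list(values = vals, u = us), class = "correction_factors")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.correction_factors <- function(x, ...) {
  cat("Dose-to-water correction factors:\n")
  for (nm in names(x$values)) {
    cat(sprintf("  %-7s %.3f +/- %.3f\n", nm, x$values[[nm]], x$u[[nm]]))
  }
  cat(sprintf("  product %.6f\n", prod(unlist(x$values))))
  invisible(x)
}

#' Source calibration for the TG-43 ionometric reference
#'
#' @param s_k Air-kerma strength in U (1 U = 1 cGy cm^2/h), positive.
#' @param delta_t Irradiation time in hours, positive.
#' @param lambda_const Dose rate constant in cGy/(h U); default is the
#'   packaged microSelectron value 1.108.
#' @param lambda_rel_u_percent Relative standard uncertainty of the dose
#'   rate constant in percent (default 0.13).
#' @return Object of class `source_calibration`.
#' @export
source_calibration <- function(s_k, delta_t,
                               lambda_const = default_constants()$tg43$lambda_cGy_per_h_per_U,
                               lambda_rel_u_percent = default_constants()$tg43$lambda_rel_u_percent) {
  if (!is.numeric(s_k) || is.na(s_k) || s_k <= 0) stop("s_k must be positive (U)")
  if (!is.numeric(delta_t) || is.na(delta_t) || delta_t < 0) {
    stop("delta_t must be non-negative (hours)")
  }
  if (lambda_const <= 0) stop("dose rate constant must be positive")
  structure(list(s_k = s_k, delta_t = delta_t, lambda_const = lambda_const,
                 lambda_rel_u_percent = lambda_rel_u_percent),
            class = "source_calibration")
}

#' Absorbed dose to the Fricke solution from a net optical density
#'
#' \deqn{D_F = \frac{\Delta OD}{\rho \, L \, \varepsilon \, G(Fe^{3+})}}
#' with the density in kg/L (numerically the g/cm^3 value), the path
#' length in cm, epsilon in L/(mol cm) and G in mol/J, so the result is
#' in gray with no hidden conversion constants.
#'
#' @param dod A `net_od` from [average_replicates()], or a bare ΔOD
#'   number (then `path_length` must be given).
#' @param constants A [fricke_constants()] bundle.
#' @param path_length Optical path length in cm, used only when `dod`
#'   is numeric.
#' @return Dose in Gy. A non-positive ΔOD yields a non-positive dose
#'   with a warning rather than an error, so QC logic downstream can
#'   flag the run.
#' @export
dose_fricke <- function(dod, constants = fricke_constants(), path_length = 1.0) {
  if (inherits(dod, "net_od")) {
    value <- dod$value
    path_length <- dod$path_length
  } else {
    value <- as.numeric(dod)
  }
  if (path_length <= 0) stop("path length must be positive")
  if (value < 0) {
    warning("net OD is negative; reporting the (unphysical) negative dose for QC")
  }
  value / (constants$rho * path_length * constants$epsilon *
             constants$g_value$value)
}

#' Absorbed dose to water from the dose to the Fricke solution
#'
#' Multiplies by the four correction factors:
#' \eqn{D_w = D_F \, f \, p_{wall} \, F_h \, k_{dd}}.
#'
#' @param d_fricke Dose in the Fricke solution, Gy.
#' @param cf A [correction_factors()] object.
#' @return Dose to water in Gy.
#' @export
dose_water_fricke <- function(d_fricke, cf = correction_factors()) {
  if (!inherits(cf, "correction_factors")) {
    stop("`cf` must be a correction_factors object")
  }
  d_fricke * prod(unlist(cf$values))
}

#' TG-43 dose to water at 1 cm from air-kerma strength
#'
#' The point form of the TG-43 formalism at the transverse reference
#' distance: dose rate is the air-kerma strength times the dose rate
#' constant, integrated over the irradiation time, converted cGy to Gy:
#' \eqn{D_w = S_k \, \Lambda \, \Delta t / 100}.
#'
#' @param cal A [source_calibration()].
#' @return Dose to water in Gy.
#' @export
dose_water_tg43 <- function(cal) {
  if (!inherits(cal, "source_calibration")) {
    stop("`cal` must be a source_calibration object")
  }
  cal$s_k * cal$lambda_const * cal$delta_t / 100
}

#' Compare Fricke-measured and TG-43 reference doses across runs
#'
#' @param results data.frame with columns `d_water` (Fricke route, Gy)
#'   and `d_water_tg43` (ionometric route, Gy); a `run_id` column is
#'   carried into the per-run table if present.
#' @return List of class `method_comparison` with the per-run ratio
#'   table, `mean_ratio`, `sd_ratio` (NA for a single pair) and
#'   residuals (d_water - d_water_tg43).
#' @export
compare_methods <- function(results) {
  results <- as.data.frame(results)
  if (nrow(results) == 0) stop("need at least one paired dose result")
  if (!all(c("d_water", "d_water_tg43") %in% names(results))) {
    stop("`results` must have columns d_water and d_water_tg43")
  }
  if (anyNA(results$d_water) || anyNA(results$d_water_tg43)) {
    stop("paired comparison requires both doses in every row")
  }
  ratio <- results$d_water / results$d_water_tg43
  per_run <- data.frame(
    run_id = if ("run_id" %in% names(results)) results$run_id else seq_len(nrow(results)),
    d_water = results$d_water,
    d_water_tg43 = results$d_water_tg43,
    ratio = ratio,
    residual_gy = results$d_water - results$d_water_tg43)
  structure(list(per_run = per_run,
                 mean_ratio = mean(ratio),
                 sd_ratio = if (length(ratio) >= 2) stats::sd(ratio) else NA_real_,
                 n = length(ratio)),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Fricke vs TG-43 over %d run(s): mean ratio %.5f", x$n, x$mean_ratio))
  if (!is.na(x$sd_ratio)) cat(sprintf(" (SD %.5f)", x$sd_ratio))
  cat("\n")
  print(format(x$per_run, digits = 6), row.names = FALSE)
  invisible(x)
}

#' Process a full set of runs from readings and irradiation records
#'
#' For each run: averages the irradiated replicates against the run's
#' control through the temperature correction, converts the net OD to
#' dose in the Fricke solution and then to dose in water, and — when the
#' run carries an air-kerma strength — computes the TG-43 reference dose
#' and the ratio of the two. The combined standard uncertainty from the
#' budget is attached to every run; when a run has replicate spread, its
#' measured Type A replaces the budget's nominal dose-determination row
#' for that run.
#'
#' @param readings data.frame in the [read_cuvette_readings()] schema.
#' @param irradiations data.frame in the [read_irradiation_records()]
#'   schema.
#' @param constants A [fricke_constants()] bundle.
#' @param cf A [correction_factors()] object.
#' @param budget An [uncertainty_budget()]; default packaged budget.
#' @param coeff_irr,coeff_read Temperature coefficients per degree C.
#' @return data.frame (one row per run): `run_id`, `delta_od`,
#'   `path_length_cm`, `n_replicates`, `type_a_percent`, `d_fricke`,
#'   `d_water`, `d_water_tg43`, `ratio`, `combined_u_percent`,
#'   `flagged`.
#' @export
process_runs <- function(readings, irradiations,
                         constants = fricke_constants(),
                         cf = correction_factors(),
                         budget = default_budget(),
                         coeff_irr = default_constants()$temperature_coefficients$irradiation_per_C,
                         coeff_read = default_constants()$temperature_coefficients$reading_per_C) {
  readings <- as.data.frame(readings)
  irradiations <- as.data.frame(irradiations)
  out <- lapply(seq_len(nrow(irradiations)), function(i) {
    irr <- irradiations[i, , drop = FALSE]
    rr <- readings[readings$run_id == irr$run_id, , drop = FALSE]
    reps <- rr[rr$role == "irradiated", , drop = FALSE]
    ctrl <- rr[rr$role == "control", , drop = FALSE]
    if (nrow(reps) == 0 || nrow(ctrl) != 1) {
      stop(sprintf(
        "run %s needs >=1 irradiated reading and exactly 1 control", irr$run_id))
    }
    nod <- average_replicates(reps, ctrl, irr, coeff_irr, coeff_read)
    d_f <- dose_fricke(nod, constants)
    d_w <- dose_water_fricke(d_f, cf)
    run_budget <- if (!is.na(nod$type_a_percent)) {
      inject_type_a(budget, "Dose determination", nod$type_a_percent)
    } else {
      budget
    }
    cu <- combine_budget(run_budget)
    if (!is.na(irr$s_k_u)) {
      cal <- source_calibration(irr$s_k_u, irr$duration_h)
      d_tg <- dose_water_tg43(cal)
      ratio <- d_w / d_tg
    } else {
      d_tg <- NA_real_
      ratio <- NA_real_
    }
    data.frame(run_id = irr$run_id, delta_od = nod$value,
               path_length_cm = nod$path_length,
               n_replicates = nod$n_replicates,
               type_a_percent = nod$type_a_percent,
               d_fricke = d_f, d_water = d_w, d_water_tg43 = d_tg,
               ratio = ratio, combined_u_percent = cu$combined_percent,
               flagged = nod$flagged, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
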