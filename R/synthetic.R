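# Synthetic experiment generator: inverts the dose chain to produce
# replicate cuvette readings with measurement-level noise, so the whole
# pipeline can be exercised end-to-end and dose recovery can be studied.

#' Measurement noise model for the generator
#'
#' Noise enters at the reading level (per-cuvette optical density), not
#' the dose level, so the Type A statistics computed downstream are
#' exercised honestly. Defaults are sized from the reading-process rows
#' of the packaged uncertainty budget at the 20 Gy reference dose; they
#' are configuration, not measured truth.
#'
#' @param od_read_sd Per-reading absorbance repeatability SD, AU.
#' @param path_sd Cuvette path-length SD around the nominal 1.0 cm, cm.
#' @param t_irr_drift_sd,t_read_drift_sd SD of the Gaussian temperature
#'   drift around 25 C during irradiation / reading, degrees C.
#' @param control_od_mean,control_od_sd Mean and between-run SD of the
#'   control-solution baseline absorbance, AU.
#' @param seed Integer seed; `NA` leaves the RNG stream untouched.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(od_read_sd = 2.7e-4, path_sd = 5e-4,
                        t_irr_drift_sd = 0.2, t_read_drift_sd = 0.2,
                        control_od_mean = 0.05, control_od_sd = 0.002,
                        seed = NA_integer_) {
  sds <- c(od_read_sd, path_sd, t_irr_drift_sd, t_read_drift_sd, control_od_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("all noise SDs must be finite and non-negative")
  }
  if (control_od_mean < 0) stop("control baseline absorbance must be non-negative")
  structure(list(od_read_sd = od_read_sd, path_sd = path_sd,
                 t_irr_drift_sd = t_irr_drift_sd,
                 t_read_drift_sd = t_read_drift_sd,
                 control_od_mean = control_od_mean,
                 control_od_sd = control_od_sd,
                 seed = seed),
            class = "noise_model")
}

#' Zero-noise model (temperatures pinned at 25 C)
#'
#' Convenience for exactness tests: every SD zero, baseline kept.
#' @param seed Optional seed (irrelevant with all SDs zero).
#' @return A [noise_model()].
#' @export
noise_free <- function(seed = NA_integer_) {
  noise_model(od_read_sd = 0, path_sd = 0, t_irr_drift_sd = 0,
              t_read_drift_sd = 0, control_od_sd = 0, seed = seed)
}

# Clamp sampled temperatures into the schema's validity band.
.clamp_temp <- function(t) pmin(pmax(t, 10), 40)

#' Simulate one irradiation run
#'
#' Works the dose chain backwards: the target dose to water is divided
#' by the correction-factor product to get the dose in the Fricke
#' solution, inverted through the OD-to-dose relation to the noiseless
#' net optical density at 25 C, then re-dressed with the two
#' temperature factors at the sampled irradiation/reading temperatures,
#' the control baseline, per-cuvette path lengths and reading noise.
#' With all noise SDs at zero the downstream pipeline recovers the true
#' dose exactly.
#'
#' @param true_dose Target dose to water in Gy; values outside the
#'   Fricke operating band [5, 400] Gy warn.
#' @param constants A [fricke_constants()] bundle.
#' @param cf A [correction_factors()] object.
#' @param noise A [noise_model()]; its `seed`, when not `NA`, is set
#'   before sampling so equal seeds give identical runs.
#' @param run_id Run identifier.
#' @param s_k Air-kerma strength in U paired with the run; the
#'   irradiation time is chosen so the TG-43 reference dose equals
#'   `true_dose`.
#' @param n_replicates Number of irradiated cuvette readings (default
#'   2, one solution volume filling two cuvettes).
#' @param coeff_irr,coeff_read Temperature coefficients per degree C.
#' @return Object of class `synthetic_experiment`: `true_dose`,
#'   `readings` (schema-valid cuvette rows: replicates + control +
#'   water blank), `irradiation` (one record) and `provenance` (noise
#'   model echo and generator version).
#' @export
simulate_run <- function(true_dose,
                         constants = fricke_constants(),
                         cf = correction_factors(),
                         noise = noise_model(),
                         run_id = "run1",
                         s_k = 40000,
                         n_replicates = 2,
                         coeff_irr = default_constants()$temperature_coefficients$irradiation_per_C,
                         coeff_read = default_constants()$temperature_coefficients$reading_per_C) {
  if (!is.numeric(true_dose) || is.na(true_dose) || true_dose <= 0) {
    stop("true dose must be positive (Gy)")
  }
  if (true_dose < 5 || true_dose > 400) {
    warning(sprintf(
      "true dose %.1f Gy is outside the Fricke operating band [5, 400] Gy",
      true_dose))
  }
  if (!inherits(noise, "noise_model")) stop("`noise` must be a noise_model")
  if (n_replicates < 1) stop("need at least one irradiated replicate")
  if (!is.na(noise$seed)) set.seed(noise$seed)

  cf_prod <- prod(unlist(cf$values))
  d_fricke <- true_dose / cf_prod
  od_per_cm <- d_fricke * constants$rho * constants$epsilon *
    constants$g_value$value

  t_irr <- .clamp_temp(25 + stats::rnorm(1, 0, noise$t_irr_drift_sd))
  baseline <- max(0, noise$control_od_mean +
                    stats::rnorm(1, 0, noise$control_od_sd))

  rep_rows <- lapply(seq_len(n_replicates), function(j) {
    L <- 1.0 + stats::rnorm(1, 0, noise$path_sd)
    t_read <- .clamp_temp(25 + stats::rnorm(1, 0, noise$t_read_drift_sd))
    od25 <- od_per_cm * L
    od <- baseline +
      od25 * (1 + coeff_irr * (t_irr - 25)) * (1 + coeff_read * (t_read - 25)) +
      stats::rnorm(1, 0, noise$od_read_sd)
    cuvette_reading(sprintf("%s_cuv%d", run_id, j), "irradiated",
                    max(0, od), L, t_read, run_id)
  })
  ctrl_t <- .clamp_temp(25 + stats::rnorm(1, 0, noise$t_read_drift_sd))
  ctrl <- cuvette_reading(
    paste0(run_id, "_ctrl"), "control",
    max(0, baseline + stats::rnorm(1, 0, noise$od_read_sd)),
    1.0 + stats::rnorm(1, 0, noise$path_sd), ctrl_t, run_id)
  blank <- cuvette_reading(
    paste0(run_id, "_blank"), "water_blank",
    max(0, stats::rnorm(1, 0, noise$od_read_sd)),
    1.0 + stats::rnorm(1, 0, noise$path_sd),
    .clamp_temp(25 + stats::rnorm(1, 0, noise$t_read_drift_sd)), run_id)

  cal <- source_calibration(s_k, true_dose * 100 / (s_k * default_constants()$tg43$lambda_cGy_per_h_per_U))
  irr <- irradiation_record(run_id, t_irr, cal$delta_t, true_dose, s_k)

  structure(list(
    true_dose = true_dose,
    readings = do.call(rbind, c(rep_rows, list(ctrl, blank))),
    irradiation = irr,
    provenance = list(noise = unclass(noise), generator = "frickedose-sim-1")
  ), class = "synthetic_experiment")
}

#' Simulate a measurement campaign over a dose grid
#'
#' Repeats [simulate_run()] over a grid of target doses with a fixed
#' number of runs per dose, pairing every run with the same source
#' calibration so the Fricke and TG-43 routes can be compared. Each run
#' draws from a deterministic sub-seed (`seed + run index`), so equal
#' campaign seeds give byte-identical output.
#'
#' @param dose_grid Doses in Gy; default spans the 14-40 Gy range of an
#'   HDR afterloader feasibility measurement.
#' @param n_runs_per_dose Runs (independent irradiations) per grid
#'   point, default 3.
#' @param seed Campaign seed (integer).
#' @param constants,cf,noise,s_k,n_replicates Passed to
#'   [simulate_run()]; the `seed` field of `noise` is overridden by the
#'   per-run sub-seed.
#' @return Object of class `synthetic_campaign`: list of experiments
#'   plus the flattened `readings`, `irradiations` and `truth` tables.
#' @export
simulate_campaign <- function(dose_grid = c(14, 20, 30, 40),
                              n_runs_per_dose = 3,
                              seed = 1L,
                              constants = fricke_constants(),
                              cf = correction_factors(),
                              noise = noise_model(),
                              s_k = 40000,
                              n_replicates = 2) {
  if (length(dose_grid) == 0 || any(dose_grid <= 0)) {
    stop("dose grid must be non-empty and positive")
  }
  if (n_runs_per_dose < 1) stop("need at least one run per dose")
  plan <- expand.grid(rep = seq_len(n_runs_per_dose), dose = dose_grid)
  experiments <- lapply(seq_len(nrow(plan)), function(i) {
    nm <- noise
    nm$seed <- as.integer(seed + i)
    simulate_run(plan$dose[i], constants, cf, nm,
                 run_id = sprintf("d%g_r%d", plan$dose[i], plan$rep[i]),
                 s_k = s_k, n_replicates = n_replicates)
  })
  readings <- do.call(rbind, lapply(experiments, `[[`, "readings"))
  irradiations <- do.call(rbind, lapply(experiments, `[[`, "irradiation"))
  truth <- data.frame(
    run_id = irradiations$run_id,
    true_dose_gy = vapply(experiments, `[[`, numeric(1), "true_dose"),
    stringsAsFactors = FALSE)
  structure(list(experiments = experiments, readings = readings,
                 irradiations = irradiations, truth = truth,
                 seed = seed),
            class = "synthetic_campaign")
}

#' Write a campaign to disk as plain-text inputs plus ground truth
#'
#' Produces `readings.csv` and `irradiations.csv` in the schemas the
#' readers expect, and `truth.json` with per-run true doses and the
#' generator provenance.
#'
#' @param campaign A [simulate_campaign()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_campaign <- function(campaign, dir) {
  if (!inherits(campaign, "synthetic_campaign")) {
    stop("`campaign` must come from simulate_campaign()")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rp <- file.path(dir, "readings.csv")
  ip <- file.path(dir, "irradiations.csv")
  tp <- file.path(dir, "truth.json")
  utils::write.csv(campaign$readings, rp, row.names = FALSE)
  utils::write.csv(campaign$irradiations, ip, row.names = FALSE)
  jsonlite::write_json(
    list(seed = campaign$seed,
         truth = campaign$truth,
         provenance = campaign$experiments[[1]]$provenance),
    tp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(readings = rp, irradiations = ip, truth = tp))
}

#' Recover doses from a synthetic campaign through the full pipeline
#'
#' Convenience wrapper: runs [process_runs()] on the campaign's tables
#' and joins the ground truth, giving one row per run with the
#' recovered dose to water next to the true dose.
#'
#' @param campaign A [simulate_campaign()] result.
#' @param ... Passed on to [process_runs()] (constants, correction
#'   factors, budget, temperature coefficients).
#' @return data.frame: the [process_runs()] columns plus `true_dose_gy`
#'   and `rel_error` (recovered/true - 1).
#' @export
recover_campaign <- function(campaign, ...) {
  res <- process_runs(campaign$readings, campaign$irradiations, ...)
  res <- merge(res, campaign$truth, by = "run_id", sort = FALSE)
  res$rel_error <- res$d_water / res$true_dose_gy - 1
  res
}
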