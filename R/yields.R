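# Radiation chemical yields: primary-species G values as a function of
# LET, the ferric-ion yield of the aerated Fricke system, unit
# conversions, LET-energy curve fitting and spectrum-weighted averaging.

# molecules per 100 eV -> mol/J: 1/(100 * e[J/eV] * N_A)
.MOL_PER_J_PER_G100EV <- 1 / (100 * 1.602176634e-19 * 6.02214076e23)

# LET range (keV/um) over which the quartic parameterisation is supported;
# outside it the evaluation still proceeds but warns.
.LET_SUPPORTED <- c(0.2, 10)

#' Radiolysis coefficient set for one primary species
#'
#' Bundles the five coefficients of the quartic polynomial in ln(LET)
#' describing how the primary yield of one water-radiolysis species (H,
#' OH or H2O2, in aerated 0.4 M H2SO4) varies with linear energy
#' transfer. Coefficients are fully expanded (no column scale factors).
#'
#' @param species One of `"H"`, `"OH"`, `"H2O2"`.
#' @param alpha Numeric vector of exactly 5 coefficients, constant term
#'   first.
#' @return An object of class `radiolysis_coefficients`.
#' @export
radiolysis_coefficients <- function(species, alpha) {
  species <- match.arg(species, c("H", "OH", "H2O2"))
  if (!is.numeric(alpha) || length(alpha) != 5L || anyNA(alpha)) {
    stop("`alpha` must be 5 finite numeric coefficients (alpha0..alpha4)")
  }
  structure(list(species = species, alpha = as.numeric(alpha)),
            class = "radiolysis_coefficients")
}

#' @export
print.radiolysis_coefficients <- function(x, ...) {
  cat("Radiolysis coefficients, G_", x$species, "(ln LET):\n", sep = "")
  cat(" ", paste(sprintf("a%d=%.6g", 0:4, x$alpha), collapse = "  "), "\n")
  invisible(x)
}

.check_let <- function(let) {
  if (!is.numeric(let) || length(let) != 1L || is.na(let) || let <= 0) {
    stop("LET must be a single strictly positive value in keV/um ",
         "(its logarithm is taken)")
  }
  if (let < .LET_SUPPORTED[1] || let > .LET_SUPPORTED[2]) {
    warning(sprintf(
      "LET = %g keV/um is outside the supported range [%g, %g]; extrapolating",
      let, .LET_SUPPORTED[1], .LET_SUPPORTED[2]))
  }
  invisible(let)
}

#' Primary-species radiolysis yield at a given LET
#'
#' Evaluates the quartic polynomial in the natural logarithm of LET,
#' \eqn{G = \sum_{i=0}^{4} \alpha_i (\ln LET)^i}, for a single primary
#' species. At LET = 1 keV/um the result is exactly the constant term.
#'
#' @param species Species tag, must match `coeffs$species`.
#' @param let LET in keV/um, strictly positive.
#' @param coeffs A [radiolysis_coefficients()] object.
#' @return Yield in molecules per 100 eV.
#' @export
primary_yield <- function(species, let, coeffs) {
  if (!inherits(coeffs, "radiolysis_coefficients")) {
    stop("`coeffs` must be a radiolysis_coefficients object")
  }
  if (!identical(coeffs$species, species)) {
    stop(sprintf("species mismatch: asked for %s, coefficients are for %s",
                 species, coeffs$species))
  }
  .check_let(let)
  x <- log(let)
  sum(coeffs$alpha * x^(0:4))
}

#' Ferric-ion yield G(Fe3+) of the aerated Fricke dosimeter at a given LET
#'
#' Combines the primary yields through the stoichiometry of the aerated
#' ferrous-sulfate system: each H atom oxidises three ferrous ions (via
#' HO2), each OH one, and each H2O2 two, so
#' \eqn{G(Fe^{3+}) = 3 G_H + G_{OH} + 2 G_{H_2O_2}}.
#'
#' @param let LET in keV/um.
#' @param coeff_set Named list with `radiolysis_coefficients` for exactly
#'   the species H, OH and H2O2. Defaults to the packaged set.
#' @return Yield in molecules per 100 eV.
#' @export
ferric_yield <- function(let, coeff_set = default_constants()$radiolysis_coefficients) {
  if (!setequal(names(coeff_set), c("H", "OH", "H2O2"))) {
    stop("`coeff_set` must cover exactly the species H, OH and H2O2")
  }
  3 * primary_yield("H", let, coeff_set$H) +
    primary_yield("OH", let, coeff_set$OH) +
    2 * primary_yield("H2O2", let, coeff_set$H2O2)
}

#' Convert a yield between molecules per 100 eV and mol/J
#'
#' `to_mol_per_joule()` multiplies by \eqn{1/(100\,e\,N_A)} =
#' 1.036427e-7; `from_mol_per_joule()` is its exact inverse.
#'
#' @param g Yield in molecules per 100 eV (or mol/J for the inverse);
#'   must be non-negative.
#' @return The yield in the other unit system.
#' @export
to_mol_per_joule <- function(g) {
  if (!is.numeric(g) || anyNA(g) || any(g < 0)) {
    stop("yield must be non-negative")
  }
  g * .MOL_PER_J_PER_G100EV
}

#' @rdname to_mol_per_joule
#' @export
from_mol_per_joule <- function(g) {
  if (!is.numeric(g) || anyNA(g) || any(g < 0)) {
    stop("yield must be non-negative")
  }
  g / .MOL_PER_J_PER_G100EV
}

#' Radiation chemical yield value with provenance
#'
#' @param value Yield in mol/J, strictly positive.
#' @param uncertainty Standard uncertainty in mol/J, or `NA`.
#' @param method How the value was obtained: `"energy_weighted"`
#'   (fluence-weighted literature average), `"let_formalism"` (quartic
#'   ln-LET model) or `"user"`.
#' @return An object of class `g_value`.
#' @export
g_value <- function(value, uncertainty = NA_real_,
                    method = c("user", "energy_weighted", "let_formalism")) {
  method <- match.arg(method)
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value <= 0) {
    stop("G value must be a single positive number (mol/J)")
  }
  if (!is.na(uncertainty) && uncertainty < 0) {
    stop("G-value uncertainty must be non-negative")
  }
  structure(list(value = value, uncertainty = uncertainty, method = method),
            class = "g_value")
}

#' @export
print.g_value <- function(x, ...) {
  cat(sprintf("G value: %.4g mol/J", x$value))
  if (!is.na(x$uncertainty)) cat(sprintf(" +/- %.2g", x$uncertainty))
  cat(" [", x$method, "]\n", sep = "")
  invisible(x)
}

#' Fit a polynomial LET-versus-energy calibration curve
#'
#' Least-squares fit of LET (keV/um) against photon energy (MeV) through
#' a small set of literature anchor points; degree 1 or 2, matching the
#' two interpolation routes used to place Ir-192 on the LET axis. With
#' exactly degree + 1 anchors the polynomial interpolates them exactly.
#'
#' @param anchors data.frame with columns `energy` (MeV, distinct) and
#'   `let` (keV/um); an optional `label` column is carried along.
#' @param degree 1 (straight line) or 2 (quadratic).
#' @return An object of class `let_curve` wrapping the `lm` fit.
#' @export
fit_let_curve <- function(anchors, degree = 1) {
  if (!is.data.frame(anchors) || !all(c("energy", "let") %in% names(anchors))) {
    stop("`anchors` must be a data.frame with columns `energy` and `let`")
  }
  if (!degree %in% c(1, 2)) stop("`degree` must be 1 or 2")
  if (anyDuplicated(anchors$energy)) {
    stop("anchor energies must be distinct")
  }
  if (any(anchors$energy <= 0) || any(anchors$let <= 0)) {
    stop("anchor energies and LET values must be positive")
  }
  if (nrow(anchors) < degree + 1) {
    stop(sprintf("need at least %d anchors for a degree-%d fit",
                 degree + 1, degree))
  }
  fit <- stats::lm(let ~ stats::poly(energy, degree, raw = TRUE),
                   data = anchors)
  structure(list(fit = fit, degree = degree, anchors = anchors),
            class = "let_curve")
}

#' @export
print.let_curve <- function(x, ...) {
  cat(sprintf("LET-energy calibration: degree-%d polynomial, %d anchors\n",
              x$degree, nrow(x$anchors)))
  cat("  coefficients:",
      paste(sprintf("%.6g", stats::coef(x$fit)), collapse = ", "), "\n")
  invisible(x)
}

#' Interpolate LET at a photon energy from a fitted calibration curve
#'
#' Evaluates a [fit_let_curve()] model; warns when the requested energy
#' lies outside the anchor range (extrapolation), and errors if the
#' predicted LET is non-positive since its logarithm is taken downstream.
#'
#' @param model A `let_curve` object.
#' @param energy Photon energy in MeV.
#' @return Predicted LET in keV/um.
#' @export
interpolate_let <- function(model, energy) {
  if (!inherits(model, "let_curve")) stop("`model` must be a let_curve fit")
  if (!is.numeric(energy) || length(energy) != 1L || is.na(energy) || energy <= 0) {
    stop("`energy` must be a single positive value in MeV")
  }
  rng <- range(model$anchors$energy)
  if (energy < rng[1] || energy > rng[2]) {
    warning(sprintf(
      "energy %g MeV is outside the anchor range [%g, %g] MeV; extrapolating",
      energy, rng[1], rng[2]))
  }
  pred <- unname(stats::predict(model$fit,
                                newdata = data.frame(energy = energy)))
  if (!is.finite(pred) || pred <= 0) {
    stop(sprintf(
      "predicted LET (%.4g keV/um) is non-positive at %g MeV; the fitted curve is unusable there",
      pred, energy))
  }
  pred
}

#' Photon-fluence-weighted average G value over an energy grid
#'
#' Computes \eqn{\sum_i w_i G_i / \sum_i w_i} where the weights are the
#' photon fluence per MeV per 100 decays of the source spectrum and the
#' G table assigns a yield to each energy bin. Weight energies are
#' matched to G-table energies by nearest bin within a tolerance
#' (default: half the 50 keV grid step).
#'
#' @param g_table data.frame with columns `energy` (MeV) and `g`
#'   (mol/J).
#' @param weights data.frame with columns `energy` (MeV) and `weight`
#'   (non-negative; at least one positive).
#' @param energy_tol Maximum |energy difference| allowed when matching a
#'   weight to its nearest G-table bin, in MeV.
#' @return A [g_value()] with method `"energy_weighted"`; the uncertainty
#'   slot is left `NA` (weights are treated as exact).
#' @export
weighted_g_value <- function(g_table, weights, energy_tol = 0.025) {
  if (!is.data.frame(g_table) || !all(c("energy", "g") %in% names(g_table)) ||
      nrow(g_table) == 0) {
    stop("`g_table` must be a non-empty data.frame with columns `energy`, `g`")
  }
  if (!is.data.frame(weights) || !all(c("energy", "weight") %in% names(weights)) ||
      nrow(weights) == 0) {
    stop("`weights` must be a non-empty data.frame with columns `energy`, `weight`")
  }
  if (any(weights$weight < 0)) stop("spectrum weights must be non-negative")
  if (sum(weights$weight) <= 0) stop("at least one spectrum weight must be positive")
  idx <- vapply(weights$energy, function(e) which.min(abs(g_table$energy - e)),
                integer(1))
  gap <- abs(g_table$energy[idx] - weights$energy)
  if (any(gap > energy_tol)) {
    stop(sprintf(
      "no G-table bin within %g MeV of weight energy %g MeV",
      energy_tol, weights$energy[which.max(gap)]))
  }
  g_value(sum(weights$weight * g_table$g[idx]) / sum(weights$weight),
          method = "energy_weighted")
}

#' Read a two-column (energy, value) CSV of anchors or spectrum weights
#'
#' @param path CSV file with a header row and two numeric columns: the
#'   first is energy in MeV, the second the value (LET or weight).
#' @param value_name Name to give the second column (`"let"` or
#'   `"weight"`).
#' @return data.frame with columns `energy` and `value_name`.
#' @export
read_energy_table <- function(path, value_name = "let") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected a two-column CSV (energy, value)")
  out <- data.frame(energy = as.numeric(df[[1]]), v = as.numeric(df[[2]]))
  names(out)[2] <- value_name
  if (anyNA(out)) stop("non-numeric entries in ", path)
  out
}
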