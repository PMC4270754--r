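# Packaged constants: loading, validation and scale expansion.

#' Load the packaged (or a user-supplied) constants file
#'
#' Reads the YAML constants bundle shipped with the package: Fricke solution
#' constants (molar absorption coefficient, density, default ferric yield),
#' the adopted LET values for Ir-192, temperature-correction coefficients,
#' the four dose-to-water correction factors and the TG-43 dose rate
#' constant, plus the quartic ln(LET) coefficients of the three primary
#' radiolysis species.
#'
#' The radiolysis coefficients are stored on their published column scales
#' (alpha1--alpha3 carry a factor 1e-2, alpha4 a factor 1e-3); this loader
#' expands them to plain dimensionless coefficients, so downstream code
#' never sees the scaled representation.
#'
#' @param path Path to a YAML constants file. Defaults to the packaged one.
#' @return A list with elements `fricke`, `let_ir192`,
#'   `temperature_coefficients`, `correction_factors`, `tg43` and
#'   `radiolysis_coefficients` (a named list of [radiolysis_coefficients()]
#'   objects with fully expanded coefficients).
#' @export
load_constants <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "constants.yaml", package = "frickedose")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("constants file not found: ", path)
  }
  raw <- yaml::read_yaml(path)
  needed <- c("fricke", "let_ir192", "temperature_coefficients",
              "correction_factors", "tg43", "radiolysis_coefficients")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("constants file is missing sections: ", paste(missing, collapse = ", "))
  }
  raw$radiolysis_coefficients <- lapply(
    names(raw$radiolysis_coefficients),
    function(sp) {
      row <- raw$radiolysis_coefficients[[sp]]
      radiolysis_coefficients(
        species = sp,
        alpha = c(row$alpha0,
                  row$alpha1_e2 * 1e-2,
                  row$alpha2_e2 * 1e-2,
                  row$alpha3_e2 * 1e-2,
                  row$alpha4_e3 * 1e-3)
      )
    }
  )
  names(raw$radiolysis_coefficients) <-
    vapply(raw$radiolysis_coefficients, function(x) x$species, character(1))
  raw
}

# Cached copy of the packaged constants (filled lazily).
.frickedose_env <- new.env(parent = emptyenv())

#' Packaged default constants
#'
#' Cached accessor for [load_constants()] on the packaged file.
#' @return See [load_constants()].
#' @export
default_constants <- function() {
  if (is.null(.frickedose_env$constants)) {
    .frickedose_env$constants <- load_constants()
  }
  .frickedose_env$constants
}
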