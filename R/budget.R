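# Declarative GUM-style uncertainty budget: Type A / Type B components
# combined in quadrature into combined (k=1) and expanded (k*u)
# uncertainties.

#' One labelled uncertainty component
#'
#' @param label Unique component name.
#' @param group Free-text grouping (e.g. "Reading Process").
#' @param type_a,type_b Relative standard uncertainties in percent;
#'   either may be `NA` (absent) but not both; each must be
#'   non-negative.
#' @param reference Free-text provenance note.
#' @return A one-row data.frame.
#' @export
budget_entry <- function(label, group = "", type_a = NA_real_,
                         type_b = NA_real_, reference = "") {
  if (is.na(type_a) && is.na(type_b)) {
    stop("entry '", label, "' must carry at least one of type_a / type_b")
  }
  if ((!is.na(type_a) && type_a < 0) || (!is.na(type_b) && type_b < 0)) {
    stop("uncertainty components must be non-negative (percent)")
  }
  data.frame(label = label, group = group, type_a = type_a, type_b = type_b,
             reference = reference, stringsAsFactors = FALSE)
}

#' Assemble an uncertainty budget
#'
#' @param entries data.frame of [budget_entry()] rows (labels unique,
#'   non-empty).
#' @param coverage_k Default coverage factor attached to the budget.
#' @return Object of class `uncertainty_budget`.
#' @export
uncertainty_budget <- function(entries, coverage_k = 1) {
  entries <- as.data.frame(entries)
  if (nrow(entries) == 0) stop("budget must contain at least one entry")
  if (anyDuplicated(entries$label)) stop("budget labels must be unique")
  if (coverage_k <= 0) stop("coverage factor must be positive")
  ok <- !(is.na(entries$type_a) & is.na(entries$type_b))
  if (!all(ok)) {
    stop("entries with neither Type A nor Type B component: ",
         paste(entries$label[!ok], collapse = ", "))
  }
  structure(list(entries = entries, coverage_k = coverage_k),
            class = "uncertainty_budget")
}

#' Read a budget file
#'
#' YAML layout: a `coverage_k` scalar and an `entries` list whose items
#' carry `label`, `group`, optional `type_a` / `type_b` (percent) and
#' `reference`.
#'
#' @param path YAML budget file; defaults to the packaged budget that
#'   reproduces the reference table for the 20 Gy dose point.
#' @return An [uncertainty_budget()].
#' @export
read_budget <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "budget.yaml", package = "frickedose")
  }
  raw <- yaml::read_yaml(path)
  rows <- lapply(raw$entries, function(e) {
    budget_entry(e$label, e$group %||% "",
                 e$type_a %||% NA_real_, e$type_b %||% NA_real_,
                 e$reference %||% "")
  })
  uncertainty_budget(do.call(rbind, rows), raw$coverage_k %||% 1)
}

#' Packaged default budget
#'
#' Cached accessor for [read_budget()] on the packaged file.
#' @return An [uncertainty_budget()].
#' @export
default_budget <- function() {
  if (is.null(.frickedose_env$budget)) {
    .frickedose_env$budget <- read_budget()
  }
  .frickedose_env$budget
}

#' Combine a budget in quadrature
#'
#' The combined relative standard uncertainty is
#' \eqn{u_c = \sqrt{\sum_j (u_{A,j}^2 + u_{B,j}^2)}} over all entries,
#' absent components counting as zero: all components are relative (%)
#' uncertainties of the final dose with unit sensitivity coefficients
#' and no correlation terms. Full precision is kept internally; rounding
#' to two decimals happens only in the print method.
#'
#' @param budget An [uncertainty_budget()].
#' @return Object of class `combined_uncertainty` with
#'   `combined_percent` (k=1), `expanded_percent` (at the budget's
#'   coverage factor), `k` and `per_entry` (label, squared contribution,
#'   share of the total variance).
#' @export
combine_budget <- function(budget) {
  if (!inherits(budget, "uncertainty_budget")) {
    stop("`budget` must be an uncertainty_budget object")
  }
  e <- budget$entries
  a2 <- ifelse(is.na(e$type_a), 0, e$type_a^2)
  b2 <- ifelse(is.na(e$type_b), 0, e$type_b^2)
  sq <- a2 + b2
  combined <- sqrt(sum(sq))
  per_entry <- data.frame(label = e$label, group = e$group,
                          squared_contribution = sq,
                          share = if (combined > 0) sq / sum(sq) else NA_real_,
                          stringsAsFactors = FALSE)
  structure(list(combined_percent = combined,
                 expanded_percent = budget$coverage_k * combined,
                 k = budget$coverage_k,
                 per_entry = per_entry),
            class = "combined_uncertainty")
}

#' Expanded uncertainty at a coverage factor
#'
#' @param cu A `combined_uncertainty` from [combine_budget()].
#' @param k Coverage factor, positive (k = 2 approximates 95% coverage
#'   for a normal distribution).
#' @return Expanded uncertainty `k * combined_percent`, in percent.
#' @export
expand_uncertainty <- function(cu, k = 2) {
  if (!inherits(cu, "combined_uncertainty")) {
    stop("`cu` must come from combine_budget()")
  }
  if (!is.numeric(k) || is.na(k) || k <= 0) stop("coverage factor must be positive")
  k * cu$combined_percent
}

#' Replace the Type A component of a named entry
#'
#' Returns a new budget in which the named entry's Type A percentage is
#' replaced by a measured value (typically the replicate
#' standard-deviation-of-the-mean from [average_replicates()]); the
#' original budget is untouched.
#'
#' @param budget An [uncertainty_budget()].
#' @param label Entry label; must exist.
#' @param percent New Type A value in percent, non-negative.
#' @return A modified copy of the budget.
#' @export
inject_type_a <- function(budget, label, percent) {
  if (!inherits(budget, "uncertainty_budget")) {
    stop("`budget` must be an uncertainty_budget object")
  }
  if (!is.numeric(percent) || is.na(percent) || percent < 0) {
    stop("injected Type A percent must be non-negative")
  }
  i <- match(label, budget$entries$label)
  if (is.na(i)) stop("no budget entry labelled '", label, "'")
  budget$entries$type_a[i] <- percent
  budget
}

#' @export
print.combined_uncertainty <- function(x, ...) {
  cat(sprintf("Combined standard uncertainty (k=1): %.2f%%\n", x$combined_percent))
  cat(sprintf("Expanded uncertainty (k=%.1f): %.2f%%\n", x$k, x$expanded_percent))
  top <- x$per_entry[order(-x$per_entry$squared_contribution), ]
  cat("Largest contributions:\n")
  n_show <- min(5L, nrow(top))
  for (i in seq_len(n_show)) {
    cat(sprintf("  %-40s %5.1f%% of variance\n", top$label[i], 100 * top$share[i]))
  }
  invisible(x)
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf("Uncertainty budget: %d entries, coverage k = %g\n",
              nrow(x$entries), x$coverage_k))
  print(x$entries[, c("label", "group", "type_a", "type_b")], row.names = FALSE)
  invisible(x)
}
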