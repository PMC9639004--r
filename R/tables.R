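#' Rate-parameter sets
#'
#' A rate-parameter set maps the free rate symbols of a scheme to
#' nonnegative first-order constants in 1/h, optionally with standard
#' errors.
#'
#' @param values Named numeric vector (symbol -> rate in 1/h), all >= 0.
#' @param se Optional named numeric vector of standard errors (1/h).
#' @return An object of class `migkin_rates`.
#' @export
rate_parameter_set <- function(values, se = NULL) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("all rate constants must be finite and >= 0")
  }
  if (!is.null(se)) {
    se <- se[names(values)]
    names(se) <- names(values)
  }
  structure(list(values = values, se = se), class = "migkin_rates")
}

#' @export
print.migkin_rates <- function(x, ...) {
  cat("<migkin_rates> (1/h)\n")
  for (s in names(x$values)) {
    if (!is.null(x$se) && is.finite(x$se[[s]])) {
      cat(sprintf("  %-12s %.4g +/- %.3g\n", s, x$values[[s]], x$se[[s]]))
    } else {
      cat(sprintf("  %-12s %.4g\n", s, x$values[[s]]))
    }
  }
  invisible(x)
}

# coerce a migkin_rates or named vector to a named vector matching a scheme
as_rate_values <- function(params, scheme = NULL) {
  v <- if (inherits(params, "migkin_rates")) params$values else params
  if (!is.numeric(v) || is.null(names(v))) {
    stop("rate parameters must be a migkin_rates object or named numeric vector")
  }
  if (!is.null(scheme)) {
    if (!setequal(names(v), scheme$rate_symbols)) {
      stop("rate parameter symbols {", paste(names(v), collapse = ", "),
           "} do not match scheme '", scheme$name, "' symbols {",
           paste(scheme$rate_symbols, collapse = ", "), "}")
    }
    v <- v[scheme$rate_symbols]
  }
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("all rate constants must be finite and >= 0")
  }
  v
}

#' Fitted rate constants for the xylan trisaccharide at pH 8
#'
#' Least-squares estimates (with standard errors) of the four rate
#' constants of the xylan scheme, fitted to NMR time courses recorded in
#' 100 mM phosphate, 10% D2O, 25 degrees C, starting pH 8: `k1` hydrolysis
#' per acetyl from the diacetylated `1a`, `k2`/`k-2` the adjacent
#' O2 <-> O3 migration pair, `k3` hydrolysis from the monoacetylated
#' `1b`/`1c`.
#'
#' @return A `migkin_rates` object (units 1/h).
#' @export
xylan_rate_constants <- function() {
  rate_parameter_set(
    values = c("k1" = 1.82e-3, "k2" = 6.33e-1, "k-2" = 3.25e-1,
               "k3" = 3.01e-3),
    se = c("k1" = 1.28e-4, "k2" = 5.32e-2, "k-2" = 3.58e-2,
           "k3" = 1.94e-4)
  )
}

#' Fitted rate constants for the glucan trisaccharide at pH 8
#'
#' Least-squares estimates (with standard errors) of the six rate
#' constants of the glucan scheme under the same conditions as
#' [xylan_rate_constants()]: `k1` the cross-unit O2 -> O6 migration from
#' the diacetylated `2a`, `k2`/`k-2` the adjacent O2 <-> O3 pair, `k3`
#' the cross-unit migration from the monoacetylated `2e`, and the
#' hydrolysis constants per primary (`k_hydr_prim`) and secondary
#' (`k_hydr_sec`) acetyl.
#'
#' @return A `migkin_rates` object (units 1/h).
#' @export
glucan_rate_constants <- function() {
  rate_parameter_set(
    values = c("k1" = 3.33e-2, "k2" = 4.92e-1, "k-2" = 4.82e-1,
               "k3" = 4.85e-3, "k_hydr_prim" = 1.35e-3,
               "k_hydr_sec" = 3.24e-3),
    se = c("k1" = 1.62e-3, "k2" = 5.46e-2, "k-2" = 4.58e-2,
           "k3" = 5.08e-4, "k_hydr_prim" = 1.55e-4,
           "k_hydr_sec" = 1.50e-4)
  )
}

#' Built-in rate constants for a scheme
#'
#' @param scheme A `migkin_scheme` or built-in scheme name.
#' @return The `migkin_rates` fixture matching the scheme.
#' @export
default_rate_constants <- function(scheme) {
  name <- if (inherits(scheme, "migkin_scheme")) scheme$name else scheme
  switch(name,
         xylan  = xylan_rate_constants(),
         glucan = glucan_rate_constants(),
         stop("no built-in rate constants for scheme '", name, "'"))
}

#' Computed formal constants of the anionic migration mechanism
#'
#' DFT-derived formal rate constants and activation free energies for the
#' four acetyl migrations of the glucan trisaccharide under the anionic
#' mechanism (three explicit water molecules), forward and reverse:
#' the cross-unit migrations (`k2`/`k-2` for the diacetylated and
#' `k10`/`k-10` for the monoacetylated substrate) and the adjacent
#' O2 <-> O3 migrations (`k4`/`k-4`, `k7`/`k-7`).  Each formal constant
#' was composed from the two elementary barriers of the stepwise
#' mechanism through the orthoester intermediate (see
#' [formal_constants()]).
#'
#' @return Data frame with columns `label`, `rate_s` (1/s) and
#'   `barrier_kcal` (kcal/mol, 298.15 K).
#' @export
anionic_mechanism_constants <- function() {
  data.frame(
    label = c("k2", "k-2", "k4", "k-4", "k7", "k-7", "k10", "k-10"),
    rate_s = c(2.68, 5.23e-5, 3.75e2, 1.10e-3, 1.07e-1, 5.28,
               1.33e-1, 7.57e-9),
    barrier_kcal = c(16.9, 23.3, 13.9, 21.5, 18.8, 16.5, 18.6, 28.5),
    stringsAsFactors = FALSE
  )
}

#' Observed rate constants of the glucan migrations at pH 8
#'
#' Experimental (from the fitted 1/h constants converted to 1/s) and
#' predicted (formal anionic-mechanism constants weighted by the computed
#' hydroxyl anion fraction at pH 8) observed rate constants with their
#' Eyring barriers, and the barrier gap `ddg = dg_pred - dg_exp`.  The two
#' reverse primary-to-secondary migrations (`k-1_obs`, `k-4_obs`) were
#' never observed experimentally; their experimental columns hold the
#' detection bound (rate < 1e-14 1/s, barrier > 36 kcal/mol) and are
#' marked not measurable, with no barrier gap.
#'
#' @return Data frame with columns `label`, `k_exp`, `dg_exp`, `k_pred`,
#'   `dg_pred` (1/s and kcal/mol), `ddg` (kcal/mol; `NA` where not
#'   measurable) and `measurable` (logical).
#' @export
observed_rate_table <- function() {
  data.frame(
    label = c("k1_obs", "k-1_obs", "k2_obs", "k-2_obs", "k3_obs",
              "k-3_obs", "k4_obs", "k-4_obs"),
    k_exp = c(9.25e-6, NA, 1.37e-4, 1.34e-4, 1.37e-4, 1.34e-4,
              1.35e-6, NA),
    dg_exp = c(24.3, NA, 22.7, 22.7, 22.7, 22.7, 25.5, NA),
    k_pred = c(1.56e-7, 2.80e-12, 2.01e-5, 2.52e-5, 8.97e-5, 6.79e-7,
               8.25e-9, 6.73e-14),
    dg_pred = c(26.7, 33.2, 23.9, 23.7, 23.0, 25.9, 28.5, 35.4),
    ddg = c(2.4, NA, 1.2, 1.0, 0.3, 3.2, 3.0, NA),
    measurable = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}
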