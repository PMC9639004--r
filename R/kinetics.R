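#' Hydroxide-concentration scale factor for pH-sensitive rate constants
#'
#' The anionic migration/hydrolysis mechanism proceeds through the
#' deprotonated hydroxyl, so in the dilute-anion regime every rate scales
#' with the hydroxide concentration `c(OH-) = 10^(ph - 14)` mol/L.  Rate
#' constants are tabulated at a reference pH (8 by default, where
#' `c(OH-) = 1e-6` mol/L); the factor returned here is
#' `c(OH)_t / c(OH)_ref = 10^(ph - reference_ph)`.
#'
#' @param ph pH value(s), in (0, 14).
#' @param reference_ph Reference pH at which constants are quoted.
#' @return Unitless multiplier(s).
#' @export
ph_scale_factor <- function(ph, reference_ph = 8) {
  if (any(!is.finite(ph)) || any(ph <= 0) || any(ph >= 14)) {
    stop("ph must lie strictly between 0 and 14")
  }
  if (reference_ph <= 0 || reference_ph >= 14) {
    stop("reference_ph must lie strictly between 0 and 14")
  }
  10^(ph - reference_ph)
}

#' pH trajectory
#'
#' Time-stamped pH measurements defining the hydroxide scaling of the rate
#' constants during a run.  Between nodes the pH is linearly interpolated;
#' beyond the last node it is held constant.
#'
#' @param times Sampling times in hours, strictly increasing, at least one.
#' @param ph pH values in (0, 14), same length as `times`.
#' @param reference_ph Reference pH of the rate constants.
#' @return An object of class `migkin_ph`.
#' @export
ph_trajectory <- function(times, ph, reference_ph = 8) {
  stopifnot(length(times) == length(ph), length(times) >= 1)
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (any(ph <= 0) || any(ph >= 14)) {
    stop("ph must lie strictly between 0 and 14")
  }
  structure(list(times = as.numeric(times), ph = as.numeric(ph),
                 reference_ph = reference_ph),
            class = "migkin_ph")
}

# split the generator into pH-sensitive and -insensitive parts, unscaled;
# A(ph) = insens + ph_scale_factor(ph) * sens
rate_matrix_parts <- function(scheme, params) {
  p <- as_rate_values(params, scheme)
  sp <- names(scheme$species)
  n <- length(sp)
  sens <- matrix(0, n, n, dimnames = list(sp, sp))
  insens <- sens
  for (i in seq_len(nrow(scheme$reactions))) {
    r <- scheme$reactions[i, ]
    k <- p[[r$rate_symbol]]
    if (isTRUE(r$ph_sensitive)) {
      sens[r$product, r$reactant] <- sens[r$product, r$reactant] + k
    } else {
      insens[r$product, r$reactant] <- insens[r$product, r$reactant] + k
    }
  }
  diag(sens) <- -colSums(sens)
  diag(insens) <- -colSums(insens)
  list(sens = sens, insens = insens)
}

#' First-order generator matrix of a scheme
#'
#' Builds the matrix `A` of the linear system `dy/dt = A y` over the
#' scheme's species (mole fractions).  Entry `(product, reactant)` is the
#' sum of the rate constants of all reactions `reactant -> product`, each
#' pH-sensitive constant multiplied by [ph_scale_factor()]; the diagonal
#' holds minus the column sums, so every column sums to zero and total
#' mole fraction is conserved.
#'
#' @param scheme A `migkin_scheme`.
#' @param params A `migkin_rates` or named numeric vector matching the
#'   scheme's rate symbols (1/h).
#' @param ph pH at which to evaluate the matrix.
#' @param reference_ph Reference pH of the constants.
#' @return Square numeric matrix (1/h) with species dimnames.
#' @export
rate_matrix <- function(scheme, params, ph = 8, reference_ph = 8) {
  parts <- rate_matrix_parts(scheme, params)
  parts$insens + ph_scale_factor(ph, reference_ph) * parts$sens
}

#' Concentration time series
#'
#' Species mole fractions versus time, either simulated or observed.
#'
#' @param times Times in hours.
#' @param values Numeric matrix, `length(times)` rows by one column per
#'   species, of mole fractions.
#' @param species Character vector of species ids (column order).
#' @return An object of class `migkin_series`.
#' @export
concentration_series <- function(times, values, species = colnames(values)) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(times), ncol(values) == length(species))
  colnames(values) <- species
  structure(list(times = as.numeric(times), values = values,
                 species = as.character(species)),
            class = "migkin_series")
}

#' @export
print.migkin_series <- function(x, ...) {
  cat("<migkin_series> ", length(x$times), " times x ",
      length(x$species), " species (",
      paste(x$species, collapse = ", "), ")\n", sep = "")
  cat("  t in [", min(x$times), ", ", max(x$times), "] h\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.migkin_series <- function(x, ...) {
  data.frame(
    time_h = rep(x$times, times = length(x$species)),
    species = rep(x$species, each = length(x$times)),
    fraction = as.vector(x$values),
    stringsAsFactors = FALSE
  )
}

#' Plot a concentration series
#'
#' Lines for each species; optionally overlays a second series (e.g.
#' observed data) as points.
#'
#' @param x A `migkin_series`.
#' @param points Optional second `migkin_series` drawn as points.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.migkin_series <- function(x, points = NULL, ...) {
  matplot(x$times, x$values, type = "l", lty = 1,
          col = seq_along(x$species), xlab = "time (h)",
          ylab = "mole fraction", ...)
  if (!is.null(points)) {
    idx <- match(points$species, x$species)
    matpoints(points$times, points$values, pch = 1, col = idx)
  }
  legend("topright", legend = x$species, col = seq_along(x$species),
         lty = 1, bty = "n")
  invisible(x)
}

#' Simulate a migration/hydrolysis scheme
#'
#' Integrates the linear first-order system `dy/dt = A(ph(t)) y` of
#' species mole fractions with a stiff implicit multistep (BDF)
#' integrator.  The pH may be a constant or a [ph_trajectory()]; between
#' trajectory nodes the pH is linearly interpolated and beyond the last
#' node held constant.  The analytic Jacobian (the generator matrix
#' itself) is supplied to the integrator.
#'
#' @param scheme A `migkin_scheme`.
#' @param params Rate constants (1/h), `migkin_rates` or named vector.
#' @param y0 Named initial mole fractions (missing species are 0); must
#'   sum to 1.
#' @param times Output times in hours, strictly increasing, starting at or
#'   after 0.  Integration always starts at t = 0.
#' @param ph Constant pH (scalar) or a `migkin_ph` trajectory.
#' @param reference_ph Reference pH of the constants (ignored when `ph` is
#'   a trajectory carrying its own).
#' @param atol,rtol Absolute and relative solver tolerances.  The tight
#'   absolute tolerance keeps the accumulated error well below the
#'   mole-fraction scale of the sparsest observable species (~1e-4).
#' @return A `migkin_series` over all scheme species at `times`.
#' @export
simulate_scheme <- function(scheme, params, y0, times, ph = 8,
                            reference_ph = 8, atol = 1e-12, rtol = 1e-8) {
  sp <- names(scheme$species)
  y <- setNames(numeric(length(sp)), sp)
  if (is.null(names(y0))) stop("y0 must be a named vector of mole fractions")
  unknown <- setdiff(names(y0), sp)
  if (length(unknown)) {
    stop("y0 names not in scheme: ", paste(unknown, collapse = ", "))
  }
  y[names(y0)] <- y0
  if (abs(sum(y) - 1) > 1e-6) stop("y0 must sum to 1")
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (times[1] < 0) stop("times must be >= 0")

  parts <- rate_matrix_parts(scheme, params)
  if (inherits(ph, "migkin_ph")) {
    phfun <- approxfun(ph$times, ph$ph, rule = 2)
    refph <- ph$reference_ph
    Afun <- function(t) {
      parts$insens + ph_scale_factor(phfun(t), refph) * parts$sens
    }
  } else {
    A0 <- parts$insens + ph_scale_factor(ph, reference_ph) * parts$sens
    Afun <- function(t) A0
  }
  deriv <- function(t, y, parms) list(Afun(t) %*% y)
  jac <- function(t, y, parms) Afun(t)

  prepend <- times[1] > 0
  tt <- if (prepend) c(0, times) else times
  out <- tryCatch(
    deSolve::ode(y = y, times = tt, func = deriv, parms = NULL,
                 method = "bdf", jacfunc = jac, jactype = "fullusr",
                 atol = atol, rtol = rtol),
    error = function(e) {
      stop("ODE solver failed on [", min(tt), ", ", max(tt), "] h: ",
           conditionMessage(e))
    }
  )
  if (nrow(out) < length(tt)) {
    stop("ODE solver stopped early at t = ", max(out[, 1]), " h (of ",
         max(tt), " h)")
  }
  vals <- out[, sp, drop = FALSE]
  if (prepend) vals <- vals[-1, , drop = FALSE]
  concentration_series(times, vals, sp)
}

#' First time a species crosses a mole-fraction threshold
#'
#' Finds the first time the species' trajectory reaches `threshold` from
#' its initial side, by linear interpolation between samples.
#'
#' @param series A `migkin_series`.
#' @param species_id Species to inspect.
#' @param threshold Mole-fraction threshold.
#' @return Crossing time in hours, or `NA` if never crossed.
#' @export
time_to_fraction <- function(series, species_id, threshold) {
  if (!species_id %in% series$species) {
    stop("unknown species id '", species_id, "'")
  }
  v <- series$values[, species_id]
  t <- series$times
  d <- v - threshold
  if (d[1] == 0) return(t[1])
  s0 <- sign(d[1])
  for (i in seq_along(d)[-1]) {
    if (sign(d[i]) != s0) {
      # linear interpolation on the bracketing interval
      return(t[i - 1] + (t[i] - t[i - 1]) * d[i - 1] / (d[i - 1] - d[i]))
    }
  }
  NA_real_
}
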