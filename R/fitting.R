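#' Bundle one observed experiment for fitting
#'
#' An experiment is one concentration time series together with the known
#' initial composition and the pH under which it was recorded.  Several
#' experiments (e.g. different starting compounds) are fitted jointly
#' with one shared parameter set.
#'
#' @param series Observed `migkin_series`; its species must be a subset of
#'   the scheme's.
#' @param y0 Named initial mole fractions (sums to 1).
#' @param ph Constant pH or a `migkin_ph` trajectory.
#' @return An object of class `migkin_experiment`.
#' @export
kinetic_experiment <- function(series, y0, ph = 8) {
  stopifnot(inherits(series, "migkin_series"))
  structure(list(series = series, y0 = y0, ph = ph),
            class = "migkin_experiment")
}

#' Residual vector of a parameter set against observed experiments
#'
#' Simulates each experiment from its own initial composition and pH and
#' returns the concatenated differences observed minus simulated over all
#' experiments, time points and observed species.  This is the vector
#' whose squared norm is the least-squares objective Q.
#'
#' @param scheme A `migkin_scheme`.
#' @param params Rate constants (1/h).
#' @param data List of `migkin_experiment` (a single experiment is
#'   wrapped automatically).
#' @param reference_ph Reference pH of the constants.
#' @return Numeric residual vector of length
#'   `sum(n_times * n_observed_species)`.
#' @export
kinetic_residuals <- function(scheme, params, data, reference_ph = 8) {
  data <- as_experiment_list(data)
  res <- lapply(data, function(ex) {
    bad <- setdiff(ex$series$species, names(scheme$species))
    if (length(bad)) {
      stop("observed species not in scheme: ", paste(bad, collapse = ", "))
    }
    sim <- simulate_scheme(scheme, params, ex$y0, ex$series$times,
                           ph = ex$ph, reference_ph = reference_ph)
    as.vector(ex$series$values - sim$values[, ex$series$species, drop = FALSE])
  })
  unlist(res, use.names = FALSE)
}

as_experiment_list <- function(data) {
  if (inherits(data, "migkin_experiment")) data <- list(data)
  if (!length(data) || !all(vapply(data, inherits, logical(1),
                                   "migkin_experiment"))) {
    stop("data must be one or a list of kinetic_experiment() objects")
  }
  data
}

#' Fit rate constants to concentration time series
#'
#' Minimises the sum of squared residuals
#' `Q = sum((observed - simulated)^2)` over the scheme's free rate
#' constants by a staged optimisation: a derivative-free Nelder-Mead
#' simplex search followed by Levenberg-Marquardt refinement
#' ([minpack.lm::nls.lm]), both operating on log-transformed parameters so
#' the constants stay positive.  All experiments are fitted jointly with
#' equal weight.
#'
#' Standard errors are asymptotic: with `J` the numerical Jacobian of the
#' residual vector with respect to the log parameters at the optimum and
#' `s2 = Q/(n - p)` the residual variance, the covariance of the log
#' parameters is `s2 (J'J)^-1`, mapped to the natural scale by the delta
#' method.  A parameter with no influence on the residuals (structurally
#' unidentifiable for the given experiments) gets an `NA` standard error.
#' The scalar `paper_style_se = s2 / sqrt(n)` is reported alongside for
#' comparability with the variance/sqrt(N) convention of older kinetic
#' software.
#'
#' @param scheme A `migkin_scheme`.
#' @param data One or a list of `migkin_experiment` objects.
#' @param init Initial rate constants (1/h), all > 0; `migkin_rates` or
#'   named vector.
#' @param stages Character vector, ordered subset of
#'   `c("simplex", "lm")`.
#' @param reference_ph Reference pH of the constants.
#' @param control List: `simplex_maxit` (default 2000), `lm_maxit`
#'   (default 200).
#' @return An object of class `migkin_fit` with elements `params`
#'   (`migkin_rates` with SEs), `objective` (Q), `degree_of_explanation`
#'   (percent), `n_observations`, `converged`, `trace` (one row per
#'   stage with Q before/after), `paper_style_se`, `residuals`.
#' @export
fit_scheme <- function(scheme, data, init,
                       stages = c("simplex", "lm"),
                       reference_ph = 8, control = list()) {
  data <- as_experiment_list(data)
  ctrl <- modifyList(list(simplex_maxit = 2000, lm_maxit = 200), control)
  stages <- match.arg(stages, c("simplex", "lm"), several.ok = TRUE)
  init_v <- as_rate_values(init, scheme)
  if (any(init_v <= 0)) stop("init must be strictly positive")
  theta <- log(init_v)

  resid_fn <- function(th) {
    kinetic_residuals(scheme, exp(th), data, reference_ph = reference_ph)
  }
  obj_fn <- function(th) sum(resid_fn(th)^2)

  trace <- data.frame(stage = character(0), q_before = numeric(0),
                      q_after = numeric(0), converged = logical(0),
                      stringsAsFactors = FALSE)
  converged <- TRUE
  for (stage in stages) {
    q0 <- obj_fn(theta)
    if (stage == "simplex") {
      opt <- optim(theta, obj_fn, method = "Nelder-Mead",
                   control = list(maxit = ctrl$simplex_maxit,
                                  reltol = 1e-12))
      theta_new <- opt$par
      ok <- opt$convergence == 0
    } else {
      opt <- minpack.lm::nls.lm(
        par = theta, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = ctrl$lm_maxit, ftol = 1e-13, ptol = 1e-13)
      )
      theta_new <- opt$par
      ok <- opt$info %in% 1:4
    }
    q1 <- obj_fn(theta_new)
    # a stage never makes the objective worse; keep the better point
    if (q1 <= q0) theta <- theta_new else q1 <- q0
    converged <- converged && ok
    trace <- rbind(trace, data.frame(stage = stage, q_before = q0,
                                     q_after = q1, converged = ok,
                                     stringsAsFactors = FALSE))
  }

  k <- exp(theta)
  res <- resid_fn(theta)
  n <- length(res)
  p <- length(theta)
  q <- sum(res^2)

  J <- numeric_jacobian(resid_fn, theta)
  se <- rep(NA_real_, p)
  col_norm <- sqrt(colSums(J^2))
  identifiable <- col_norm > max(col_norm, 1) * 1e-10
  if (n > p && any(identifiable)) {
    Ji <- J[, identifiable, drop = FALSE]
    s2 <- q / (n - p)
    cov_theta <- tryCatch(s2 * solve(crossprod(Ji)),
                          error = function(e) NULL)
    if (!is.null(cov_theta)) {
      se[identifiable] <- sqrt(pmax(diag(cov_theta), 0))
    }
  }
  se_nat <- se * k  # delta method: d k / d log k = k

  observed <- unlist(lapply(data, function(ex) as.vector(ex$series$values)))
  fitted_vals <- observed - res
  doe <- degree_of_explanation(observed, fitted_vals)

  structure(
    list(
      params = rate_parameter_set(setNames(k, names(init_v)),
                                  se = setNames(se_nat, names(init_v))),
      objective = q,
      degree_of_explanation = doe,
      n_observations = n,
      converged = converged,
      trace = trace,
      paper_style_se = (q / max(n - p, 1)) / sqrt(n),
      residuals = res,
      scheme = scheme$name
    ),
    class = "migkin_fit"
  )
}

#' @export
print.migkin_fit <- function(x, ...) {
  cat("<migkin_fit> scheme '", x$scheme, "'\n", sep = "")
  print(x$params)
  cat(sprintf("  Q = %.4g over %d observations\n", x$objective,
              x$n_observations))
  cat(sprintf("  degree of explanation: %.2f%%\n", x$degree_of_explanation))
  cat("  converged: ", x$converged, "\n", sep = "")
  for (i in seq_len(nrow(x$trace))) {
    cat(sprintf("    stage %-8s Q %.4g -> %.4g\n", x$trace$stage[i],
                x$trace$q_before[i], x$trace$q_after[i]))
  }
  invisible(x)
}

# central-difference Jacobian of a vector-valued function
numeric_jacobian <- function(fn, x, eps = 1e-6) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

#' Degree of explanation of a fit
#'
#' R-squared-type statistic in percent:
#' `100 * (1 - SS_res / SS_tot)` with `SS_tot` taken about the grand mean
#' of all observed values (the convention of classical kinetic-fitting
#' software; set `per_species_mean = TRUE` to centre each column of a
#' matrix input on its own mean instead).
#'
#' @param observed,fitted Numeric vectors or matrices of equal shape with
#'   at least 2 observations.
#' @param per_species_mean Centre per column instead of on the grand mean.
#' @return Percent of explained variance (at most 100; can be negative).
#' @export
degree_of_explanation <- function(observed, fitted,
                                  per_species_mean = FALSE) {
  if (length(observed) != length(fitted)) {
    stop("observed and fitted must have equal shapes")
  }
  if (length(observed) < 2) stop("need at least 2 observations")
  ss_res <- sum((observed - fitted)^2)
  if (per_species_mean && is.matrix(observed)) {
    centred <- sweep(observed, 2, colMeans(observed))
    ss_tot <- sum(centred^2)
  } else {
    ss_tot <- sum((observed - mean(observed))^2)
  }
  if (ss_tot == 0) {
    stop("degree of explanation undefined: observations have zero variance")
  }
  100 * (1 - ss_res / ss_tot)
}
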