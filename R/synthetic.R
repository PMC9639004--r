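#' Default NMR-like sampling schedule
#'
#' Fifteen sampling times front-loaded over the first 24 h (where the
#' adjacent O2 <-> O3 migration equilibrates within about 3 h) and then
#' roughly log-spaced out to the end of the run, matching the two time
#' scales of the migration/hydrolysis dynamics.
#'
#' @param t_end Last sampling time in hours.
#' @return Numeric vector of 15 strictly increasing times starting at 0.
#' @export
default_sampling_times <- function(t_end = 400) {
  early <- c(0, 0.5, 1, 2, 3, 6, 12, 24)
  late <- exp(seq(log(40), log(t_end), length.out = 7))
  round(c(early, late), 2)
}

#' Specification of a synthetic migration experiment set
#'
#' Describes how to emulate the NMR migration study on a built-in scheme:
#' which rate constants are "true", which starting compounds are run, the
#' sampling schedule, the observation-noise level, and the pH model.
#' Defaults mirror the study design on the fixtures: both starting
#' compounds of the scheme (pure `1a` and `1b` for xylan, pure `2a` and
#' `2e` for glucan), 15 samples to 400 h (xylan) or 336 h (glucan),
#' additive Gaussian noise of sd 0.01 on mole fractions, constant pH 8.
#'
#' @param scheme `"xylan"`, `"glucan"`, or a `migkin_scheme`.
#' @param true_params True rate constants; defaults to
#'   [default_rate_constants()] for the scheme.
#' @param starts Character vector of starting species (one experiment
#'   each, initialised pure).
#' @param times Sampling times in hours.
#' @param noise_sd Standard deviation of the additive Gaussian
#'   observation noise (mole-fraction units), >= 0.
#' @param ph Constant pH (scalar) or a `migkin_ph` trajectory, e.g. a
#'   slow drift from 8 to 7.5 to exercise the hydroxide correction.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `migkin_synth_spec`.
#' @export
synthetic_spec <- function(scheme = c("xylan", "glucan"),
                           true_params = NULL, starts = NULL,
                           times = NULL, noise_sd = 0.01, ph = 8,
                           seed = 1) {
  if (is.character(scheme)) scheme <- match.arg(scheme)
  scheme <- get_scheme(scheme)
  if (is.null(true_params)) true_params <- default_rate_constants(scheme)
  if (is.null(starts)) {
    starts <- switch(scheme$name,
                     xylan = c("1a", "1b"),
                     glucan = c("2a", "2e"),
                     names(scheme$species)[1])
  }
  if (is.null(times)) {
    t_end <- switch(scheme$name, glucan = 336, 400)
    times <- default_sampling_times(t_end)
  }
  stopifnot(noise_sd >= 0, all(diff(times) > 0))
  structure(
    list(scheme = scheme, true_params = true_params, starts = starts,
         times = as.numeric(times), noise_sd = noise_sd, ph = ph,
         seed = as.integer(seed)),
    class = "migkin_synth_spec"
  )
}

#' Generate synthetic NMR-like concentration time series
#'
#' Simulates every experiment of the spec under the true parameters, adds
#' i.i.d. Gaussian noise (sd `noise_sd`) to each mole fraction, clips to
#' \[0, 1\] and renormalises each time point to sum to 1.  Deterministic
#' for a fixed spec (the seed is applied locally and the caller's RNG
#' state is restored).
#'
#' @param spec A [synthetic_spec()].
#' @return List of `migkin_experiment` objects (one per starting
#'   compound), with the true parameters attached as attribute `truth`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "migkin_synth_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)
  out <- lapply(spec$starts, function(start) {
    y0 <- setNames(1, start)
    sim <- simulate_scheme(spec$scheme, spec$true_params, y0, spec$times,
                           ph = spec$ph)
    vals <- sim$values
    if (spec$noise_sd > 0) {
      vals <- vals + matrix(rnorm(length(vals), sd = spec$noise_sd),
                            nrow = nrow(vals))
      vals <- pmin(pmax(vals, 0), 1)
      vals <- vals / rowSums(vals)
    }
    kinetic_experiment(
      concentration_series(spec$times, vals, sim$species),
      y0 = y0, ph = spec$ph
    )
  })
  attr(out, "truth") <- spec$true_params
  out
}

#' Parameter-recovery study on synthetic data
#'
#' Runs `generate -> fit` for `n_replicates` independent noise
#' realisations (seeds `seed, seed+1, ...`) and summarises how well each
#' rate constant is recovered.  Fit failures are collected, not fatal.
#'
#' @param spec A [synthetic_spec()].
#' @param n_replicates Number of replicates, >= 1.
#' @param init_factor Multiplier applied to the true constants to form the
#'   fit's initial guess (default 2).
#' @param stages Optimizer stages passed to [fit_scheme()].
#' @return An object of class `migkin_recovery`: data frame `summary`
#'   (per symbol: truth, median estimate, median/IQR of the signed
#'   relative error, median absolute relative error), matrix `estimates`
#'   (replicate x symbol), `n_failed`, and the spec.
#' @export
recovery_experiment <- function(spec, n_replicates = 20, init_factor = 2,
                                stages = c("simplex", "lm")) {
  stopifnot(n_replicates >= 1)
  truth <- as_rate_values(spec$true_params, spec$scheme)
  init <- truth * init_factor
  est <- matrix(NA_real_, n_replicates, length(truth),
                dimnames = list(NULL, names(truth)))
  failures <- character(0)
  for (i in seq_len(n_replicates)) {
    spec_i <- spec
    spec_i$seed <- spec$seed + i - 1L
    fit <- tryCatch(
      fit_scheme(spec$scheme, generate_synthetic(spec_i), init,
                 stages = stages),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", i,
                                      conditionMessage(fit)))
    } else {
      est[i, ] <- fit$params$values[names(truth)]
    }
  }
  rel <- sweep(est, 2, truth, "/") - 1
  summary <- data.frame(
    symbol = names(truth),
    truth = unname(truth),
    median_estimate = apply(est, 2, median, na.rm = TRUE),
    median_rel_error = apply(rel, 2, median, na.rm = TRUE),
    iqr_rel_error = apply(rel, 2, function(x)
      diff(quantile(x, c(0.25, 0.75), na.rm = TRUE))),
    median_abs_rel_error = apply(abs(rel), 2, median, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(summary = summary, estimates = est, n_failed = length(failures),
         failures = failures, spec = spec),
    class = "migkin_recovery"
  )
}

#' @export
print.migkin_recovery <- function(x, ...) {
  cat("<migkin_recovery> scheme '", x$spec$scheme$name, "', ",
      nrow(x$estimates), " replicates (", x$n_failed, " failed), ",
      "noise sd ", x$spec$noise_sd, "\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}
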