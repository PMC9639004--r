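# Matrix-exponential reference solution for a constant-pH linear system;
# independent of the BDF path exercised by simulate_scheme().
expm_solution <- function(scheme, params, y0, times, ph = 8) {
  A <- rate_matrix(scheme, params, ph)
  y <- stats::setNames(numeric(length(scheme$species)),
                       names(scheme$species))
  y[names(y0)] <- y0
  t(vapply(times, function(t) {
    as.numeric(Matrix::expm(A * t) %*% y)
  }, numeric(length(y))))
}

# random strictly positive rate draw for a scheme (log-uniform)
random_rates <- function(scheme, lo = 1e-3, hi = 1) {
  k <- exp(stats::runif(length(scheme$rate_symbols), log(lo), log(hi)))
  stats::setNames(k, scheme$rate_symbols)
}
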