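test_that("ph_scale_factor is the relative hydroxide concentration", {
  expect_equal(ph_scale_factor(8, 8), 1.0)
  expect_equal(ph_scale_factor(7, 8), 0.1)
  expect_equal(ph_scale_factor(9, 8), 10.0)
  expect_error(ph_scale_factor(0), "between 0 and 14")
  expect_error(ph_scale_factor(14.5), "between 0 and 14")
})

test_that("rate_matrix builds a conservative generator", {
  s <- build_xylan_scheme()
  zero <- setNames(rep(0, 4), s$rate_symbols)
  expect_true(all(rate_matrix(s, zero) == 0))

  # columns sum to zero (total mole fraction conserved) for any draw
  set.seed(7)
  for (scheme in list(s, build_glucan_scheme())) {
    for (ph in c(7, 8, 9)) {
      A <- rate_matrix(scheme, random_rates(scheme), ph)
      expect_lt(max(abs(colSums(A))), 1e-14)
      expect_true(all(A[row(A) != col(A)] >= 0))
    }
  }

  # the monoacetylated -> deacetylated hydrolysis entry carries k3
  A <- rate_matrix(s, xylan_rate_constants(), ph = 8)
  expect_equal(A["1d", "1b"], 3.01e-3)
  expect_error(rate_matrix(s, c(k1 = 1)), "do not match")
})

test_that("simulation matches the matrix-exponential solution", {
  set.seed(11)
  times <- c(0, 0.5, 2, 5, 20, 50)
  for (scheme in list(build_xylan_scheme(), build_glucan_scheme())) {
    start <- names(scheme$species)[1]
    for (rep in 1:10) {
      p <- random_rates(scheme)
      sim <- simulate_scheme(scheme, p, setNames(1, start), times)
      ref <- expm_solution(scheme, p, setNames(1, start), times)
      big <- abs(ref) >= 1e-4
      expect_lt(max(abs(sim$values[big] - ref[big]) / abs(ref[big])), 1e-6)
      expect_lt(max(abs(sim$values[!big] - ref[!big])), 1e-8)
    }
  }
})

test_that("mole fractions are conserved and the terminal species grows", {
  set.seed(3)
  times <- seq(0, 400, by = 10)
  for (scheme in list(build_xylan_scheme(), build_glucan_scheme())) {
    terminal <- names(which(acetyl_counts(scheme) == 0))
    sim <- simulate_scheme(scheme, default_rate_constants(scheme),
                           setNames(1, names(scheme$species)[1]), times)
    expect_lt(max(abs(rowSums(sim$values) - 1)), 1e-8)
    expect_true(all(diff(sim$values[, terminal]) >= -1e-10))
    expect_true(all(sim$values >= -1e-8 & sim$values <= 1 + 1e-8))
  }
})

test_that("all rates zero freezes the state", {
  s <- build_xylan_scheme()
  zero <- setNames(rep(0, 4), s$rate_symbols)
  y0 <- c("1a" = 0.4, "1b" = 0.6)
  sim <- simulate_scheme(s, zero, y0, c(1, 10, 100))
  expect_equal(sim$values[, "1a"], rep(0.4, 3), tolerance = 1e-12)
  expect_equal(sim$values[, "1b"], rep(0.6, 3), tolerance = 1e-12)
})

test_that("raising the pH never slows the approach to equilibrium", {
  # all channels scale by the same hydroxide factor, so trajectories are
  # time-rescaled: 1b (starting pure) decays towards its equilibrium
  # share strictly faster at higher pH
  s <- build_xylan_scheme()
  p <- xylan_rate_constants()
  times <- seq(0, 6, by = 0.5)
  crossings <- vapply(c(7.5, 8, 8.5), function(ph) {
    sim <- simulate_scheme(s, p, c("1b" = 1), times, ph = ph)
    time_to_fraction(sim, "1b", 0.5)
  }, numeric(1))
  expect_true(all(diff(crossings) < 0))
})

test_that("a measured pH drift modulates the rates", {
  s <- build_xylan_scheme()
  p <- xylan_rate_constants()
  times <- seq(0, 48, by = 2)
  drift <- ph_trajectory(c(0, 48), c(8, 7.5))
  sim_const <- simulate_scheme(s, p, c("1b" = 1), times, ph = 8)
  sim_drift <- simulate_scheme(s, p, c("1b" = 1), times, ph = drift)
  # falling pH slows hydrolysis: more total acetyl retained
  n <- acetyl_counts(s)
  expect_gt(sum(sim_drift$values[25, ] * n), sum(sim_const$values[25, ] * n))
  expect_lt(max(abs(rowSums(sim_drift$values) - 1)), 1e-8)
  # beyond the last node the pH is held, matching a constant-pH run
  hold <- ph_trajectory(c(0, 1), c(8, 8))
  sim_hold <- simulate_scheme(s, p, c("1b" = 1), times, ph = hold)
  expect_equal(sim_hold$values, sim_const$values, tolerance = 1e-7)
})

test_that("time_to_fraction finds the first interpolated crossing", {
  flat <- concentration_series(0:10, matrix(1, 11, 1), "x")
  expect_true(is.na(time_to_fraction(flat, "x", 0.5)))
  expect_error(time_to_fraction(flat, "nope", 0.5), "unknown species")

  # single-exponential decay crosses one half at ln(2)/r
  r <- 0.23
  t <- seq(0, 20, by = 0.05)
  dec <- concentration_series(t, matrix(exp(-r * t), ncol = 1), "x")
  expect_equal(time_to_fraction(dec, "x", 0.5), log(2) / r,
               tolerance = 1e-4)
})
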