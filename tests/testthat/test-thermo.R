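test_that("Eyring conversions invert each other and match known values", {
  # prefactor k_B T / h at 25 C
  expect_equal(eyring_rate(0), 6.21e12, tolerance = 1e-3)
  # a 13.9 kcal/mol barrier corresponds to ~3.9e2 1/s (within the
  # rounding of the printed one-decimal barrier)
  expect_equal(eyring_rate(13.9), 3.9e2, tolerance = 0.05)
  expect_equal(round(eyring_barrier(eyring_rate(13.9)), 1), 13.9)
  expect_equal(eyring_barrier(3.75e2), 13.9, tolerance = 0.005)
  expect_equal(eyring_barrier(7.57e-9), 28.5, tolerance = 0.005)
  expect_equal(eyring_barrier(9.25e-6), 24.3, tolerance = 0.005)
  for (x in c(5, 15, 25, 35)) {
    expect_equal(eyring_barrier(eyring_rate(x)), x, tolerance = 1e-10)
  }
  expect_error(eyring_barrier(0), "> 0")
})

test_that("every tabulated (rate, barrier) pair is Eyring-consistent", {
  t3 <- anionic_mechanism_constants()
  expect_identical(nrow(t3), 8L)
  expect_lt(max(abs(eyring_barrier(t3$rate_s) - t3$barrier_kcal)), 0.1)

  t4 <- observed_rate_table()
  meas <- t4[t4$measurable, ]
  expect_lt(max(abs(eyring_barrier(meas$k_exp) - meas$dg_exp)), 0.1)
  expect_lt(max(abs(eyring_barrier(t4$k_pred) - t4$dg_pred)), 0.1)
})

test_that("pKa from free energies follows the thermodynamic cycle", {
  # constructed null: anion - neutral difference exactly cancels the
  # proton free energy and standard-state correction
  expect_equal(pka_from_free_energies(0, 264.01), 0, tolerance = 1e-10)
  # hand arithmetic: dG = 282 - 264.01 = 17.99 kcal/mol -> pKa ~ 13.2
  expect_equal(pka_from_free_energies(0, 282.0), 13.19, tolerance = 1e-3)
  # linear in the free-energy difference with slope 1/(ln 10 R T)
  slope <- 1 / (log(10) * thermo_constants()$gas_constant_kcal * 298.15)
  d <- pka_from_free_energies(0, 283) - pka_from_free_energies(0, 282)
  expect_equal(d, slope, tolerance = 1e-12)
  # a 1.9 kcal/mol DFT error maps to ~1.4 pKa units
  expect_equal(pka_uncertainty(1.9), 1.4, tolerance = 0.01)
  # hartree inputs are converted
  expect_equal(
    pka_from_free_energies(0, 282 / 627.5095, unit = "hartree"),
    pka_from_free_energies(0, 282), tolerance = 1e-9)
})

test_that("formal constants collapse the stepwise mechanism correctly", {
  expect_equal(formal_constants(2, 1, 1, 2),
               c(k_forward = 1, k_reverse = 1))
  # fast breakdown limit: formation becomes rate-determining
  fc <- formal_constants(0.3, 1e-4, 1e4, 0.2)
  expect_equal(unname(fc["k_forward"]), 0.3, tolerance = 1e-6)

  # eigen-oracle: for a low-populated intermediate the slowest nonzero
  # relaxation rate of the full 3-state system is k_forward + k_reverse
  set.seed(5)
  for (rep in 1:5) {
    ka <- runif(1, 0.1, 1); kmb <- runif(1, 0.1, 1)
    kma <- runif(1, 50, 100); kb <- runif(1, 50, 100)
    M <- matrix(c(-ka,  kma,        0,
                  ka, -(kma + kb),  kmb,
                  0,   kb,         -kmb), 3, 3, byrow = TRUE)
    lam <- sort(abs(Re(eigen(M)$values)))
    slow <- lam[2]  # lam[1] ~ 0 (conservation)
    fc <- formal_constants(ka, kma, kb, kmb)
    expect_equal(unname(sum(fc)), slow, tolerance = 0.02)
  }
})

test_that("observed rates follow the anion fraction of the hydroxyl", {
  expect_equal(observed_rate(1.0, 8, 8), 0.5)
  expect_equal(observed_rate(1.0, 13, 8), 1e-5, tolerance = 1e-4)
  # strictly increasing in pH and bounded by the formal constant
  ph <- seq(4, 13, by = 0.5)
  k <- vapply(ph, function(p) observed_rate(2.68, 13.1, p), numeric(1))
  expect_true(all(diff(k) > 0))
  expect_true(all(k < 2.68))
  # inverting the pH 8 prediction for the adjacent migration gives a
  # plausible sugar-hydroxyl pKa
  pka <- 8 - log10(2.01e-5 / (2.68 - 2.01e-5))
  expect_gt(pka, 12.5)
  expect_lt(pka, 13.7)
})

test_that("rate constants convert exactly between 1/h and 1/s", {
  expect_equal(rate_unit_convert(3.33e-2, "h-1", "s-1"), 9.25e-6)
  expect_equal(signif(rate_unit_convert(4.92e-1, "h-1", "s-1"), 3), 1.37e-4)
  expect_equal(rate_unit_convert(1, "s-1", "h-1"), 3600)
  expect_equal(rate_unit_convert(5, "s-1", "s-1"), 5)
  expect_error(rate_unit_convert(1, "min-1", "s-1"), "units")
})

test_that("barrier_gap compares records recomputed through Eyring", {
  a <- thermo_record("k1_obs", 9.25e-6, kind = "observed")
  expect_equal(barrier_gap(a, a), 0)
  b <- thermo_record("k1_obs", 1.56e-7, kind = "predicted_observed")
  expect_equal(barrier_gap(a, b), 2.4, tolerance = 0.05)
  wrong <- thermo_record("k2_obs", 1.56e-7, kind = "predicted_observed")
  expect_error(barrier_gap(a, wrong), "labels differ")
})
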