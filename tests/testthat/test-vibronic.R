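test_that("Huang-Rhys factor matches the full SI-unit oracle", {
  # independent arithmetic: 2*pi*c*omega * (amu A^2) / (2*hbar), inline
  oracle <- function(omega, dq) {
    hbar <- 6.62607015e-34 / (2 * pi)
    (2 * pi * 2.99792458e10 * omega) *
      (dq^2 * 1.66053906660e-27 * 1e-20) / (2 * hbar)
  }
  expect_equal(huang_rhys(1000, 1), oracle(1000, 1), tolerance = 1e-12)
  expect_equal(huang_rhys(1000, 1), 14.83, tolerance = 1e-3)
  expect_equal(huang_rhys(2149, 0.5), oracle(2149, 0.5), tolerance = 1e-12)
  expect_identical(huang_rhys(750, 0), 0)
  expect_error(huang_rhys(-5, 1), "positive")
})

test_that("delta_q_from_huang_rhys is the exact algebraic inverse", {
  for (omega in c(300, 1000, 2149, 3500)) {
    for (s in c(0.01, 0.5, 1.978, 5)) {
      dq <- delta_q_from_huang_rhys(omega, s)
      expect_equal(huang_rhys(omega, dq), s, tolerance = 1e-10)
    }
  }
})

test_that("per-mode reorganization energies reproduce the published HCN rows", {
  expect_equal(round(mode_reorg_energy(2149, 1.978), 3), 0.527)
  expect_equal(round(mode_reorg_energy(1704, 1.594), 3), 0.337)
  expect_equal(round(mode_reorg_energy(3500, 0.084), 3), 0.036)
  expect_identical(mode_reorg_energy(2149, 0), 0)
})

test_that("adiabatic four-point energies partition and validate", {
  r <- adiabatic_reorg(e_n = -100, e_n_rel = -99.7,
                       e_c = -99, e_c_rel = -98.8)
  expect_equal(r$lambda_n, 0.3)
  expect_equal(r$lambda_c, 0.2)
  expect_equal(r$lambda_i, r$lambda_n + r$lambda_c)
  expect_equal(adiabatic_reorg(-100, -100, -99, -98.8)$lambda_n, 0)
  expect_error(adiabatic_reorg(-100, -100.1, -99, -98.8), "negative")
})

test_that("single-mode quadratic pair: adiabatic relaxation equals hbar*omega*S", {
  omega <- 1000; dq <- 0.3
  s <- huang_rhys(omega, dq)
  e_relax <- quadratic_relaxation_energy_eV(omega, dq)
  expect_equal(e_relax, mode_reorg_energy(omega, s), tolerance = 1e-10)
  r <- adiabatic_reorg(0, e_relax, 0, e_relax)
  expect_equal(r$lambda_n, mode_reorg_energy(omega, s), tolerance = 1e-10)
  expect_equal(r$lambda_i, 2 * mode_reorg_energy(omega, s),
               tolerance = 1e-10)
})

test_that("Table 1 per-mode sums give the HCN reorganization energies", {
  t1 <- table1_hcn()
  expect_equal(sum(t1$neutral$lambda_eV), 0.563, tolerance = 1e-12)
  expect_equal(sum(t1$anionic$lambda_eV), 0.350, tolerance = 1e-12)
  expect_equal(sum(t1$neutral$lambda_eV) + sum(t1$anionic$lambda_eV),
               0.913, tolerance = 1e-12)
})

test_that("activation energy follows the Jortner parabola", {
  # activationless channel at upsilon = S
  expect_equal(activation_energy(2149, 1.978, 1.978), 0)
  # direct evaluation of hbar*omega*(u-S)^2/(4S) at one phonon
  expect_equal(activation_energy(2149, 1.978, 1), 0.0322, tolerance = 1e-3)
  # parabola is symmetric about upsilon = S
  expect_equal(activation_energy(1704, 1.594, 2 * 1.594),
               activation_energy(1704, 1.594, 0), tolerance = 1e-12)
  expect_error(activation_energy(1000, 0, 1), "singular")
})

test_that("phonon estimate rounds half away from zero", {
  expect_identical(phonon_estimate(1.978), 2L)
  expect_identical(phonon_estimate(1.594), 2L)
  expect_identical(phonon_estimate(0), 0L)
  expect_identical(phonon_estimate(0.5), 1L)
  expect_identical(phonon_estimate(2.5), 3L)
})

test_that("build_mode_table recovers the fixture's analytic Huang-Rhys factor", {
  fx <- make_displaced_diatomic(1, 1, 1000, 0.25)
  tb <- build_mode_table(fx$neutral, fx$charged, "neutral")
  expect_equal(nrow(tb), 1L)
  expect_equal(tb$huang_rhys, fx$expected_s, tolerance = 1e-8)

  same <- build_mode_table(fx$neutral, fx$neutral, "neutral")
  expect_equal(same$huang_rhys, 0)
})

test_that("isotope substitution rescales the diatomic per the closed form", {
  # same force field: k = mu * omega^2 fixed; H -> D doubles m1
  m_h <- 1.00783; m_d <- 2.0141; m2 <- 19
  mu_h <- m_h * m2 / (m_h + m2); mu_d <- m_d * m2 / (m_d + m2)
  omega_h <- 3000
  omega_d <- omega_h * sqrt(mu_h / mu_d)
  dr <- 0.09
  fx_h <- make_displaced_diatomic(m_h, m2, omega_h, dr)
  fx_d <- make_displaced_diatomic(m_d, m2, omega_d, dr)
  s_h <- build_mode_table(fx_h$neutral, fx_h$charged, "neutral")$huang_rhys
  s_d <- build_mode_table(fx_d$neutral, fx_d$charged, "neutral")$huang_rhys
  # S = omega * mu * dr^2 / (2 hbar): ratio follows omega*mu
  expect_equal(s_d / s_h, (omega_d * mu_d) / (omega_h * mu_h),
               tolerance = 1e-8)
})

test_that("S is strictly monotone in |delta_q| at fixed frequency", {
  dqs <- seq(0, 2, by = 0.25)
  s <- huang_rhys(1500, dqs)
  expect_true(all(diff(s) > 0))
})

test_that("parameter recovery: the full pipeline returns prescribed per-mode S", {
  s_targets <- c(0.5, 1.0, 2.0, 0.25, 0, 1.3, 0.8, 0.05, 1.9)
  for (seed in c(1, 17, 102)) {
    p <- make_random_polyatomic(5, seed, s_targets)
    for (basis in c("neutral", "charged")) {
      tb <- build_mode_table(p$neutral, p$charged, basis)
      expect_equal(tb$huang_rhys, s_targets, tolerance = 1e-8)
    }
  }
})

test_that("harmonic partition identity holds on synthetic quadratic pairs", {
  set.seed(33)
  s_targets <- runif(9, 0, 2)
  p <- make_random_polyatomic(5, 33, s_targets)
  tb <- build_mode_table(p$neutral, p$charged, "neutral")
  mode_sum <- sum(tb$lambda_eV)
  adiabatic <- quadratic_relaxation_energy_eV(p$neutral$frequencies_cm1,
                                              p$delta_q)
  expect_equal(mode_sum, adiabatic, tolerance = 1e-10)
})

test_that("reorg_summary aggregates both bases and the four-point energies", {
  fx <- make_displaced_diatomic(1, 14, 2000, 0.15)
  lam <- mode_reorg_energy(2000, fx$expected_s)
  n <- fx$neutral; c <- fx$charged
  n$energy_eV <- 0;   n$energy_at_other_minimum_eV <- lam
  c$energy_eV <- 1.5; c$energy_at_other_minimum_eV <- 1.5 + lam
  r <- reorg_summary(n, c)
  expect_equal(r$lambda_n, lam, tolerance = 1e-8)
  expect_equal(r$lambda_c, lam, tolerance = 1e-8)
  expect_equal(r$lambda_i, r$adiabatic$lambda_i, tolerance = 1e-8)
})
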