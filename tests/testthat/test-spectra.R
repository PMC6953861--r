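test_that("stick spectra carry Poisson weights and the 0-0 product line", {
  t1 <- table1_hcn()
  st <- stick_spectrum(t1$anionic, upsilon_max = 5)
  zero <- st[st$upsilon == 0, ]
  expect_equal(nrow(zero), 1L)
  expect_equal(zero$weight, exp(-sum(t1$anionic$huang_rhys)),
               tolerance = 1e-12)
  cn <- st[st$mode_index == 2 & st$upsilon > 0, ]
  expect_equal(cn$position_cm1, 1704 * (1:5))
  expect_equal(cn$weight, fcf_poisson(1.594, 1:5), tolerance = 1e-12)

  # a zero-coupling table produces only the 0-0 line
  quiet <- mode_table(c(500, 1500), c(0, 0), state_basis = "charged")
  st0 <- stick_spectrum(quiet)
  expect_equal(nrow(st0), 1L)
  expect_equal(st0$position_cm1, 0)

  fund <- stick_spectrum(t1$anionic, mode = "fundamentals")
  expect_true(all(fund$upsilon == 1))
})

test_that("convolution preserves single-stick peak position and Gaussian shape", {
  one <- data.frame(position_cm1 = 1000, weight = 1)
  for (sigma in c(30, 100, 250)) {
    cs <- convolve_spectrum(one, sigma = sigma, grid_start = 0,
                            grid_stop = 2000, grid_step = 1,
                            normalization = "none")
    expect_lte(abs(cs$grid[which.max(cs$values)] - 1000), 1)
  }
  cs <- convolve_spectrum(one, sigma = 100, grid_start = 0, grid_stop = 2000,
                          grid_step = 1, normalization = "none")
  peak <- cs$values[cs$grid == 1000]
  expect_equal(cs$values[cs$grid == 900], exp(-0.5) * peak,
               tolerance = 1e-10)

  # two sticks closer than the resolution merge into one maximum
  two <- data.frame(position_cm1 = c(1000, 1050), weight = c(1, 1))
  cs2 <- convolve_spectrum(two, sigma = 100, grid_start = 500,
                           grid_stop = 1600, grid_step = 1)
  pk <- find_peaks(cs2, min_prominence = 0.001)
  expect_equal(nrow(pk), 1L)

  empty <- data.frame(position_cm1 = numeric(), weight = numeric())
  cs0 <- convolve_spectrum(empty, sigma = 100, normalization = "none")
  expect_true(all(cs0$values == 0))

  expect_warning(convolve_spectrum(one, sigma = 10, grid_step = 50),
                 "coarser")
})

test_that("convolution is linear in the stick list before normalization", {
  a <- data.frame(position_cm1 = c(400, 900), weight = c(0.3, 1.1))
  b <- data.frame(position_cm1 = c(1500, 2200), weight = c(0.8, 0.2))
  cv <- function(x) convolve_spectrum(x, sigma = 80, grid_start = 0,
                                      grid_stop = 3000, grid_step = 2,
                                      normalization = "none")$values
  expect_equal(cv(rbind(a, b)), cv(a) + cv(b), tolerance = 1e-10)
})

test_that("HCN emission and absorption bands sit at the published positions", {
  t1 <- table1_hcn()
  for (mode in c("progression", "fundamentals")) {
    for (umax in 1:10) {
      em <- emission_spectrum(t1$anionic, upsilon_max = umax, mode = mode)
      ab <- absorption_spectrum(t1$neutral, upsilon_max = umax, mode = mode)
      em_max <- em$grid[which.max(em$values)]
      ab_max <- ab$grid[which.max(ab$values)]
      expect_lte(abs(em_max - 1704), 1)
      expect_lte(abs(ab_max - 2149), 1)
      expect_lt(em_max, ab_max)   # emission left-shifted
    }
  }
})

test_that("spectra can be built straight from a state-model pair", {
  fx <- make_displaced_diatomic(1, 14, 2000, 0.25)   # S ~ 1.7: one-phonon line dominates
  em <- emission_spectrum(fx$neutral, fx$charged)
  expect_lte(abs(em$grid[which.max(em$values)] - 2000), 1)
})

test_that("deuteration shifts the diatomic emission peak by the isotope factor", {
  m2 <- 19; dr <- 0.2   # strong enough coupling that the 0-0 line does not dominate
  mu_h <- 1.00783 * m2 / (1.00783 + m2)
  mu_d <- 2.0141 * m2 / (2.0141 + m2)
  omega_h <- 2900
  omega_d <- omega_h * sqrt(mu_h / mu_d)
  fx_h <- make_displaced_diatomic(1.00783, m2, omega_h, dr)
  fx_d <- make_displaced_diatomic(2.0141, m2, omega_d, dr)
  em_h <- emission_spectrum(build_mode_table(fx_h$neutral, fx_h$charged, "charged"))
  em_d <- emission_spectrum(build_mode_table(fx_d$neutral, fx_d$charged, "charged"))
  peak_h <- em_h$grid[which.max(em_h$values)]
  peak_d <- em_d$grid[which.max(em_d$values)]
  expect_lte(abs(peak_h - omega_h), 1)
  expect_lte(abs(peak_d - omega_d), 1)
  expect_lt(peak_d, peak_h)
})

test_that("a zero-coupling table yields a flat 0-0-only spectrum", {
  quiet <- mode_table(c(500, 1500), c(0, 0), state_basis = "charged")
  em <- emission_spectrum(quiet)
  expect_lte(em$grid[which.max(em$values)], 1)
  expect_true(all(diff(em$values) <= 0))   # monotone decay from the origin
})

test_that("IETS intensities follow the point-charge quadratic form", {
  # one atom, unit charge, unit displacement
  expect_equal(iets_intensity(1, matrix(c(1, 0, 0), ncol = 1))$intensity, 1)
  # two atoms, charges +/- 0.5, each displaced by 0.1
  X <- matrix(c(0.1, 0, 0, 0, 0.1, 0), ncol = 1)
  expect_equal(iets_intensity(c(0.5, -0.5), X)$intensity, 0.005,
               tolerance = 1e-12)
  # invariant under global charge sign flip
  set.seed(4)
  X2 <- matrix(rnorm(12), ncol = 2)
  q <- c(0.3, -0.7)
  expect_equal(iets_intensity(q, X2)$intensity,
               iets_intensity(-q, X2)$intensity)
  expect_equal(iets_intensity(c(0, 0), X2)$intensity, c(0, 0))
  expect_error(iets_intensity(c(1, 1, 1), X2), "rows")
})
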