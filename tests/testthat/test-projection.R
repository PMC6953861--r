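test_that("alignment is exact for rigidly moved copies and refuses mirror images", {
  p <- make_random_polyatomic(5, 11, s_targets = rep(0, 9))
  ref <- p$neutral
  expect_equal(align_structures(ref, ref)$rmsd, 0, tolerance = 1e-12)

  moved <- rigid_transform(ref, 37 * pi / 180, "z", shift = c(1.5, -0.3, 2))
  al <- align_structures(ref, moved)
  expect_lt(al$rmsd, 1e-10)
  expect_equal(al$geometry, al$reference_geometry, tolerance = 1e-9)

  mirrored <- ref
  G <- matrix(ref$geometry_angstrom, ncol = 3, byrow = TRUE)
  G[, 1] <- -G[, 1]
  mirrored$geometry_angstrom <- as.numeric(t(G))
  expect_error(align_structures(ref, mirrored), "reflection")

  other <- ref; other$elements <- rev(other$elements)
  other$elements[1] <- "Q"
  expect_error(align_structures(ref, other), "element-order")
})

test_that("residual RMSD of a stretched diatomic equals the closed form", {
  fx <- make_displaced_diatomic(1, 1, 1000, 0.1)
  al <- align_structures(fx$neutral, fx$charged)
  # pure stretch of a homonuclear pair: rmsd = dr * sqrt(mu / M)
  expect_equal(al$rmsd, 0.1 * sqrt(0.5 / 2), tolerance = 1e-10)
})

test_that("mode projection reproduces hand-worked diatomic displacement", {
  fx <- make_displaced_diatomic(1, 1, 1000, 0.1)
  d <- normal_mode_displacements(fx$neutral, fx$charged, "neutral")
  expect_equal(abs(d$delta_q), sqrt(0.5) * 0.1, tolerance = 1e-10)
  # sign convention: charged minus neutral in the neutral basis, reversed
  # in the charged basis
  d2 <- normal_mode_displacements(fx$neutral, fx$charged, "charged")
  expect_equal(d2$delta_q, -d$delta_q, tolerance = 1e-10)

  same <- normal_mode_displacements(fx$neutral, fx$neutral, "neutral")
  expect_equal(same$delta_q, 0)
})

test_that("|delta_q| is invariant under rigid motion of either geometry", {
  p <- make_random_polyatomic(4, 3, s_targets = c(0.4, 1.2, 0, 0.8, 2, 0.1))
  base <- abs(normal_mode_displacements(p$neutral, p$charged, "neutral")$delta_q)
  for (case in list(list(m = "charged", a = 0.7, ax = "x"),
                    list(m = "neutral", a = -1.2, ax = "y"),
                    list(m = "charged", a = 2.9, ax = "z"))) {
    q <- p
    q[[case$m]] <- rigid_transform(q[[case$m]], case$a, case$ax,
                                   shift = c(0.4, 1, -2))
    moved <- abs(normal_mode_displacements(q$neutral, q$charged, "neutral")$delta_q)
    expect_equal(moved, base, tolerance = 1e-8)
  }
})

test_that("projection is complete for in-span displacements", {
  set.seed(21)
  p <- make_random_polyatomic(5, 21, s_targets = runif(9, 0, 1.5))
  d <- normal_mode_displacements(p$neutral, p$charged, "neutral")
  # the fixture displaces along the modes only, so nothing may be lost
  expect_lt(d$residual_norm, 1e-8)
  sm <- sqrt(rep(p$neutral$masses_amu, each = 3))
  mw <- sm * d$aligned_displacement
  expect_lt(sqrt(sum((p$neutral$mode_matrix %*% d$delta_q - mw)^2)), 1e-8)
})

test_that("out-of-span displacement triggers the contamination warning", {
  # a mode matrix that is orthonormal but does not span the whole
  # vibrational complement: its first column is replaced by a
  # mass-weighted translation, so a displacement along the discarded
  # vibration cannot be represented and must be reported
  p <- make_random_polyatomic(4, 5, s_targets = rep(0, 6))
  L <- p$neutral$mode_matrix
  lost <- L[, 1]
  sm <- sqrt(rep(p$neutral$masses_amu, each = 3))
  tx <- rep(0, 12); tx[seq(1, 12, by = 3)] <- sqrt(p$neutral$masses_amu)
  L[, 1] <- tx / sqrt(sum(tx^2))
  n <- p$neutral; n$mode_matrix <- L
  c <- p$charged; c$mode_matrix <- L
  c$geometry_angstrom <- c$geometry_angstrom + 0.3 * lost / sm
  expect_warning(normal_mode_displacements(n, c, "neutral"),
                 "outside the span")
})

test_that("Duschinsky matrix is the identity for self-pairs and orthogonal in general", {
  p <- make_random_polyatomic(5, 8, s_targets = rep(0.3, 9))
  d_self <- duschinsky_matrix(p$neutral, p$neutral)
  expect_equal(d_self$j_matrix, diag(9), tolerance = 1e-8)
  expect_equal(d_self$delta_q, rep(0, 9))

  d <- duschinsky_matrix(p$charged, p$neutral)
  expect_lt(max(abs(crossprod(d$j_matrix) - diag(9))), 1e-6)
  expect_equal(abs(det(d$j_matrix)), 1, tolerance = 1e-6)
})

test_that("a mode basis rotated by 30 degrees yields the textbook rotation block", {
  masses <- c(12, 1, 16)
  geom <- c(0, 0, 0, 1.1, 0, 0, -0.4, 1.2, 0)
  L <- vib_basis(masses, geom)           # 3 modes for a nonlinear triatomic
  theta <- 30 * pi / 180
  B <- diag(3)
  B[1:2, 1:2] <- matrix(c(cos(theta), sin(theta),
                          -sin(theta), cos(theta)), 2)   # rotation by +theta
  mk <- function(label, charge, modes) state_model(
    label, charge, c("C", "H", "O"), masses, geom,
    frequencies_cm1 = c(600, 1300, 2900), mode_matrix = modes)
  ini <- mk("anion", -1L, L %*% t(B))    # initial modes = rotated basis
  fin <- mk("neutral", 0L, L)
  J <- duschinsky_matrix(ini, fin)$j_matrix
  expected <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)),
                     2, byrow = TRUE)
  expect_equal(J[1:2, 1:2], expected, tolerance = 1e-10)
  expect_equal(J[3, 3], 1, tolerance = 1e-10)

  short <- make_displaced_diatomic(1, 1, 1000, 0)$neutral
  expect_error(duschinsky_matrix(short, fin), "unequal mode counts")
})
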