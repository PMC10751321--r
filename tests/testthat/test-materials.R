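test_that("linear <-> Neo-Hooke conversions reproduce the reference values", {
  nh <- neo_hooke_from_linear(600, 0.45)
  expect_equal(nh$C10, 103.45, tolerance = 1e-4)  # 600 / (4 * 1.45)
  expect_equal(nh$D1, 0.001, tolerance = 1e-12)   # 6 * 0.1 / 600
  nh_l <- neo_hooke_from_linear(10, 0.45)
  expect_equal(nh_l$C10, 1.724138, tolerance = 1e-6)
  expect_equal(nh_l$D1, 0.06, tolerance = 1e-12)

  lin <- linear_from_neo_hooke(103.45, 0.001)
  expect_equal(lin$E, 600, tolerance = 1e-3)
  lin_l <- linear_from_neo_hooke(1.72, 0.06)
  expect_equal(lin_l$E, 10, tolerance = 0.02)

  expect_error(neo_hooke_from_linear(600, 0.5), "nu")
  expect_error(linear_from_neo_hooke(100, 0.2), "nu")
})

test_that("conversion round-trips are exact across the modulus range", {
  for (E in c(1, 10, 600, 1e4)) for (nu in c(0.01, 0.3, 0.45, 0.49)) {
    nh <- neo_hooke_from_linear(E, nu)
    lin <- linear_from_neo_hooke(nh$C10, nh$D1)
    expect_equal(lin$E, E, tolerance = 1e-12)
    expect_equal(lin$nu, nu, tolerance = 1e-12)
  }
})

test_that("strain energy vanishes at the identity and matches direct evaluation", {
  kinI <- kinematics(diag(2))
  mats <- list(neo_hooke(103.45, 0.001), fibrotic_goh("calcified1"),
               linear_elastic(600, 0.45))
  for (m in mats) expect_equal(strain_energy(m, kinI), 0)

  # GOH at incompressible plane-strain stretch lambda = 1.05: independent
  # symbolic evaluation of the energy expression (J = 1, fibers at 0 and 90
  # degrees so I4 = lambda^2, I6 = lambda^-2)
  lam <- 1.05
  F2 <- diag(c(lam, 1 / lam))
  kin <- kinematics(F2)
  m <- fibrotic_goh("calcified1")
  I1 <- lam^2 + 1 / lam^2 + 1
  k <- m$kappa
  E4 <- k * (I1 - 3) + (1 - 3 * k) * (lam^2 - 1)
  E6 <- k * (I1 - 3) + (1 - 3 * k) * (1 / lam^2 - 1)
  psi_ref <- m$mu * (I1 - 3) +
    m$k1 / (2 * m$k2) * (exp(m$k2 * E4^2) - 1 + exp(m$k2 * E6^2) - 1)
  expect_equal(strain_energy(m, kin), psi_ref, tolerance = 1e-12)
})

test_that("Cauchy stress is the derivative of the strain energy", {
  fd_stress <- function(mat, F2, h = 1e-6) {
    P <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2) {
      Fp <- F2; Fp[i, j] <- Fp[i, j] + h
      Fm <- F2; Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (strain_energy(mat, kinematics(Fp)) -
                    strain_energy(mat, kinematics(Fm))) / (2 * h)
    }
    s <- P %*% t(F2) / det(F2)
    (s + t(s)) / 2
  }
  F2 <- matrix(c(1.08, 0.03, -0.02, 0.95), 2, 2)
  for (m in list(neo_hooke(103.45, 0.001), neo_hooke(1.72, 0.06),
                 fibrotic_goh("calcified1"), fibrotic_goh("cellular"),
                 linear_elastic(600, 0.45))) {
    sig <- cauchy_stress(m, kinematics(F2))
    expect_lt(max(abs(sig[1:2, 1:2] - fd_stress(m, F2))) /
                max(abs(sig), 1e-10), 1e-5)
    expect_equal(sig, t(sig))
    expect_equal(max(abs(cauchy_stress(m, kinematics(diag(2))))), 0)
  }
})

test_that("linear-elastic stress matches Hooke plane strain at small strain", {
  E <- 600; nu <- 0.45
  eps <- matrix(c(2e-4, 5e-5, 5e-5, -1e-4), 2, 2)
  F2 <- diag(2) + eps
  sig <- cauchy_stress(linear_elastic(E, nu), kinematics(F2))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  hooke <- lam * sum(diag(eps)) * diag(2) + 2 * mu * eps
  expect_lt(max(abs(sig[1:2, 1:2] - hooke)), 1e-3 * max(abs(hooke)))
  expect_equal(sig[3, 3], nu * (sig[1, 1] + sig[2, 2]), tolerance = 1e-3)
})

test_that("uniaxial curves follow the Neo-Hooke closed form and GOH ordering", {
  nh <- neo_hooke(1.72, 0.06)
  cv <- uniaxial_curve(nh, 1.3, 50)
  expect_equal(cv$sigma[1], 0)
  expect_equal(cv$sigma[50], 2 * 1.72 * (1.3^2 - 1 / 1.3), tolerance = 1e-12)
  lam12 <- which.min(abs(cv$lambda - 1.2))
  expect_equal(uniaxial_stress(nh, 1.2), 2 * 1.72 * (1.44 - 1 / 1.2),
               tolerance = 1e-12)

  # exponential hardening: GOH tangent stiffness non-decreasing
  g <- uniaxial_curve(fibrotic_goh("calcified2"), 1.3, 100)
  slopes <- diff(g$sigma) / diff(g$lambda)
  expect_true(all(diff(slopes) > -1e-8))

  # stiffness ordering at lambda = 1.1: calcified 1 above cellular
  s_cal <- uniaxial_stress(fibrotic_goh("calcified1"), 1.1)
  s_cel <- uniaxial_stress(fibrotic_goh("cellular"), 1.1)
  expect_gt(s_cal, s_cel)
})

test_that("GOH response with kappa = 1/3 is independent of fiber angles", {
  m1 <- goh(9.58, 17564, 0.51, kappa = 1 / 3)
  m2 <- goh(9.58, 17564, 0.51, kappa = 1 / 3, fiber_angles = c(0.7, 2.1))
  F2 <- matrix(c(1.1, 0.05, 0.02, 0.93), 2, 2)
  expect_identical(strain_energy(m1, kinematics(F2)),
                   strain_energy(m2, kinematics(F2)))
  expect_equal(cauchy_stress(m1, kinematics(F2)),
               cauchy_stress(m2, kinematics(F2)), tolerance = 1e-12)
})

test_that("curve R^2 matches hand arithmetic and detects offsets", {
  ref <- structure(list(lambda = c(1, 1.1, 1.2), sigma = c(0, 2, 6)),
                   class = "behavior_curve")
  cand <- structure(list(lambda = c(1, 1.1, 1.2), sigma = c(0.5, 2, 5)),
                    class = "behavior_curve")
  # ss_res = 0.25 + 0 + 1 = 1.25; ss_tot = (0-8/3)^2+(2-8/3)^2+(6-8/3)^2
  ss_tot <- (0 - 8 / 3)^2 + (2 - 8 / 3)^2 + (6 - 8 / 3)^2
  expect_equal(curve_r2(ref, cand), 1 - 1.25 / ss_tot, tolerance = 1e-12)
  expect_equal(curve_r2(ref, ref), 1)
  off1 <- ref; off1$sigma <- ref$sigma + 0.5
  off2 <- ref; off2$sigma <- ref$sigma + 1
  expect_lt(curve_r2(ref, off1), 1)
  expect_lt(curve_r2(ref, off2), curve_r2(ref, off1))
  flat <- ref; flat$sigma <- rep(2, 3)
  expect_error(curve_r2(flat, cand), "constant")
})

test_that("Latin hypercube samples are stratified per dimension", {
  rng <- list(c(1, 100), c(390, 1200))
  x <- lhs_sample(rng, 15, seed = 42L)
  expect_equal(dim(x), c(15L, 2L))
  for (j in 1:2) {
    strata <- findInterval(x[, j], seq(rng[[j]][1], rng[[j]][2], length.out = 16),
                           rightmost.closed = TRUE)
    expect_setequal(strata, 1:15)
  }
  expect_identical(lhs_sample(rng, 15, seed = 42L), x)  # deterministic
  x1 <- lhs_sample(list(c(0, 1)), 1, seed = 1L)
  expect_true(x1 >= 0 && x1 <= 1)
})
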