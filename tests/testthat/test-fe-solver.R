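test_that("zero pressure produces a zero displacement field", {
  mesh <- annulus_mesh(1, 2, nr = 3, nt = 12)
  mats <- material_set(fibrotic = neo_hooke(25, 0.01))
  sol <- inflate(mesh, mats, 0)
  expect_equal(max(abs(sol$displacements)), 0)
  expect_equal(max(abs(max_principal_stress(sol)$sigma_max)), 0)
  u <- inflate_linear_increment(mesh, material_set(fibrotic = linear_elastic(600, 0.49)), 0)
  expect_equal(max(abs(u)), 0)
})

test_that("linear increment displacements scale exactly with pressure", {
  mesh <- small_plaque_mesh()
  mats <- material_set(fibrotic = linear_elastic(600, 0.49),
                       lipid_1 = linear_elastic(10, 0.49),
                       calcification_1 = linear_elastic(5000, 0.333))
  u1 <- inflate_linear_increment(mesh, mats, 5)
  u2 <- inflate_linear_increment(mesh, mats, 10)
  expect_equal(u2, 2 * u1, tolerance = 1e-12)
})

test_that("a softer lipid attracts larger radial strain magnitude", {
  mesh <- small_plaque_mesh()
  run <- function(E_lip) {
    mats <- material_set(fibrotic = linear_elastic(600, 0.49),
                         lipid_1 = linear_elastic(E_lip, 0.49),
                         calcification_1 = linear_elastic(5000, 0.333))
    u <- inflate_linear_increment(mesh, mats, 5)
    f <- strain_fields(mesh, u, atheroIFEM:::lumen_centroid(mesh))
    mean(abs(f$err[startsWith(f$labels, "lipid")]))
  }
  expect_gt(run(10), run(100))
})

test_that("single-element patch reproduces the material-point stress", {
  # one CST element under an imposed affine (uniaxial stretch) map
  nodes <- rbind(c(0, 0), c(1, 0), c(0, 1))
  tri <- matrix(c(1L, 2L, 3L), 1)
  mesh <- atheroIFEM:::labeled_mesh(nodes, tri, "fibrotic",
                                    lumen_edges = matrix(integer(0), 0, 2),
                                    outer_nodes = 1:3, fixed_nodes = 1:3)
  lam <- 1.1
  F2 <- diag(c(lam, 0.96))
  disp <- t((F2 - diag(2)) %*% t(nodes))
  mat <- fibrotic_goh("calcified1")
  pre <- atheroIFEM:::fe_precompute(nodes, tri)
  st <- atheroIFEM:::element_state(pre, as.vector(t(disp)))
  expect_equal(c(st$F11, st$F12, st$F21, st$F22), c(F2[1, 1], F2[1, 2], F2[2, 1], F2[2, 2]),
               tolerance = 1e-12)
  asm <- atheroIFEM:::assemble_internal(pre, atheroIFEM:::material_groups(
    mesh, material_set(fibrotic = mat)), st, want_K = FALSE)
  sig_ref <- cauchy_stress(mat, kinematics(F2))
  J <- det(F2)
  S_ref <- J * solve(F2) %*% sig_ref[1:2, 1:2] %*% t(solve(F2))
  expect_equal(as.numeric(asm$S[1, 1:3]),
               c(S_ref[1, 1], S_ref[2, 2], S_ref[1, 2]), tolerance = 1e-10)
})

test_that("multi-element patch test reproduces constant strain exactly", {
  mesh <- small_plaque_mesh()
  eps <- matrix(c(3e-3, 1e-3, 1e-3, -2e-3), 2, 2)
  disp <- t(eps %*% t(mesh$nodes))
  f <- strain_fields(mesh, disp, center = atheroIFEM:::lumen_centroid(mesh))
  expect_lt(max(abs(f$exx - eps[1, 1])), 1e-12)
  expect_lt(max(abs(f$eyy - eps[2, 2])), 1e-12)
  expect_lt(max(abs(f$exy - eps[1, 2])), 1e-12)
  # trace invariance of the cylindrical transform
  expect_lt(max(abs((f$err + f$ett) - (f$exx + f$eyy))), 1e-12)
})

test_that("Lame oracle: annulus inflation converges to the closed form", {
  E <- 600; nu <- 0.49; a <- 1.5; b <- 4; p <- mmHg_to_kPa(5)
  oracle <- lame_annulus(E, nu, a, b, p)
  expect_equal(oracle(a), (1 + nu) * p * a^2 / (E * (b^2 - a^2)) *
                 ((1 - 2 * nu) * a + b^2 / a), tolerance = 1e-12)
  expect_true(all(diff(oracle(seq(a, b, length.out = 20))) < 0))
  errs <- vapply(c(4, 8, 16), function(nr) {
    mesh <- annulus_mesh(a, b, nr = nr, nt = 2 * nr, quarter = TRUE)
    u <- inflate_linear_increment(mesh, material_set(fibrotic = linear_elastic(E, nu)),
                                  5, fixed_dofs = attr(mesh, "sym_fixed_dofs"))
    r <- sqrt(rowSums(mesh$nodes^2))
    ur <- rowSums(u * mesh$nodes) / r
    max(abs(ur - oracle(r))) / max(abs(oracle(r)))
  }, 0)
  expect_true(all(diff(errs) < 0))   # monotone convergence under refinement
  expect_lt(errs[3], 0.01)
})

test_that("strain rotation identities hold for random displacement fields", {
  mesh <- annulus_mesh(1, 2, nr = 4, nt = 24)
  set.seed(99)
  for (rep in 1:5) {
    disp <- matrix(rnorm(2 * nrow(mesh$nodes), sd = 0.01), ncol = 2)
    f <- strain_fields(mesh, disp, center = c(0, 0))
    # explicit rotation-matrix conjugation per element
    th <- atan2(f$centroids[, 2], f$centroids[, 1])
    for (k in sample(length(f$exx), 10)) {
      Q <- matrix(c(cos(th[k]), sin(th[k]), -sin(th[k]), cos(th[k])), 2, 2,
                  byrow = TRUE)   # rows = radial / tangential unit vectors
      eps <- matrix(c(f$exx[k], f$exy[k], f$exy[k], f$eyy[k]), 2, 2)
      cyl <- Q %*% eps %*% t(Q)
      expect_equal(f$err[k], cyl[1, 1], tolerance = 1e-12)
      expect_equal(f$ett[k], cyl[2, 2], tolerance = 1e-12)
      expect_equal(f$ert[k], cyl[1, 2], tolerance = 1e-12)
    }
    expect_lt(max(abs(f$err + f$ett - f$exx - f$eyy)), 1e-10)
    expect_true(all(f$e1 >= f$e2))
  }
  # rigid translation: zero strain
  f0 <- strain_fields(mesh, matrix(1, nrow(mesh$nodes), 2), center = c(0, 0))
  expect_equal(max(abs(c(f0$exx, f0$eyy, f0$exy, f0$err, f0$evm))), 0)
  # uniform radial expansion u = alpha x about the center
  alpha <- 1e-3
  fr <- strain_fields(mesh, alpha * mesh$nodes, center = c(0, 0))
  expect_lt(max(abs(fr$err - alpha)), 1e-12)
  expect_lt(max(abs(fr$ett - alpha)), 1e-12)
})

test_that("external work balances stored energy for hyperelastic inflation", {
  mesh <- annulus_mesh(1.2, 2.2, nr = 6, nt = 36)
  mats <- material_set(fibrotic = neo_hooke(25, 0.005))
  # walk the load path in small steps, integrating p dA of the lumen
  pressures <- seq(0, 60, by = 5)
  areas <- numeric(length(pressures)); energies <- numeric(length(pressures))
  for (i in seq_along(pressures)) {
    sol <- inflate(mesh, mats, pressures[i], solver_config(load_steps = 4))
    areas[i] <- abs(polygon_area(atheroIFEM:::lumen_polygon(
      mesh, mesh$nodes + sol$displacements)))
    energies[i] <- total_strain_energy(sol)
  }
  p_kPa <- mmHg_to_kPa(pressures)
  work <- sum((p_kPa[-1] + p_kPa[-length(p_kPa)]) / 2 * diff(areas))
  expect_equal(work, energies[length(energies)], tolerance = 0.01 * work)
})

test_that("peak wall stress concentrates in the fibrotic cap, not the lipid", {
  mesh <- small_plaque_mesh()
  mats <- goh_materials(mesh)
  sol <- inflate(mesh, mats, 110, solver_config(load_steps = 4))
  sf <- max_principal_stress(sol)
  expect_true(all(sf$sigma_max >= sf$principal[, 1] - 1e-12))
  top <- order(sf$sigma_max, decreasing = TRUE)[1:10]
  expect_false(any(startsWith(sf$labels[top], "lipid")))
})

test_that("identical inputs give identical solutions", {
  mesh <- annulus_mesh(1, 2, nr = 4, nt = 24)
  mats <- material_set(fibrotic = neo_hooke(25, 0.01))
  s1 <- inflate(mesh, mats, 40, solver_config(load_steps = 3))
  s2 <- inflate(mesh, mats, 40, solver_config(load_steps = 3))
  expect_identical(s1$displacements, s2$displacements)
})
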