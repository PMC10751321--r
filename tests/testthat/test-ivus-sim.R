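test_that("degenerate frame pairs are rejected", {
  mesh <- small_plaque_mesh()
  mats <- table1_materials(mesh)
  expect_error(simulate_frame_pair(mesh, mats, 110, 110), "exceed")
})

test_that("linear-material frames equal the single linear increment", {
  mesh <- small_plaque_mesh()
  mats <- material_set(fibrotic = linear_elastic(600, 0.49),
                       lipid_1 = linear_elastic(10, 0.49),
                       calcification_1 = linear_elastic(5000, 0.333))
  fp <- simulate_frame_pair(mesh, mats, 0, 5)
  u <- inflate_linear_increment(mesh, mats, 5)
  expect_equal(fp$rel_disp, u, tolerance = 1e-10)
  # exact pressure-scale invariance of the linear increment
  fp2 <- simulate_frame_pair(mesh, mats, 110, 115)
  expect_equal(fp2$rel_disp, fp$rel_disp, tolerance = 1e-10)
})

test_that("hyperelastic stiffening shrinks the increment at higher pressure", {
  mesh <- annulus_mesh(1.2, 2.2, nr = 5, nt = 30)
  mats <- material_set(fibrotic = fibrotic_goh("calcified1"))
  cfg <- solver_config(load_steps = 4)
  lo <- simulate_frame_pair(mesh, mats, 80, 85, cfg)
  hi <- simulate_frame_pair(mesh, mats, 110, 115, cfg)
  expect_lt(max(sqrt(rowSums(hi$rel_disp^2))), max(sqrt(rowSums(lo$rel_disp^2))))
})

test_that("inflation thins the wall: mean radial strain is negative", {
  mesh <- annulus_mesh(1.2, 2.2, nr = 5, nt = 30)
  mats <- material_set(fibrotic = fibrotic_goh("calcified1"))
  fp <- simulate_frame_pair(mesh, mats, 110, 115, solver_config(load_steps = 4))
  f <- frame_strains(fp)
  expect_lt(mean(f$err), 0)
})

test_that("frame strains vanish for identical frames", {
  mesh <- small_plaque_mesh()
  pair <- structure(list(coords = mesh$nodes,
                         rel_disp = matrix(0, nrow(mesh$nodes), 2),
                         p_lo = 110, p_hi = 115, mesh = mesh),
                    class = "frame_pair")
  f <- frame_strains(pair)
  expect_equal(max(abs(f$err)), 0)
})

test_that("noise injection hits the target SNR and is seed-deterministic", {
  # synthetic smooth field on ~10^4 elements; no FE solve needed
  n <- 12000
  set.seed(5)
  cent <- cbind(runif(n, -2, 2), runif(n, -2, 2))
  cent <- cent[rowSums(cent^2) > 0.8, ][1:10000, ]
  r2 <- rowSums(cent^2)
  clean <- strain_field_from_cartesian(
    exx = -1e-3 / r2, eyy = -5e-4 / r2, exy = 2e-4 * cent[, 1] / r2,
    centroids = cent, center = c(0, 0))
  snrs <- vapply(1:20, function(s)
    measure_snr(clean, add_noise(clean, 20, seed = s)), 0)
  expect_lt(max(abs(snrs - 20)), 0.5)
  expect_equal(add_noise(clean, 20, seed = 3L), add_noise(clean, 20, seed = 3L))
  n1 <- add_noise(clean, 20, seed = 1L); n2 <- add_noise(clean, 20, seed = 2L)
  expect_gt(max(abs(n1$exx - n2$exx)), 0)
  # infinite SNR sentinel: unchanged field
  expect_identical(add_noise(clean, Inf, seed = 1L), clean)
  expect_identical(measure_snr(clean, clean), Inf)
  # noise power equal to signal power -> 0 dB
  z <- add_noise(clean, 0, seed = 4L)
  expect_lt(abs(measure_snr(clean, z)), 0.5)
})

test_that("noised fields keep the derived-component identities and are unbiased", {
  mesh <- small_plaque_mesh()
  mats <- table1_materials(mesh)
  fp <- simulate_frame_pair(mesh, mats, 110, 115, solver_config(load_steps = 4))
  clean <- frame_strains(fp)
  acc <- 0
  for (s in 1:60) {
    noisy <- add_noise(clean, 20, seed = s)
    acc <- acc + mean(noisy$err)
    if (s <= 3) {
      expect_lt(max(abs(noisy$err + noisy$ett - noisy$exx - noisy$eyy)), 1e-12)
      expect_true(all(noisy$e1 >= noisy$e2))
    }
  }
  # E[noised] = clean (Monte-Carlo tolerance)
  sd_mean <- stats::sd(clean$err) / sqrt(60 * length(clean$err)) * 10
  expect_lt(abs(acc / 60 - mean(clean$err)), 5 * sd_mean + 1e-6 * abs(mean(clean$err)))
})
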