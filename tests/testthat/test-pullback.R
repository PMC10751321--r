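test_that("K = 0 leaves the geometry unchanged; stiff bodies barely move", {
  mesh <- annulus_mesh(1.2, 2.2, nr = 4, nt = 24)
  mats <- material_set(fibrotic = fibrotic_goh("calcified1"))
  cfg <- solver_config(load_steps = 3)
  step0 <- pullback_step(mesh, mats, 110, K = 0, config = cfg)
  expect_equal(step0$coords, mesh$nodes)
  # very stiff body: K = 1 candidate stays within a tiny distance
  stiff <- material_set(fibrotic = linear_elastic(1e6, 0.3))
  step1 <- pullback_step(mesh, stiff, 110, K = 1, config = cfg)
  expect_lt(max(abs(step1$coords - mesh$nodes)), 1e-3)
})

test_that("one pull-back step reduces the re-pressurization error", {
  mesh <- annulus_mesh(1.2, 2.2, nr = 4, nt = 24)
  mats <- material_set(fibrotic = neo_hooke(103.45, 0.001))
  cfg <- solver_config(load_steps = 3)
  target <- mesh$nodes
  rms_K0 <- repressurize_error(mesh$nodes, mesh, mats, 20, target, cfg)
  cand <- pullback_step(mesh, mats, 20, K = 1, config = cfg)
  rms_K1 <- repressurize_error(cand$coords, mesh, mats, 20, target, cfg)
  expect_gt(rms_K0, 0)
  expect_lt(rms_K1, rms_K0)
})

test_that("rms error equals an explicit per-node loop", {
  mesh <- annulus_mesh(1.2, 2.2, nr = 3, nt = 18)
  mats <- material_set(fibrotic = neo_hooke(50, 0.005))
  cfg <- solver_config(load_steps = 3)
  zp <- mesh$nodes * 0.98
  target <- mesh$nodes
  rms <- repressurize_error(zp, mesh, mats, 30, target, cfg)
  sol <- inflate(mesh, mats, 30, cfg, coords = zp)
  xy <- zp + sol$displacements
  acc <- 0
  for (i in seq_len(nrow(xy))) acc <- acc + sum((xy[i, ] - target[i, ])^2)
  expect_equal(rms, sqrt(acc / nrow(xy)), tolerance = 1e-12)
})

test_that("optimized K beats the fixed K = 1 pull-back", {
  A <- 1.2; B <- 2.2
  zp_mesh <- annulus_mesh(A, B, nr = 4, nt = 24)
  mats <- material_set(fibrotic = fibrotic_goh("calcified1"))
  cfg <- solver_config(load_steps = 4)
  sol <- inflate(zp_mesh, mats, 110, cfg)
  img <- atheroIFEM:::labeled_mesh(zp_mesh$nodes + sol$displacements,
                                   zp_mesh$triangles, zp_mesh$labels,
                                   zp_mesh$lumen_edges, zp_mesh$outer_nodes,
                                   zp_mesh$fixed_nodes, zp_mesh$lumen_nodes)
  pb <- pullback_optimize(img, mats, 110, config = cfg)
  fixed1 <- pullback_step(img, mats, 110, K = 1, config = cfg)
  rms1 <- repressurize_error(fixed1$coords, img, mats, 110, img$nodes, cfg)
  expect_lte(pb$residual_rms, rms1 + 1e-12)
  expect_true(pb$K_zp >= 0.5 && pb$K_zp <= 1.5)
  # best-so-far rms is non-increasing along the search history
  best <- cummin(pb$history[, "rms"])
  expect_true(all(diff(best) <= 0))
})
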