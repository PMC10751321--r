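test_that("NRMSE cost matches closed forms and hand arithmetic", {
  expect_equal(nrmse_cost(c(-0.01, -0.02), c(-0.01, -0.02)), 0)
  # constant offset c: J0 = 100 |c| / |mean(ref)|
  ref <- c(-0.01, -0.03)
  expect_equal(nrmse_cost(ref, ref + 0.005), 100 * 0.005 / 0.02, tolerance = 1e-12)
  # three-element hand example
  expect_equal(nrmse_cost(c(-0.01, -0.02, -0.03), c(-0.02, -0.02, -0.02)),
               100 * sqrt(2 / 3) * 0.01 / 0.02, tolerance = 1e-12)
  expect_error(nrmse_cost(c(-0.01, 0.01), c(0, 0)), class = "degenerate_normalization")
  # scale covariance
  expect_equal(nrmse_cost(ref * 7, (ref + 0.005) * 7),
               nrmse_cost(ref, ref + 0.005), tolerance = 1e-12)
})

test_that("success rate follows its definition including edge cases", {
  expect_equal(success_rate(600, 600), 100)
  expect_equal(success_rate(600, 0), 0)
  expect_equal(success_rate(600, 535.25), 89.208333, tolerance = 1e-6)
  expect_equal(success_rate(10, 12), 80)
  expect_lt(success_rate(600, 1300), 0)  # gross over-estimate, no clamping
  expect_error(success_rate(0, 10), "positive")
  for (E in c(0.5, 10, 600)) expect_equal(success_rate(E, E), 100)
})

test_that("GSS finds the minimum of a bounded convex quadratic", {
  target <- c(3.2, -1.5)
  cost <- function(x) sum((x - target)^2) + 0.7
  fit <- gss_minimize(cost, lower = c(0, -10), upper = c(10, 10),
                      config = gss_config(initial_mesh = 10, mesh_tol = 1e-5,
                                          cost_tol = 0, max_evaluations = 500L))
  norm_err <- max(abs(100 * (fit$par - target) / c(10, 20) -
                        100 * (target - target) / c(10, 20)))
  expect_lt(norm_err, 1e-3 * 100)
  # best-so-far cost is non-increasing
  expect_true(all(diff(cummin(fit$history$J0)) <= 0))
})

test_that("GSS respects bounds, survives failing costs, and stops on flat cost", {
  # minimizer outside the box: returned point sits exactly on the bound
  fit <- gss_minimize(function(x) (x[1] - 20)^2, lower = 0, upper = 10,
                      config = gss_config(initial_mesh = 25, mesh_tol = 1e-4,
                                          max_evaluations = 200L))
  expect_lte(fit$par, 10)
  expect_equal(fit$par, 10, tolerance = 1e-6)

  # constant cost: terminates on mesh_tol with the initial (center) point
  fit2 <- gss_minimize(function(x) 5, lower = c(0, 0), upper = c(1, 1),
                       config = gss_config(initial_mesh = 1, mesh_tol = 0.05,
                                           max_evaluations = 500L))
  expect_identical(fit2$termination, "mesh_tol")
  expect_equal(fit2$par, c(0.5, 0.5))

  # cost that errors in a half-plane: treated as +Inf, never crashes
  fit3 <- gss_minimize(function(x) { if (x[1] < 2) stop("boom"); (x[1] - 5)^2 },
                       lower = 0, upper = 10,
                       config = gss_config(initial_mesh = 20, mesh_tol = 1e-3,
                                           max_evaluations = 100L),
                       x0 = 1)  # start inside the failing half-plane
  expect_equal(fit3$par, 5, tolerance = 1e-2)
  expect_true(any(!is.finite(fit3$history$J0)))
})

test_that("linear characterization recovers moduli on a noise-free annulus", {
  # Neo-Hooke-simulated annulus, exact mesh, generous budget
  mesh <- annulus_mesh(1.2, 2.2, nr = 5, nt = 36)
  nh <- neo_hooke_from_linear(600, 0.45)
  mats <- material_set(fibrotic = neo_hooke(nh$C10, nh$D1))
  fp <- simulate_frame_pair(mesh, mats, 110, 115, solver_config(load_steps = 4))
  clean <- frame_strains(fp)
  imaged <- imaged_mesh(mesh, fp)
  res <- characterize_linear(clean, imaged, dP = 5,
                             truth = c(fibrotic = 600),
                             config = gss_config(initial_mesh = 1,
                                                 max_evaluations = 120L))
  expect_gte(res$sr[["fibrotic"]], 85)
  expect_lt(res$J0, 20)
  # ground truth = estimate gives sr = 100
  expect_equal(success_rate(res$parameters[["fibrotic"]],
                            res$parameters[["fibrotic"]]), 100)
})

test_that("search spaces carry the documented parameter ranges", {
  sp <- nonlinear_search_space(c("fibrotic", "lipid_1", "calcification_1"))
  expect_equal(sp$lower[sp$name == "k1_fibrotic"], 5)
  expect_equal(sp$upper[sp$name == "k1_fibrotic"], 1e5)
  expect_equal(sp$lower[sp$name == "C10_fibrotic"], 1)
  expect_equal(sp$upper[sp$name == "C10_fibrotic"], 50)
  expect_equal(sp$upper[sp$name == "k2_fibrotic"], 100)
  expect_equal(sp$lower[sp$name == "D1_lipid_1"], 0.005)
  expect_equal(sp$upper[sp$name == "C10_lipid_1"], 100)
  expect_equal(sp$upper[sp$name == "E_calcification_1"], 10000)
  lin <- linear_search_space(c("fibrotic", "lipid_1"))
  expect_equal(lin$lower, c(390, 1))
  expect_equal(lin$upper, c(1200, 100))
  m <- atheroIFEM:::nonlinear_materials_from_par(c(9.58, 17564, 0.51, 1.72, 0.06, 5000),
                                                 sp)
  expect_s3_class(m$fibrotic, "goh")
  expect_equal(m$fibrotic$D, 0.005)
  expect_equal(m$fibrotic$kappa, 0.3333)
  expect_s3_class(m$lipid_1, "neo_hooke")
  expect_equal(m$calcification_1$nu, 0.333)
})
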