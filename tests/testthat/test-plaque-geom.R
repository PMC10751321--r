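test_that("concentric spec with no inclusions gives a circular annulus", {
  sp <- plaque_spec(outer_radius = 2, lumen_radius = 1, lumen_offset = c(0, 0),
                    inclusions = list(), contour_noise_amplitude = 0)
  g <- generate_plaque(sp)
  r_out <- sqrt(rowSums(g$outer^2))
  r_lum <- sqrt(rowSums(g$lumen^2))
  expect_lt(max(abs(r_out - 2)), 1e-9)
  expect_lt(max(abs(r_lum - 1)), 1e-9)
  m <- geometry_metrics(g)
  # polygonal area ratio approximates the circle-area ratio 0.75
  expect_equal(m$stenosis_fraction, 0.75, tolerance = 2e-3)
  expect_true(is.na(m$cap_thickness))
  expect_identical(m$lipid_area, 0)
})

test_that("a lipid at exactly the minimum cap distance is accepted", {
  # lumen radius 0.8 centered at origin; lipid circle radius 0.3 centered at
  # (-1.4, 0): boundary gap = 1.4 - 0.8 - 0.3 = 0.3 = min_cap_thickness
  sp <- plaque_spec(outer_radius = 2.2, lumen_radius = 0.8,
                    lumen_offset = c(0, 0),
                    inclusions = list(list(kind = "lipid", center = c(-1.4, 0),
                                           semi_axes = c(0.3, 0.3), rotation = 0)),
                    min_cap_thickness = 0.3, contour_noise_amplitude = 0)
  expect_no_error(g <- generate_plaque(sp))
  # polygonal discretization can only widen the circle-to-circle gap
  expect_gte(geometry_metrics(g)$cap_thickness, 0.3 - 1e-9)
})

test_that("infeasible placement fails loudly instead of clipping", {
  sp <- plaque_spec(outer_radius = 2.2, lumen_radius = 0.8,
                    lumen_offset = c(0, 0),
                    inclusions = list(list(kind = "lipid", center = c(-1.2, 0),
                                           semi_axes = c(0.3, 0.3), rotation = 0)),
                    min_cap_thickness = 0.3, contour_noise_amplitude = 0)
  expect_error(generate_plaque(sp), class = "plaque_placement_error")
})

test_that("different seeds perturb contours but preserve all invariants", {
  g1 <- generate_plaque(small_plaque_spec(seed = 11L))
  g2 <- generate_plaque(small_plaque_spec(seed = 12L))
  expect_gt(max(abs(g1$outer - g2$outer)), 1e-6)
  for (s in 1:25) {
    g <- generate_plaque(small_plaque_spec(seed = s))
    expect_no_error(validate_plaque_geometry(g))
  }
  # determinism for a fixed seed
  g1b <- generate_plaque(small_plaque_spec(seed = 11L))
  expect_identical(g1, g1b)
})

test_that("geometry metrics match brute-force oracles", {
  # lipid polygon = unit square -> area 1
  sq <- rbind(c(-1.5, -0.5), c(-0.5, -0.5), c(-0.5, 0.5), c(-1.5, 0.5))
  expect_equal(abs(polygon_area(sq)), 1)

  g <- generate_plaque(small_plaque_spec(seed = 3L))
  m <- geometry_metrics(g)
  lip <- Filter(function(i) i$kind == "lipid", g$inclusions)[[1]]$poly
  # brute force: all vertex-to-segment distances in both directions
  brute <- Inf
  segd <- function(p, a, b) {
    t <- max(0, min(1, sum((p - a) * (b - a)) / sum((b - a)^2)))
    sqrt(sum((p - (a + t * (b - a)))^2))
  }
  nl <- nrow(g$lumen); np <- nrow(lip)
  for (i in seq_len(np)) for (j in seq_len(nl))
    brute <- min(brute, segd(lip[i, ], g$lumen[j, ], g$lumen[j %% nl + 1, ]))
  for (i in seq_len(nl)) for (j in seq_len(np))
    brute <- min(brute, segd(g$lumen[i, ], lip[j, ], lip[j %% np + 1, ]))
  expect_equal(m$cap_thickness, brute, tolerance = 1e-12)

  # shoelace by explicit loop
  sh <- 0
  for (i in seq_len(np)) {
    j <- i %% np + 1
    sh <- sh + lip[i, 1] * lip[j, 2] - lip[j, 1] * lip[i, 2]
  }
  expect_equal(m$lipid_area, abs(sh) / 2, tolerance = 1e-12)
})

test_that("geometry metrics are invariant under rigid motion", {
  g <- generate_plaque(small_plaque_spec(seed = 5L))
  m0 <- geometry_metrics(g)
  th <- 0.83; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shift <- c(3.2, -1.7)
  move <- function(p) sweep(p %*% t(R), 2, -shift)
  g2 <- g
  g2$outer <- move(g$outer); g2$lumen <- move(g$lumen)
  g2$inclusions <- lapply(g$inclusions, function(i) { i$poly <- move(i$poly); i })
  m1 <- geometry_metrics(g2)
  expect_equal(m1$cap_thickness, m0$cap_thickness, tolerance = 1e-9)
  expect_equal(m1$lipid_area, m0$lipid_area, tolerance = 1e-9)
  expect_equal(m1$stenosis_fraction, m0$stenosis_fraction, tolerance = 1e-9)
})
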