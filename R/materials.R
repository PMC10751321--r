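# Constitutive models for plaque tissues. All moduli in kPa, D-type
# volumetric parameters in 1/kPa. Plane-strain kinematics embed the 2D
# deformation gradient into 3D with F33 = 1, so the invariants I1 and J keep
# their 3D definitions.
#
# Strain-energy functions (isochoric invariants Ibar = J^(-2/3) I, the
# convention whose small-strain limit the E/nu parameter conversions match):
#   Neo-Hooke:  Psi = C10 (Ibar1 - 3) + (1/D1) (J - 1)^2
#   GOH:        Psi = (1/D) (J - 1)^2 + mu (Ibar1 - 3)
#                     + k1/(2 k2) sum_{i=4,6} [exp(k2 Ei^2) - 1],
#               Ei = kappa (Ibar1 - 3) + (1 - 3 kappa) (Ibar_i - 1)
# With kappa = 1/3 the fiber term is isotropic and both families coincide.
# See the methods vignette for the relation to the canonical dispersed-fiber
# form and for why the isochoric split is used.

#' Linear elastic material
#'
#' @param E Young's modulus, kPa.
#' @param nu Poisson ratio, in (0, 0.5).
#' @return object of class `linear_elastic` / `plaque_material`.
#' @export
linear_elastic <- function(E, nu) {
  stopifnot(E > 0, nu > 0, nu < 0.5)
  structure(list(E = E, nu = nu),
            class = c("linear_elastic", "plaque_material"))
}

#' Neo-Hookean material
#'
#' @param C10 shear-like stiffness coefficient, kPa.
#' @param D1 volumetric compliance, 1/kPa.
#' @return object of class `neo_hooke` / `plaque_material`.
#' @export
neo_hooke <- function(C10, D1) {
  stopifnot(C10 > 0, D1 > 0)
  structure(list(C10 = C10, D1 = D1),
            class = c("neo_hooke", "plaque_material"))
}

#' Gasser-Ogden-Holzapfel material
#'
#' `mu` is the ground-matrix stiffness (often written C10 for this model);
#' `k1` and `k2` set the exponential fiber response; `kappa` is the fiber
#' dispersion, fixed at 1/3 for an isotropic fiber response in this work.
#' With `kappa = 1/3` the fiber directions are inert.
#'
#' @param mu ground-matrix stiffness, kPa (alias `c10`).
#' @param k1 fiber stiffness, kPa.
#' @param k2 dimensionless exponential shape factor.
#' @param D volumetric compliance, 1/kPa (default 0.005).
#' @param kappa fiber dispersion in \[0, 1/3\] (default 0.3333).
#' @param fiber_angles angles (rad) of the two in-plane fiber families.
#' @return object of class `goh` / `plaque_material`.
#' @export
goh <- function(mu, k1, k2, D = 0.005, kappa = 0.3333,
                fiber_angles = c(0, pi / 2)) {
  stopifnot(mu > 0, k1 > 0, k2 > 0, D > 0, kappa >= 0, kappa <= 1 / 3 + 1e-9)
  structure(list(mu = mu, k1 = k1, k2 = k2, D = D, kappa = kappa,
                 fiber_angles = fiber_angles),
            class = c("goh", "plaque_material"))
}

#' Reference GOH parameter sets for fibrotic tissue
#'
#' Literature-fitted parameter sets for calcified, cellular and hypocellular
#' fibrotic tissue (`D = 0.005` kPa^-1, `kappa = 0.3333` throughout).
#'
#' @param name one of `"calcified1"`, `"calcified2"`, `"cellular"`,
#'   `"hypocellular"`.
#' @return a [goh()] material.
#' @export
fibrotic_goh <- function(name = c("calcified1", "calcified2", "cellular",
                                  "hypocellular")) {
  name <- match.arg(name)
  p <- switch(name,
    calcified1   = c(9.58,  17564,    0.51),
    calcified2   = c(17.29, 13968.82, 3.36),
    cellular     = c(0.1,   1948.80,  3.36),
    hypocellular = c(139.32, 15918,   0.1))
  goh(mu = p[1], k1 = p[2], k2 = p[3])
}

#' Convert linear elastic constants to Neo-Hookean parameters
#'
#' `C10 = E / (4 (1 + nu))`, `D1 = 6 (1 - 2 nu) / E`.
#'
#' @param E Young's modulus, kPa.
#' @param nu Poisson ratio in (0, 0.5) (`nu >= 0.5` would give `D1 <= 0`).
#' @return list with `C10` (kPa) and `D1` (1/kPa).
#' @export
neo_hooke_from_linear <- function(E, nu) {
  stopifnot(E > 0)
  if (nu <= 0 || nu >= 0.5) stopf("nu must lie in (0, 0.5)")
  list(C10 = E / (4 * (1 + nu)), D1 = 6 * (1 - 2 * nu) / E)
}

#' Convert Neo-Hookean parameters to linear elastic constants
#'
#' Unique closed-form inverse of [neo_hooke_from_linear()]:
#' `nu = (6 - 4 C10 D1) / (12 + 4 C10 D1)`, `E = 4 (1 + nu) C10`.
#'
#' @param C10 kPa.
#' @param D1 1/kPa.
#' @return list with `E` (kPa) and `nu`.
#' @export
linear_from_neo_hooke <- function(C10, D1) {
  stopifnot(C10 > 0, D1 > 0)
  nu <- (6 - 4 * C10 * D1) / (12 + 4 * C10 * D1)
  if (nu <= 0 || nu >= 0.5) stopf("parameters imply nu outside (0, 0.5)")
  list(E = 4 * (1 + nu) * C10, nu = nu)
}

#' Plane-strain kinematics from a 2D deformation gradient
#'
#' Embeds the in-plane deformation gradient into 3D with `F33 = 1` and no
#' out-of-plane shear, and evaluates `J = det F`, `I1 = tr(F^T F)` and the
#' squared fiber stretches `I4`, `I6` along two in-plane fiber families.
#'
#' @param F2 2 x 2 in-plane deformation gradient.
#' @param fiber_angles angles (rad) of the two fiber families.
#' @return object of class `kinematics`.
#' @export
kinematics <- function(F2, fiber_angles = c(0, pi / 2)) {
  stopifnot(is.matrix(F2), all(dim(F2) == 2))
  J <- F2[1, 1] * F2[2, 2] - F2[1, 2] * F2[2, 1]
  if (J <= 0) stopf("J <= 0: invalid deformation state", class = "kinematics_error")
  C2 <- t(F2) %*% F2
  I1 <- sum(diag(C2)) + 1
  a <- cbind(cos(fiber_angles), sin(fiber_angles))
  I46 <- vapply(1:2, function(i) drop(a[i, ] %*% C2 %*% a[i, ]), 0)
  beta <- J^(-2 / 3)
  structure(list(F2 = F2, C2 = C2, J = J, I1 = I1,
                 I4 = I46[1], I6 = I46[2],
                 Ib1 = beta * I1, Ib4 = beta * I46[1], Ib6 = beta * I46[2],
                 beta = beta, fiber_angles = fiber_angles),
            class = "kinematics")
}

#' Strain energy density
#'
#' Evaluates the strain-energy function of a material at a plane-strain
#' kinematic state. Zero at the identity for every model.
#'
#' @param material a `plaque_material`.
#' @param kin a [kinematics()] state.
#' @return energy density, kPa.
#' @export
strain_energy <- function(material, kin) UseMethod("strain_energy")

#' @export
strain_energy.neo_hooke <- function(material, kin) {
  material$C10 * (kin$Ib1 - 3) + (1 / material$D1) * (kin$J - 1)^2
}

#' @export
strain_energy.goh <- function(material, kin) {
  k <- material$kappa
  Ei <- k * (kin$Ib1 - 3) + (1 - 3 * k) * (c(kin$Ib4, kin$Ib6) - 1)
  (1 / material$D) * (kin$J - 1)^2 + material$mu * (kin$Ib1 - 3) +
    material$k1 / (2 * material$k2) * sum(exp(material$k2 * Ei^2) - 1)
}

#' @export
strain_energy.linear_elastic <- function(material, kin) {
  # Saint Venant-Kirchhoff extension: quadratic in the Green strain
  Eg <- (kin$C2 - diag(2)) / 2
  lam <- material$E * material$nu / ((1 + material$nu) * (1 - 2 * material$nu))
  mu <- material$E / (2 * (1 + material$nu))
  tr <- Eg[1, 1] + Eg[2, 2]   # E33 = 0 in plane strain
  lam / 2 * tr^2 + mu * sum(Eg * Eg)
}

#' Cauchy stress tensor
#'
#' Push-forward of the second Piola-Kirchhoff stress `S = 2 dPsi/dC` to the
#' current configuration, `sigma = J^-1 F S F^T`, including the out-of-plane
#' (plane-strain) component `sigma_33`.
#'
#' @param material a `plaque_material`.
#' @param kin a [kinematics()] state.
#' @return 3 x 3 symmetric Cauchy stress, kPa.
#' @export
cauchy_stress <- function(material, kin) UseMethod("cauchy_stress")

cauchy_from_S <- function(kin, S2, S33) {
  s2 <- kin$F2 %*% S2 %*% t(kin$F2) / kin$J
  out <- matrix(0, 3, 3)
  out[1:2, 1:2] <- (s2 + t(s2)) / 2
  out[3, 3] <- S33 / kin$J
  out
}

#' @export
cauchy_stress.neo_hooke <- function(material, kin) {
  Cinv <- solve(kin$C2)
  b <- kin$beta
  g <- (2 / material$D1) * (kin$J - 1) * kin$J
  S2 <- 2 * material$C10 * b * (diag(2) - kin$I1 / 3 * Cinv) + g * Cinv
  S33 <- 2 * material$C10 * b * (1 - kin$I1 / 3) + g    # Cinv_33 = 1
  cauchy_from_S(kin, S2, S33)
}

#' @export
cauchy_stress.goh <- function(material, kin) {
  k <- material$kappa
  Cinv <- solve(kin$C2)
  b <- kin$beta
  g <- (2 / material$D) * (kin$J - 1) * kin$J
  S2 <- 2 * material$mu * b * (diag(2) - kin$I1 / 3 * Cinv) + g * Cinv
  S33 <- 2 * material$mu * b * (1 - kin$I1 / 3) + g
  a <- cbind(cos(material$fiber_angles), sin(material$fiber_angles))
  I46 <- c(kin$I4, kin$I6)
  for (i in 1:2) {
    W <- k * kin$I1 + (1 - 3 * k) * I46[i]
    Ei <- b * W - 1
    phi <- 2 * material$k1 * Ei * exp(material$k2 * Ei^2)
    H2 <- k * diag(2) + (1 - 3 * k) * (a[i, ] %o% a[i, ])
    S2 <- S2 + phi * b * (H2 - W / 3 * Cinv)
    S33 <- S33 + phi * b * (k - W / 3)
  }
  cauchy_from_S(kin, S2, S33)
}

#' @export
cauchy_stress.linear_elastic <- function(material, kin) {
  Eg <- (kin$C2 - diag(2)) / 2
  lam <- material$E * material$nu / ((1 + material$nu) * (1 - 2 * material$nu))
  mu <- material$E / (2 * (1 + material$nu))
  tr <- Eg[1, 1] + Eg[2, 2]
  S2 <- lam * tr * diag(2) + 2 * mu * Eg
  S33 <- lam * tr
  cauchy_from_S(kin, S2, S33)
}

#' Uniaxial incompressible tension curve
#'
#' Cauchy stress against stretch under incompressible uniaxial tension
#' (`lambda_2 = lambda_3 = lambda^-1/2`), the standard behavior-curve summary
#' for hyperelastic tissue. For a Neo-Hookean material this reduces to the
#' closed form `sigma = 2 C10 (lambda^2 - 1/lambda)`.
#'
#' @param material a `plaque_material`.
#' @param lambda_max maximum stretch (> 1), default 1.3.
#' @param n_points number of stretch samples, default 100.
#' @return object of class `behavior_curve`: list with `lambda` and `sigma`
#'   (kPa).
#' @export
uniaxial_curve <- function(material, lambda_max = 1.3, n_points = 100) {
  stopifnot(lambda_max > 1, n_points >= 2)
  lam <- seq(1, lambda_max, length.out = n_points)
  sigma <- vapply(lam, function(l) uniaxial_stress(material, l), 0)
  structure(list(lambda = lam, sigma = sigma), class = "behavior_curve")
}

#' Uniaxial incompressible Cauchy stress at a single stretch
#'
#' Pointwise evaluation backing [uniaxial_curve()].
#'
#' @param material a `plaque_material`.
#' @param lam stretch (>= 1).
#' @return Cauchy stress, kPa.
#' @export
uniaxial_stress <- function(material, lam) UseMethod("uniaxial_stress")

#' @export
uniaxial_stress.neo_hooke <- function(material, lam) {
  2 * material$C10 * (lam^2 - 1 / lam)
}

#' @export
uniaxial_stress.linear_elastic <- function(material, lam) {
  material$E * (lam - 1)
}

#' @export
uniaxial_stress.goh <- function(material, lam) {
  k <- material$kappa
  if (k < 0 || k > 1 / 3 + 1e-9) stopf("kappa outside [0, 1/3]")
  # incompressible uniaxial state: I1 = lam^2 + 2/lam; fiber families along
  # the loading axis contribute through I4 = I6 = lam^2 (isotropic at k=1/3)
  I1 <- lam^2 + 2 / lam
  dI1 <- 2 * lam - 2 / lam^2
  I4 <- lam^2
  dI4 <- 2 * lam
  W <- function(Ei, dEi) material$k1 * Ei * exp(material$k2 * Ei^2) * dEi
  sig <- material$mu * dI1
  for (i in 1:2) {
    Ei <- k * (I1 - 3) + (1 - 3 * k) * (I4 - 1)
    dEi <- k * dI1 + (1 - 3 * k) * dI4
    sig <- sig + W(Ei, dEi)
  }
  lam * sig
}

#' Coefficient of determination between behavior curves
#'
#' `R^2 = 1 - sum((ref - cand)^2) / sum((ref - mean(ref))^2)`, computed on a
#' shared stretch grid; equals 1 iff the curves are identical.
#'
#' @param reference,candidate `behavior_curve` objects on identical grids.
#' @return dimensionless R^2 (can be negative for poor candidates).
#' @export
curve_r2 <- function(reference, candidate) {
  if (length(reference$lambda) != length(candidate$lambda) ||
      max(abs(reference$lambda - candidate$lambda)) > 1e-12)
    stopf("behavior curves must share the same stretch grid")
  ss_tot <- sum((reference$sigma - mean(reference$sigma))^2)
  if (ss_tot <= 0) stopf("constant reference curve: R^2 undefined")
  1 - sum((reference$sigma - candidate$sigma)^2) / ss_tot
}

#' Latin hypercube sample of a parameter box
#'
#' Stratified space-filling sample: per dimension exactly one point falls in
#' each of `n` equal strata. Deterministic for a fixed seed.
#'
#' @param ranges list of `c(lo, hi)` per dimension.
#' @param n number of samples.
#' @param seed integer seed.
#' @return n x d matrix of parameter vectors.
#' @export
lhs_sample <- function(ranges, n, seed = 1L) {
  stopifnot(n >= 1, length(ranges) >= 1)
  for (r in ranges) stopifnot(length(r) == 2, r[1] < r[2])
  u <- with_seed(seed, lhs::randomLHS(n, length(ranges)))
  out <- sapply(seq_along(ranges), function(j) {
    ranges[[j]][1] + u[, j] * (ranges[[j]][2] - ranges[[j]][1])
  })
  matrix(out, nrow = n)
}

#' Assemble a material set for a labeled mesh
#'
#' A material set is a named list mapping every tissue label of a mesh to a
#' `plaque_material`. Validates one-to-one coverage against mesh labels.
#'
#' @param ... named materials, e.g. `fibrotic = goh(...)`.
#' @param .list alternatively, a named list of materials.
#' @return object of class `material_set`.
#' @export
material_set <- function(..., .list = NULL) {
  mats <- .list %||% list(...)
  stopifnot(length(mats) > 0, !is.null(names(mats)), all(nzchar(names(mats))))
  for (m in mats) stopifnot(inherits(m, "plaque_material"))
  structure(mats, class = "material_set")
}

check_materials_cover <- function(materials, mesh) {
  missing <- setdiff(unique(mesh$labels), names(materials))
  if (length(missing))
    stopf("material set lacks labels: %s", paste(missing, collapse = ", "))
  invisible(TRUE)
}
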