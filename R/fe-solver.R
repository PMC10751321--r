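# Plane-strain finite-element solver on 3-node linear triangles (the direct
# analog of CPE3): displacement formulation, one-point integration, total-
# Lagrangian kinematics with an exact consistent tangent, follower lumen
# pressure, Newton iteration with automatic load-step bisection. Assembly is
# vectorized across elements; linear systems use Matrix sparse LU.

#' Solver configuration
#'
#' @param load_steps initial number of equal pressure increments.
#' @param newton_tol relative residual norm for convergence.
#' @param newton_max_iter Newton iterations per load step.
#' @param max_bisections bound on automatic load-step halvings.
#' @param follower_pressure treat the lumen pressure as a follower load
#'   (normal to the deforming surface).
#' @return object of class `solver_config`.
#' @export
solver_config <- function(load_steps = 10L, newton_tol = 1e-8,
                          newton_max_iter = 25L, max_bisections = 6L,
                          follower_pressure = TRUE) {
  stopifnot(load_steps >= 1, newton_tol > 0)
  structure(list(load_steps = as.integer(load_steps), newton_tol = newton_tol,
                 newton_max_iter = as.integer(newton_max_iter),
                 max_bisections = as.integer(max_bisections),
                 follower_pressure = follower_pressure),
            class = "solver_config")
}

# --- element precomputation -------------------------------------------------

fe_precompute <- function(nodes, tri) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  A <- ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
  if (min(A) <= 0) stopf("inverted element in reference configuration",
                         class = "fe_error")
  inv2A <- 1 / (2 * A)
  # dN_a/dx = b[, a], dN_a/dy = c[, a]
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) * inv2A
  c_ <- cbind(x3 - x2, x1 - x3, x2 - x1) * inv2A
  M <- nrow(tri); ndof <- 2L * nrow(nodes)
  # dof index per (element, node a, comp i)
  dof <- array(0L, c(M, 3, 2))
  for (a in 1:3) for (i in 1:2) dof[, a, i] <- 2L * (tri[, a] - 1L) + i
  # sparse triplet pattern for the 36 entries of each element matrix,
  # column-major over (a, i) x (b, k)
  ii <- matrix(0L, M, 36); jj <- matrix(0L, M, 36)
  col <- 0L
  for (b_ in 1:3) for (k in 1:2) for (a in 1:3) for (i in 1:2) {
    col <- col + 1L
    ii[, col] <- dof[, a, i]; jj[, col] <- dof[, b_, k]
  }
  list(tri = tri, A = A, b = b, c = c_, dof = dof, ii = ii, jj = jj,
       M = M, ndof = ndof)
}

# Per-label material groups with per-element index sets.
material_groups <- function(mesh, materials) {
  check_materials_cover(materials, mesh)
  labs <- unique(mesh$labels)
  lapply(labs, function(l) {
    list(label = l, material = materials[[l]], elems = which(mesh$labels == l))
  })
}

accumulate <- function(idx, vals, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# --- follower lumen pressure ------------------------------------------------

# Nodal forces from pressure p (kPa) acting on the lumen edges evaluated at
# coordinates `xy`. Edges are oriented so rot90(b - a) = (-dy, dx) is the
# direction of the surface traction exerted by the lumen pressure on the wall.
lumen_forces <- function(edges, xy, p, ndof) {
  a <- edges[, 1]; b <- edges[, 2]
  dx <- xy[b, 1] - xy[a, 1]; dy <- xy[b, 2] - xy[a, 2]
  fx <- -p / 2 * dy; fy <- p / 2 * dx
  idx <- c(2L * a - 1L, 2L * b - 1L, 2L * a, 2L * b)
  accumulate(idx, c(fx, fx, fy, fy), ndof)
}

# --- constitutive point evaluation (vectorized per material group) ----------

# Given in-plane C (C11, C22, C12) and J on a group's elements, return stress
# components and structured tangent terms:
#   outer:    coef * T (x) U          (T, U symmetric 2x2, per element)
#   sandwich: coef * (T_MN T_JL + T_ML T_JN)
group_stress_tangent <- function(mat, C11, C22, C12, J) {
  detC <- C11 * C22 - C12^2
  i11 <- C22 / detC; i22 <- C11 / detC; i12 <- -C12 / detC
  one <- rep(1, length(C11)); zero <- rep(0, length(C11))
  Cinv <- list(T11 = i11, T22 = i22, T12 = i12)
  I2 <- list(T11 = one, T22 = one, T12 = zero)

  I1 <- C11 + C22 + 1
  beta <- J^(-2 / 3)

  # term lists reference basis tensors by name; identically-shaped terms are
  # merged by summing coefficients before assembly
  basis <- list(Cinv = Cinv, I = I2)
  outer <- list(); sandwich <- list()
  add_outer <- function(coef, Tn, Un) outer[[length(outer) + 1L]] <<-
    list(coef = coef, T = Tn, U = Un)
  add_sand <- function(coef, Tn) sandwich[[length(sandwich) + 1L]] <<-
    list(coef = coef, T = Tn)

  # isochoric term S = phi * beta * G, G = H - (W/3) Cinv named `Gn`
  iso_term <- function(phi, phiP, Gn, h33, W) {
    if (!is.null(phiP)) add_outer(2 * phiP * beta^2, Gn, Gn)
    add_outer(-2 * phi * beta / 3, Gn, "Cinv")
    add_outer(-2 * phi * beta / 3, "Cinv", Gn)
    add_outer(-2 * phi * beta * W / 9, "Cinv", "Cinv")
    add_sand(phi * beta * W / 3, "Cinv")
    G <- basis[[Gn]]
    list(S11 = phi * beta * G$T11, S22 = phi * beta * G$T22,
         S12 = phi * beta * G$T12, S33 = phi * beta * (h33 - W / 3))
  }

  if (inherits(mat, "neo_hooke") || inherits(mat, "goh")) {
    if (inherits(mat, "neo_hooke")) {
      Dvol <- mat$D1; mu <- mat$C10
    } else {
      Dvol <- mat$D; mu <- mat$mu
    }
    g <- (2 / Dvol) * (J - 1) * J
    S11 <- g * i11; S22 <- g * i22; S12 <- g * i12; S33 <- g + zero
    add_outer((2 / Dvol) * (2 * J - 1) * J, "Cinv", "Cinv")
    add_sand(-g, "Cinv")
    basis$Gm <- list(T11 = one - I1 / 3 * i11, T22 = one - I1 / 3 * i22,
                     T12 = -I1 / 3 * i12)
    sm <- iso_term(2 * mu + zero, NULL, "Gm", one, I1)
    S11 <- S11 + sm$S11; S22 <- S22 + sm$S22
    S12 <- S12 + sm$S12; S33 <- S33 + sm$S33
    if (inherits(mat, "goh")) {
      k <- mat$kappa
      isotropic_fibers <- abs(k - 1 / 3) < 1e-9
      ang <- mat$fiber_angles
      for (f in 1:2) {
        af <- c(cos(ang[f]), sin(ang[f]))
        A11 <- af[1]^2; A22 <- af[2]^2; A12 <- af[1] * af[2]
        I4 <- C11 * A11 + C22 * A22 + 2 * C12 * A12
        W <- k * I1 + (1 - 3 * k) * I4
        Ei <- beta * W - 1
        expo <- exp(mat$k2 * Ei^2)
        phi <- 2 * mat$k1 * Ei * expo
        phiP <- 2 * mat$k1 * (1 + 2 * mat$k2 * Ei^2) * expo
        if (isotropic_fibers) {
          # H = I/3 and W = I1/3, so G_fiber = Gm/3: the whole fiber term is
          # the matrix iso-term with phi/3 (and phi'/9 for the G x G block)
          sf <- iso_term(phi / 3, phiP / 9, "Gm", one, I1)
        } else {
          Gn <- paste0("Gf", f)
          basis[[Gn]] <- list(T11 = k + (1 - 3 * k) * A11 - W / 3 * i11,
                              T22 = k + (1 - 3 * k) * A22 - W / 3 * i22,
                              T12 = (1 - 3 * k) * A12 - W / 3 * i12)
          sf <- list(S11 = phi * beta * basis[[Gn]]$T11,
                     S22 = phi * beta * basis[[Gn]]$T22,
                     S12 = phi * beta * basis[[Gn]]$T12,
                     S33 = phi * beta * (k - W / 3))
          add_outer(2 * phiP * beta^2, Gn, Gn)
          add_outer(-2 * phi * beta / 3, Gn, "Cinv")
          add_outer(-2 * phi * beta / 3, "Cinv", Gn)
          add_outer(-2 * phi * beta * W / 9, "Cinv", "Cinv")
          add_sand(phi * beta * W / 3, "Cinv")
        }
        S11 <- S11 + sf$S11; S22 <- S22 + sf$S22
        S12 <- S12 + sf$S12; S33 <- S33 + sf$S33
      }
    }
  } else if (inherits(mat, "linear_elastic")) {
    # Saint Venant-Kirchhoff extension of the linear law
    lam <- mat$E * mat$nu / ((1 + mat$nu) * (1 - 2 * mat$nu))
    mu <- mat$E / (2 * (1 + mat$nu))
    E11 <- (C11 - 1) / 2; E22 <- (C22 - 1) / 2; E12 <- C12 / 2
    tr <- E11 + E22
    S11 <- lam * tr + 2 * mu * E11; S22 <- lam * tr + 2 * mu * E22
    S12 <- 2 * mu * E12; S33 <- lam * tr
    add_outer(lam + zero, "I", "I")
    add_sand(mu + zero, "I")
  } else stopf("unsupported material class: %s", class(mat)[1])

  # merge terms with identical basis shapes
  okey <- vapply(outer, function(t) paste(t$T, t$U), "")
  outer <- lapply(split(seq_along(outer), okey), function(idx) {
    list(coef = Reduce(`+`, lapply(outer[idx], `[[`, "coef")),
         T = outer[[idx[1]]]$T, U = outer[[idx[1]]]$U)
  })
  skey <- vapply(sandwich, `[[`, "", "T")
  sandwich <- lapply(split(seq_along(sandwich), skey), function(idx) {
    list(coef = Reduce(`+`, lapply(sandwich[idx], `[[`, "coef")),
         T = sandwich[[idx[1]]]$T)
  })
  list(S11 = S11, S22 = S22, S12 = S12, S33 = S33,
       outer = outer, sandwich = sandwich, basis = basis)
}

# --- nonlinear assembly -----------------------------------------------------

# Deformation state per element from nodal displacements.
element_state <- function(pre, u) {
  ux <- matrix(u[2 * (as.vector(pre$tri)) - 1], ncol = 3)
  uy <- matrix(u[2 * (as.vector(pre$tri))], ncol = 3)
  H11 <- rowSums(ux * pre$b); H12 <- rowSums(ux * pre$c)
  H21 <- rowSums(uy * pre$b); H22 <- rowSums(uy * pre$c)
  F11 <- 1 + H11; F12 <- H12; F21 <- H21; F22 <- 1 + H22
  J <- F11 * F22 - F12 * F21
  list(F11 = F11, F12 = F12, F21 = F21, F22 = F22, J = J,
       C11 = F11^2 + F21^2, C22 = F12^2 + F22^2,
       C12 = F11 * F12 + F21 * F22)
}

# Internal force and (optionally) tangent stiffness at displacement u.
assemble_internal <- function(pre, groups, st, want_K = TRUE) {
  M <- pre$M
  S11 <- numeric(M); S22 <- numeric(M); S12 <- numeric(M); S33 <- numeric(M)
  terms <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]; e <- g$elems
    ct <- group_stress_tangent(g$material, st$C11[e], st$C22[e], st$C12[e], st$J[e])
    S11[e] <- ct$S11; S22[e] <- ct$S22; S12[e] <- ct$S12; S33[e] <- ct$S33
    terms[[gi]] <- ct
  }

  # internal force: f[(a,i)] = A * P_iJ G_aJ, P = F S
  P11 <- st$F11 * S11 + st$F12 * S12
  P12 <- st$F11 * S12 + st$F12 * S22
  P21 <- st$F21 * S11 + st$F22 * S12
  P22 <- st$F21 * S12 + st$F22 * S22
  A <- pre$A
  fidx <- integer(0); fval <- numeric(0)
  for (a in 1:3) {
    fidx <- c(fidx, pre$dof[, a, 1], pre$dof[, a, 2])
    fval <- c(fval, A * (P11 * pre$b[, a] + P12 * pre$c[, a]),
                    A * (P21 * pre$b[, a] + P22 * pre$c[, a]))
  }
  fint <- accumulate(fidx, fval, pre$ndof)
  out <- list(fint = fint, S = cbind(S11, S22, S12, S33))
  if (!want_K) return(out)

  # tangent: per (a,i,b,k) combination, vectorized over elements; per-term
  # nodal projections are precomputed once (6 or 9 arrays per term)
  b_ <- pre$b; c_ <- pre$c
  gTg_all <- function(T) {  # M x 9: G_a T G_b for (a,b) column-major
    w1 <- cbind(T$T11 * b_[, 1] + T$T12 * c_[, 1],
                T$T11 * b_[, 2] + T$T12 * c_[, 2],
                T$T11 * b_[, 3] + T$T12 * c_[, 3])
    w2 <- cbind(T$T12 * b_[, 1] + T$T22 * c_[, 1],
                T$T12 * b_[, 2] + T$T22 * c_[, 2],
                T$T12 * b_[, 3] + T$T22 * c_[, 3])
    out <- matrix(0, M, 9)
    for (a in 1:3) for (bb in 1:3)
      out[, (bb - 1L) * 3L + a] <- b_[, a] * w1[, bb] + c_[, a] * w2[, bb]
    out
  }
  FT <- function(T) list(  # Q = F T (T symmetric)
    Q11 = st$F11 * T$T11 + st$F12 * T$T12,
    Q12 = st$F11 * T$T12 + st$F12 * T$T22,
    Q21 = st$F21 * T$T11 + st$F22 * T$T12,
    Q22 = st$F21 * T$T12 + st$F22 * T$T22)
  gQ_all <- function(Q) {  # M x 6: G_a . Q_i rows, (a,i) with i fastest
    out <- matrix(0, M, 6)
    for (a in 1:3) {
      out[, 2L * a - 1L] <- b_[, a] * Q$Q11 + c_[, a] * Q$Q12
      out[, 2L * a]      <- b_[, a] * Q$Q21 + c_[, a] * Q$Q22
    }
    out
  }
  geo <- gTg_all(list(T11 = S11, T22 = S22, T12 = S12))

  full_terms <- list()
  for (gi in seq_along(groups)) {
    e <- groups[[gi]]$elems
    expand <- function(v) { o <- numeric(M); o[e] <- v; o }
    used <- unique(c(vapply(terms[[gi]]$outer, `[[`, "", "T"),
                     vapply(terms[[gi]]$outer, `[[`, "", "U"),
                     vapply(terms[[gi]]$sandwich, `[[`, "", "T")))
    Texp <- list(); gQb <- list(); gTgb <- list(); Qb <- list()
    for (nm in used) {
      T0 <- terms[[gi]]$basis[[nm]]
      Te <- list(T11 = expand(T0$T11), T22 = expand(T0$T22),
                 T12 = expand(T0$T12))
      Texp[[nm]] <- Te
      Qb[[nm]] <- FT(Te)
      gQb[[nm]] <- gQ_all(Qb[[nm]])
    }
    for (tm in terms[[gi]]$outer)
      full_terms[[length(full_terms) + 1L]] <-
        list(type = "outer", coef = expand(tm$coef),
             gT = gQb[[tm$T]], gU = gQb[[tm$U]])
    for (tm in terms[[gi]]$sandwich) {
      Q <- Qb[[tm$T]]
      full_terms[[length(full_terms) + 1L]] <- list(
        type = "sandwich", coef = expand(tm$coef),
        gTg = gTg_all(Texp[[tm$T]]), gQ = gQb[[tm$T]],
        Bt = cbind(Q$Q11 * st$F11 + Q$Q12 * st$F12,   # B11
                   Q$Q11 * st$F21 + Q$Q12 * st$F22,   # B12
                   Q$Q21 * st$F11 + Q$Q22 * st$F12,   # B21
                   Q$Q21 * st$F21 + Q$Q22 * st$F22))  # B22
    }
  }

  vals <- matrix(0, M, 36)
  col <- 0L
  for (bb in 1:3) for (k in 1:2) for (a in 1:3) for (i in 1:2) {
    col <- col + 1L
    ab <- (bb - 1L) * 3L + a
    ai <- 2L * a - 2L + i; bk <- 2L * bb - 2L + k
    v <- if (i == k) geo[, ab] else numeric(M)
    for (tm in full_terms) {
      if (tm$type == "outer") {
        v <- v + tm$coef * tm$gT[, ai] * tm$gU[, bk]
      } else {
        bik <- if (i == 1) (if (k == 1) 1L else 2L) else (if (k == 1) 3L else 4L)
        v <- v + tm$coef * (tm$Bt[, bik] * tm$gTg[, ab] +
                              tm$gQ[, 2L * a - 2L + k] * tm$gQ[, 2L * bb - 2L + i])
      }
    }
    vals[, col] <- A * v
  }
  out$Kvals <- vals
  out
}

# --- Newton solve -----------------------------------------------------------

default_fixed_dofs <- function(mesh) {
  sort(c(2L * mesh$fixed_nodes - 1L, 2L * mesh$fixed_nodes))
}

nonlinear_solve <- function(pre, groups, mesh, coords, p_kPa, config,
                            fixed_dofs, u0 = NULL, p_start = 0) {
  ndof <- pre$ndof
  free <- setdiff(seq_len(ndof), fixed_dofs)
  u <- u0 %||% numeric(ndof)
  p_done <- p_start
  dp0 <- max(p_kPa - p_start, 0) / config$load_steps; dp <- dp0
  bisections <- 0L
  path <- list()
  resid <- NA_real_

  # Dirichlet handling by elimination on the triplet level (precomputed masks)
  is_fixed <- logical(ndof); is_fixed[fixed_dofs] <- TRUE
  iiK <- as.vector(pre$ii); jjK <- as.vector(pre$jj)
  maskK <- !(is_fixed[iiK] | is_fixed[jjK])
  iiK <- iiK[maskK]; jjK <- jjK[maskK]
  ed <- mesh$lumen_edges
  a_ <- ed[, 1]; b2 <- ed[, 2]
  iiF <- c(2L * a_ - 1L, 2L * a_, 2L * b2 - 1L, 2L * b2,
           2L * a_ - 1L, 2L * a_, 2L * b2 - 1L, 2L * b2)
  jjF <- c(2L * b2, 2L * b2 - 1L, 2L * b2, 2L * b2 - 1L,
           2L * a_, 2L * a_ - 1L, 2L * a_, 2L * a_ - 1L)
  # follower-load tangent values per unit pressure (subtracted from K)
  ne <- length(a_)
  xF <- c(rep(c(-0.5, 0.5), 2, each = ne), rep(c(0.5, -0.5), 2, each = ne))
  maskF <- !(is_fixed[iiF] | is_fixed[jjF])
  iiF <- iiF[maskF]; jjF <- jjF[maskF]; xF <- xF[maskF]

  newton <- function(p_try, u_start) {
    u <- u_start
    for (it in seq_len(config$newton_max_iter)) {
      st <- element_state(pre, u)
      if (min(st$J) <= 0) return(list(ok = FALSE, why = "element inversion"))
      xy <- coords + matrix(u, ncol = 2, byrow = TRUE)
      fext <- lumen_forces(mesh$lumen_edges, xy, p_try, ndof)
      asm <- assemble_internal(pre, groups, st, want_K = TRUE)
      r <- asm$fint - fext
      r[fixed_dofs] <- 0
      ref <- max(sqrt(sum(fext[free]^2)), 1e-10)
      rn <- sqrt(sum(r^2))
      if (!is.finite(rn) || rn > 1e8 * ref)
        return(list(ok = FALSE, why = "residual blow-up"))
      if (rn <= config$newton_tol * ref)
        return(list(ok = TRUE, u = u, resid = rn / ref, st = st, asm = asm))
      xK <- as.vector(asm$Kvals)[maskK]
      if (config$follower_pressure) {
        K <- Matrix::sparseMatrix(
          i = c(iiK, iiF, fixed_dofs), j = c(jjK, jjF, fixed_dofs),
          x = c(xK, -p_try * xF, rep(1, length(fixed_dofs))),
          dims = c(ndof, ndof))
      } else {
        K <- Matrix::sparseMatrix(
          i = c(iiK, fixed_dofs), j = c(jjK, fixed_dofs),
          x = c(xK, rep(1, length(fixed_dofs))), dims = c(ndof, ndof))
      }
      du <- tryCatch(as.numeric(Matrix::solve(K, -r)),
                     error = function(e) NULL)
      if (is.null(du) || any(!is.finite(du)))
        return(list(ok = FALSE, why = "singular tangent"))
      u <- u + du
    }
    list(ok = FALSE, why = "max iterations")
  }

  last <- NULL
  while (p_done < p_kPa - 1e-12 * max(p_kPa, 1)) {
    p_try <- min(p_done + dp, p_kPa)
    res <- newton(p_try, u)
    if (res$ok) {
      u <- res$u; p_done <- p_try; last <- res; resid <- res$resid
      path[[length(path) + 1L]] <- c(pressure_kPa = p_try, residual = res$resid)
      dp <- min(dp * 1.5, dp0)
    } else {
      bisections <- bisections + 1L
      if (bisections > config$max_bisections)
        stopf("load stepping failed at %.3f kPa after %d bisections (%s)",
              p_try, bisections - 1L, res$why, class = "fe_nonconvergence")
      dp <- dp / 2
    }
  }
  if (is.null(last)) {  # no stepping required (e.g. zero pressure)
    st <- element_state(pre, u)
    last <- list(st = st, asm = assemble_internal(pre, groups, st, want_K = FALSE),
                 resid = 0)
    resid <- 0
  }
  list(u = u, state = last$st, S = last$asm$S, residual = resid, path = path)
}

# --- public solver interface ------------------------------------------------

#' Inflate a labeled mesh to a lumen pressure
#'
#' Quasi-static plane-strain inflation of the mesh reference configuration to
#' the requested lumen pressure, with the pressure applied as a follower load
#' on the lumen edges and rigid-body motion removed through the mesh's three
#' pinned outer nodes (or an explicit `fixed_dofs` set, e.g. symmetry rollers
#' for oracle studies). Newton divergence triggers automatic load-step
#' bisection before a hard failure.
#'
#' @param mesh a `labeled_mesh`.
#' @param materials a [material_set()] covering all mesh labels.
#' @param pressure lumen pressure, mmHg.
#' @param config a [solver_config()].
#' @param coords optional N x 2 replacement reference coordinates (same
#'   topology), e.g. a recovered zero-pressure geometry.
#' @param fixed_dofs optional integer dof indices (2i-1 = x of node i) to fix;
#'   defaults to both components of `mesh$fixed_nodes`.
#' @return object of class `fe_solution`: nodal `displacements` (N x 2, mm),
#'   per-element deformation gradient `F` (M x 4: F11, F12, F21, F22), Cauchy
#'   stress `stress` (M x 4: s11, s22, s12, s33, kPa), `converged`,
#'   `pressure` (mmHg), `path` of accepted load steps.
#' @export
inflate <- function(mesh, materials, pressure, config = solver_config(),
                    coords = NULL, fixed_dofs = NULL) {
  stopifnot(inherits(mesh, "labeled_mesh"), pressure >= 0)
  coords <- coords %||% mesh$nodes
  pre <- fe_precompute(coords, mesh$triangles)
  groups <- material_groups(mesh, materials)
  fixed_dofs <- fixed_dofs %||% default_fixed_dofs(mesh)
  sol <- nonlinear_solve(pre, groups, mesh, coords, mmHg_to_kPa(pressure),
                         config, fixed_dofs)
  st <- sol$state
  J <- st$J
  s11 <- (st$F11 * (st$F11 * sol$S[, 1] + st$F12 * sol$S[, 3]) +
            st$F12 * (st$F11 * sol$S[, 3] + st$F12 * sol$S[, 2])) / J
  s22 <- (st$F21 * (st$F21 * sol$S[, 1] + st$F22 * sol$S[, 3]) +
            st$F22 * (st$F21 * sol$S[, 3] + st$F22 * sol$S[, 2])) / J
  s12 <- (st$F21 * (st$F11 * sol$S[, 1] + st$F12 * sol$S[, 3]) +
            st$F22 * (st$F11 * sol$S[, 3] + st$F12 * sol$S[, 2])) / J
  s33 <- sol$S[, 4] / J
  structure(list(
    displacements = matrix(sol$u, ncol = 2, byrow = TRUE),
    F = cbind(F11 = st$F11, F12 = st$F12, F21 = st$F21, F22 = st$F22),
    stress = cbind(s11 = s11, s22 = s22, s12 = s12, s33 = s33),
    converged = TRUE, residual = sol$residual,
    pressure = pressure, path = sol$path,
    coords = coords, mesh = mesh, materials = materials,
    fixed_dofs = fixed_dofs, config = config
  ), class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("<fe_solution> %.1f mmHg, %d nodes, max |u| = %.4f mm, residual %.2e\n",
              x$pressure, nrow(x$displacements),
              max(sqrt(rowSums(x$displacements^2))), x$residual))
  invisible(x)
}

#' Small linear-elastic pressure increment
#'
#' Single linear solve for a small lumen pressure increment `dP` applied on
#' the given configuration with all tissues linear elastic — the forward model
#' of the linear characterization, where a 5 mmHg step between imaging frames
#' justifies infinitesimal-strain theory. Displacements scale exactly linearly
#' with `dP`.
#'
#' @param mesh a `labeled_mesh`.
#' @param materials [material_set()] of `linear_elastic` entries only.
#' @param dP pressure increment, mmHg.
#' @param coords optional configuration coordinates (defaults to mesh nodes).
#' @param fixed_dofs optional fixed dof indices.
#' @return N x 2 matrix of nodal displacements, mm.
#' @export
inflate_linear_increment <- function(mesh, materials, dP, coords = NULL,
                                     fixed_dofs = NULL) {
  for (m in materials)
    if (!inherits(m, "linear_elastic"))
      stopf("all materials must be linear_elastic")
  coords <- coords %||% mesh$nodes
  groups <- material_groups(mesh, materials)
  E <- numeric(nrow(mesh$triangles)); nu <- numeric(nrow(mesh$triangles))
  for (g in groups) { E[g$elems] <- g$material$E; nu[g$elems] <- g$material$nu }
  pre <- fe_precompute(coords, mesh$triangles)
  K <- assemble_linear_K(pre, E, nu)
  f <- lumen_forces(mesh$lumen_edges, coords, mmHg_to_kPa(dP), pre$ndof)
  fixed_dofs <- fixed_dofs %||% default_fixed_dofs(mesh)
  free <- setdiff(seq_len(pre$ndof), fixed_dofs)
  u <- numeric(pre$ndof)
  sol <- tryCatch(Matrix::solve(K[free, free, drop = FALSE], f[free]),
                  error = function(e) stopf("singular linear system: %s",
                                            conditionMessage(e), class = "fe_error"))
  u[free] <- as.numeric(sol)
  matrix(u, ncol = 2, byrow = TRUE)
}

# Linear plane-strain stiffness with per-element E, nu.
assemble_linear_K <- function(pre, E, nu) {
  f <- E / ((1 + nu) * (1 - 2 * nu))
  d11 <- f * (1 - nu); d12 <- f * nu; d33 <- f * (1 - 2 * nu) / 2
  A <- pre$A; b_ <- pre$b; c_ <- pre$c
  vals <- matrix(0, pre$M, 36)
  col <- 0L
  for (bb in 1:3) for (k in 1:2) for (a in 1:3) for (i in 1:2) {
    col <- col + 1L
    vals[, col] <- A * (
      if (i == 1 && k == 1) d11 * b_[, a] * b_[, bb] + d33 * c_[, a] * c_[, bb]
      else if (i == 2 && k == 2) d11 * c_[, a] * c_[, bb] + d33 * b_[, a] * b_[, bb]
      else if (i == 1) d12 * b_[, a] * c_[, bb] + d33 * c_[, a] * b_[, bb]
      else d12 * c_[, a] * b_[, bb] + d33 * b_[, a] * c_[, bb])
  }
  Matrix::sparseMatrix(i = as.vector(pre$ii), j = as.vector(pre$jj),
                       x = as.vector(vals), dims = c(pre$ndof, pre$ndof))
}

# Per-tissue unit stiffness matrices (E = 1) for fast modulus sweeps:
# K(E_1..E_T) = sum_t E_t * Khat_t since K is linear in E at fixed nu.
linear_unit_stiffness <- function(mesh, coords, nu_by_label) {
  pre <- fe_precompute(coords, mesh$triangles)
  labs <- unique(mesh$labels)
  Khat <- lapply(labs, function(l) {
    E <- as.numeric(mesh$labels == l)
    nu <- rep(0.0, length(E)); nu[mesh$labels == l] <- nu_by_label[[l]]
    nu[mesh$labels != l] <- 0.3  # inert rows: E = 0 there
    assemble_linear_K(pre, E, nu)
  })
  names(Khat) <- labs
  list(Khat = Khat, pre = pre)
}

#' Strain fields from nodal displacements
#'
#' Infinitesimal strains from linear-triangle shape-function gradients
#' (constant per element), reported in Cartesian, cylindrical (about
#' `center`), principal, and von-Mises-equivalent form.
#'
#' @param mesh a `labeled_mesh` (topology and labels).
#' @param displacements N x 2 nodal displacements, mm.
#' @param center 2-vector, origin of the cylindrical frame (typically the
#'   lumen centroid of the measurement frame).
#' @param coords configuration on which strains are evaluated; defaults to
#'   the mesh reference coordinates.
#' @return object of class `strain_field`: per-element components `exx, eyy,
#'   exy, err, ett, ert, e1, e2, evm`, element `centroids`, the `center`, and
#'   the element `labels`.
#' @export
strain_fields <- function(mesh, displacements, center, coords = NULL) {
  coords <- coords %||% mesh$nodes
  pre <- fe_precompute(coords, mesh$triangles)
  u <- as.vector(t(displacements))
  ux <- matrix(u[2 * (as.vector(pre$tri)) - 1], ncol = 3)
  uy <- matrix(u[2 * (as.vector(pre$tri))], ncol = 3)
  exx <- rowSums(ux * pre$b)
  eyy <- rowSums(uy * pre$c)
  exy <- (rowSums(ux * pre$c) + rowSums(uy * pre$b)) / 2
  cent <- tri_centroids(coords, mesh$triangles)
  strain_field_from_cartesian(exx, eyy, exy, cent, center, mesh$labels)
}

#' Assemble a strain field from Cartesian components
#'
#' Derived components (cylindrical, principal, equivalent) are always
#' recomputed from the Cartesian tensor, so the rotation identities hold by
#' construction.
#'
#' @param exx,eyy,exy per-element Cartesian strains.
#' @param centroids M x 2 element centroids, mm.
#' @param center cylindrical origin, mm.
#' @param labels optional element labels.
#' @return a `strain_field`.
#' @export
strain_field_from_cartesian <- function(exx, eyy, exy, centroids, center,
                                        labels = NULL) {
  dx <- centroids[, 1] - center[1]; dy <- centroids[, 2] - center[2]
  r <- sqrt(dx^2 + dy^2)
  if (any(r < 1e-12))
    stopf("element centroid coincides with the cylindrical center")
  cth <- dx / r; sth <- dy / r
  err <- exx * cth^2 + eyy * sth^2 + 2 * exy * cth * sth
  ett <- exx * sth^2 + eyy * cth^2 - 2 * exy * cth * sth
  ert <- (eyy - exx) * cth * sth + exy * (cth^2 - sth^2)
  mean2 <- (exx + eyy) / 2
  rad <- sqrt(((exx - eyy) / 2)^2 + exy^2)
  e1 <- mean2 + rad; e2 <- mean2 - rad
  # von Mises equivalent strain of the plane-strain tensor (e_zz = 0)
  tr3 <- (exx + eyy) / 3
  dxx <- exx - tr3; dyy <- eyy - tr3; dzz <- -tr3
  evm <- sqrt(2 / 3 * (dxx^2 + dyy^2 + dzz^2 + 2 * exy^2))
  structure(list(exx = exx, eyy = eyy, exy = exy,
                 err = err, ett = ett, ert = ert,
                 e1 = e1, e2 = e2, evm = evm,
                 centroids = centroids, center = center, labels = labels),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("<strain_field> %d elements, mean err = %.3e\n",
              length(x$err), mean(x$err)))
  invisible(x)
}

#' Maximum principal Cauchy stress per element
#'
#' In-plane principal values by closed-form 2D eigendecomposition, compared
#' against the plane-strain out-of-plane component; the reported value is the
#' largest of the three.
#'
#' @param solution an [inflate()] solution.
#' @return object of class `stress_field` with `sigma_max` (kPa) per element
#'   and element centroids in the deformed configuration.
#' @export
max_principal_stress <- function(solution) {
  s <- solution$stress
  mean2 <- (s[, 1] + s[, 2]) / 2
  rad <- sqrt(((s[, 1] - s[, 2]) / 2)^2 + s[, 3]^2)
  smax <- pmax(mean2 + rad, s[, 4])
  xy <- solution$coords + solution$displacements
  structure(list(sigma_max = smax,
                 principal = cbind(p1 = mean2 + rad, p2 = mean2 - rad,
                                   p33 = s[, 4]),
                 centroids = tri_centroids(xy, solution$mesh$triangles),
                 labels = solution$mesh$labels),
            class = "stress_field")
}

#' Lamé thick-walled cylinder solution (plane strain)
#'
#' Radial displacement of a linear-elastic annulus with internal pressure `p`
#' and a free outer surface — the classical closed-form oracle for the
#' inflation solver.
#'
#' @param E Young's modulus, kPa.
#' @param nu Poisson ratio.
#' @param a,b inner and outer radii, mm.
#' @param p internal pressure, kPa.
#' @return function `u(r)` giving radial displacement in mm.
#' @export
lame_annulus <- function(E, nu, a, b, p) {
  stopifnot(a > 0, b > a)
  function(r) (1 + nu) * p * a^2 / (E * (b^2 - a^2)) *
    ((1 - 2 * nu) * r + b^2 / r)
}

#' Total strain energy of a solution
#'
#' Stored energy per unit out-of-plane thickness, integrated with one point
#' per element (consistent with the element formulation).
#'
#' @param solution an [inflate()] solution.
#' @return energy in kPa mm^2 (micro-J per mm thickness).
#' @export
total_strain_energy <- function(solution) {
  mesh <- solution$mesh
  pre <- fe_precompute(solution$coords, mesh$triangles)
  st <- element_state(pre, as.vector(t(solution$displacements)))
  groups <- material_groups(mesh, solution$materials)
  tot <- 0
  for (g in groups) {
    e <- g$elems
    psi <- vapply(e, function(k) {
      F2 <- matrix(c(st$F11[k], st$F21[k], st$F12[k], st$F22[k]), 2, 2)
      strain_energy(g$material, kinematics(F2))
    }, 0)
    tot <- tot + sum(pre$A[e] * psi)
  }
  tot
}

# Area enclosed by the lumen loop at given coordinates (used for
# pressure-volume work bookkeeping and as the cylindrical center).
lumen_polygon <- function(mesh, coords = NULL) {
  coords <- coords %||% mesh$nodes
  edges <- mesh$lumen_edges
  ord <- integer(nrow(edges))
  ord[1] <- 1L
  for (k in seq_len(nrow(edges) - 1)) {
    ord[k + 1] <- match(edges[ord[k], 1], edges[, 2])
  }
  coords[edges[ord, 2], , drop = FALSE]
}

lumen_centroid <- function(mesh, coords = NULL) {
  polygon_centroid(lumen_polygon(mesh, coords))
}
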