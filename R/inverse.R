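# Derivative-free inverse characterization. The cost is the NRMSE between
# measured and model radial strains (in percent); the optimizer is a
# Generating-Set-Search pattern search polling the coordinate directions in a
# range-normalized space, so the poll mesh size is expressed as a percentage
# of each parameter's search range (mesh 1 = 1% steps, mesh 100 = full-range
# jumps). Two pipelines sit on top: linear-elastic modulus recovery at a
# working pressure, and non-linear hyperelastic recovery with an embedded
# Pull-Back step per cost evaluation.

#' NRMSE strain cost (percent)
#'
#' `J0 = 100 * RMS(eps_ref - eps_it) / |mean(eps_ref)|`. Radial strains under
#' inflation are predominantly negative; the unsigned denominator keeps J0
#' positive. Zero iff the fields are identical; invariant under common
#' rescaling of both fields.
#'
#' @param eps_ref measured per-element radial strains.
#' @param eps_it model per-element radial strains (same elements).
#' @return cost in percent.
#' @export
nrmse_cost <- function(eps_ref, eps_it) {
  if (length(eps_ref) != length(eps_it) || length(eps_ref) < 1)
    stopf("strain vectors must have equal positive length")
  m <- mean(eps_ref)
  if (m == 0) stopf("mean reference strain is zero: normalization degenerate",
                    class = "degenerate_normalization")
  100 * sqrt(mean((eps_ref - eps_it)^2)) / abs(m)
}

#' Success rate of a modulus estimate (percent)
#'
#' `sr = 100 (1 - |E_real - E_est| / E_real)`; can be negative for gross
#' over-estimates (no clamping).
#'
#' @param E_real true Young's modulus, kPa (> 0).
#' @param E_est estimated Young's modulus, kPa.
#' @return percent.
#' @export
success_rate <- function(E_real, E_est) {
  if (E_real <= 0) stopf("E_real must be positive")
  100 * (1 - abs(E_real - E_est) / E_real)
}

#' Generating-Set-Search configuration
#'
#' @param initial_mesh initial poll mesh size in normalized units (percent of
#'   each parameter range): 1 for the linear pipeline, 100 for the
#'   non-linear one.
#' @param expansion mesh growth factor on a successful poll (2).
#' @param contraction mesh shrink factor on a failed poll (0.5).
#' @param cost_tol terminate when the cost, expressed as a fraction
#'   (percent / 100), drops below this value.
#' @param mesh_tol terminate when the poll mesh falls below this size.
#' @param max_evaluations budget of cost evaluations (the primary,
#'   hardware-independent budget).
#' @param time_budget optional wall-clock budget, seconds.
#' @param seed seed for the optional randomized start.
#' @param forcing sufficient-decrease constant: a poll step expands the mesh
#'   only if it lowers the cost by more than `forcing * (mesh / 100)^2`
#'   (cost units). Simple-decrease improvements below that threshold are
#'   still taken, but the mesh contracts — marginal gains along weakly
#'   identifiable parameters then cannot stall refinement of the parameters
#'   that matter. 0 restores plain simple-decrease expansion.
#' @return object of class `gss_config`.
#' @export
gss_config <- function(initial_mesh = 1, expansion = 2, contraction = 0.5,
                       cost_tol = 1e-4, mesh_tol = 0.01,
                       max_evaluations = 200L, time_budget = Inf, seed = NULL,
                       forcing = 5, poll = c("opportunistic", "complete")) {
  stopifnot(initial_mesh > 0, expansion > 1, contraction > 0, contraction < 1,
            forcing >= 0)
  poll <- match.arg(poll)
  structure(list(initial_mesh = initial_mesh, expansion = expansion,
                 contraction = contraction, cost_tol = cost_tol,
                 mesh_tol = mesh_tol,
                 max_evaluations = as.integer(max_evaluations),
                 time_budget = time_budget, seed = seed, forcing = forcing,
                 poll = poll),
            class = "gss_config")
}

#' Minimize a cost over a box by Generating Set Search
#'
#' Pattern search in range-normalized coordinates (each parameter affinely
#' mapped to \[0, 100\], so a poll step moves each raw parameter in
#' proportion to its search range — parameters with wider ranges get more
#' relevance). Each iteration polls the 2d coordinate directions
#' opportunistically in fixed order; a successful poll doubles the mesh, a
#' failed one halves it. Poll points are projected onto the box, failures of
#' the cost function count as infinite cost, and the incumbent is always
#' feasible.
#'
#' @param cost_fn function of a raw parameter vector returning a scalar cost
#'   (percent scale).
#' @param lower,upper numeric bounds per parameter.
#' @param config a [gss_config()].
#' @param x0 optional raw starting point; default is the box center
#'   (or a seeded random point if `config$seed` is set).
#' @return list with `par` (raw), `value`, `history` (data.frame: evaluation
#'   index, raw parameters, cost), `termination`, `n_evaluations`.
#' @export
gss_minimize <- function(cost_fn, lower, upper, config = gss_config(),
                         x0 = NULL) {
  stopifnot(length(lower) == length(upper), all(lower < upper))
  d <- length(lower)
  t_start <- Sys.time()
  to_raw <- function(z) lower + z / 100 * (upper - lower)
  to_norm <- function(x) 100 * (x - lower) / (upper - lower)

  hist_par <- list(); hist_cost <- numeric(0)
  n_eval <- 0L
  cache <- new.env(parent = emptyenv())  # clamped polls often repeat points
  safe_cost <- function(z) {
    key <- paste(signif(z, 12), collapse = ",")
    if (!is.null(v <- cache[[key]])) return(v)
    x <- to_raw(z)
    val <- tryCatch({
      v <- cost_fn(x)
      if (!is.finite(v)) Inf else v
    }, error = function(e) Inf)
    n_eval <<- n_eval + 1L
    hist_par[[n_eval]] <<- x
    hist_cost[n_eval] <<- val
    cache[[key]] <- val
    val
  }

  z <- if (!is.null(x0)) pmin(100, pmax(0, to_norm(x0)))
       else if (!is.null(config$seed)) with_seed(config$seed, stats::runif(d, 0, 100))
       else rep(50, d)
  f <- safe_cost(z)
  mesh <- config$initial_mesh
  termination <- "max_evaluations"

  budget_left <- function() {
    n_eval < config$max_evaluations &&
      as.numeric(difftime(Sys.time(), t_start, units = "secs")) < config$time_budget
  }

  # poll directions +/- e_i; opportunistic polling uses dynamic ordering
  # (the last successful direction is polled first), complete polling
  # evaluates the whole poll set and moves to the best candidate
  dirs <- rbind(cbind(seq_len(d), 1), cbind(seq_len(d), -1))
  ord <- seq_len(2 * d)
  complete <- identical(config$poll, "complete")
  while (budget_left()) {
    if (f / 100 <= config$cost_tol) { termination <- "cost_tol"; break }
    if (mesh < config$mesh_tol) { termination <- "mesh_tol"; break }
    success <- FALSE
    rho <- (config$forcing %||% 0) * (mesh / 100)^2
    best_c <- NULL; best_fc <- Inf
    for (k in ord) {
      i <- dirs[k, 1]; s <- dirs[k, 2]
      zc <- z
      zc[i] <- min(100, max(0, zc[i] + s * mesh))
      if (zc[i] == z[i]) next
      if (!budget_left()) break
      fc <- safe_cost(zc)
      if (fc < f) {
        if (complete) {
          if (fc < best_fc) { best_fc <- fc; best_c <- zc }
        } else if (fc < f - rho) {     # sufficient decrease: move and expand
          z <- zc; f <- fc; success <- TRUE
          ord <- c(k, ord[ord != k])
          break
        } else {                       # marginal decrease: bank it, contract
          z <- zc; f <- fc
        }
      }
    }
    if (complete && !is.null(best_c)) {
      if (best_fc < f - rho) success <- TRUE
      z <- best_c; f <- best_fc
    }
    if (!budget_left() && !success) break
    # poll steps beyond the full normalized range are meaningless: cap at 100
    mesh <- if (success) min(mesh * config$expansion, 100) else
      mesh * config$contraction
  }
  if (termination == "max_evaluations" &&
      as.numeric(difftime(Sys.time(), t_start, units = "secs")) >= config$time_budget)
    termination <- "time_budget"

  par_mat <- do.call(rbind, hist_par)
  colnames(par_mat) <- paste0("p", seq_len(d))
  history <- data.frame(evaluation = seq_len(n_eval), par_mat, J0 = hist_cost)
  best <- which.min(hist_cost)
  list(par = hist_par[[best]], value = hist_cost[best], history = history,
       termination = termination, n_evaluations = n_eval)
}

# --- search spaces ----------------------------------------------------------

#' Search space for the linear characterization
#'
#' One Young's modulus per tissue label; soft tissues (fibrotic, lipid) carry
#' a fixed Poisson ratio of 0.49, calcifications 0.333. Default modulus
#' ranges: fibrotic \[390, 1200\] kPa, lipid \[1, 100\] kPa, calcification
#' \[500, 10000\] kPa.
#'
#' @param labels tissue labels of the target mesh.
#' @return data.frame with columns `name`, `label`, `role`, `lower`, `upper`.
#' @export
linear_search_space <- function(labels) {
  labels <- unique(labels)
  rows <- lapply(labels, function(l) {
    rng <- if (l == "fibrotic") c(390, 1200)
           else if (startsWith(l, "lipid")) c(1, 100)
           else c(500, 10000)
    data.frame(name = paste0("E_", l), label = l, role = "E",
               lower = rng[1], upper = rng[2])
  })
  do.call(rbind, rows)
}

#' Search space for the non-linear characterization
#'
#' Three parameters for the fibrotic tissue (GOH `C10` in \[1, 50\] kPa,
#' `k1` in \[5, 1e5\] kPa, `k2` in \[1, 100\]), two per lipid (Neo-Hooke
#' `C10` in \[0.1, 100\] kPa, `D1` in \[0.005, 0.9\] 1/kPa) and one per
#' calcification (`E` in \[500, 10000\] kPa).
#'
#' @param labels tissue labels of the target mesh.
#' @return data.frame with columns `name`, `label`, `role`, `lower`, `upper`.
#' @export
nonlinear_search_space <- function(labels) {
  labels <- unique(labels)
  rows <- list()
  for (l in labels) {
    if (l == "fibrotic") {
      rows[[length(rows) + 1L]] <- data.frame(
        name = c("C10_fibrotic", "k1_fibrotic", "k2_fibrotic"),
        label = l, role = c("C10", "k1", "k2"),
        lower = c(1, 5, 1), upper = c(50, 1e5, 100))
    } else if (startsWith(l, "lipid")) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(c("C10_", "D1_"), l), label = l, role = c("C10", "D1"),
        lower = c(0.1, 0.005), upper = c(100, 0.9))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0("E_", l), label = l, role = "E",
        lower = 500, upper = 10000)
    }
  }
  do.call(rbind, rows)
}

# Materials from a parameter vector over a nonlinear search space.
nonlinear_materials_from_par <- function(par, space) {
  labs <- unique(space$label)
  mats <- lapply(labs, function(l) {
    rows <- space$label == l
    p <- stats::setNames(par[rows], space$role[rows])
    if (l == "fibrotic") goh(mu = p[["C10"]], k1 = p[["k1"]], k2 = p[["k2"]])
    else if (startsWith(l, "lipid")) neo_hooke(C10 = p[["C10"]], D1 = p[["D1"]])
    else linear_elastic(E = p[["E"]], nu = 0.333)
  })
  material_set(.list = stats::setNames(mats, labs))
}

# --- linear pipeline --------------------------------------------------------

#' Linear-elastic characterization from a measured strain field
#'
#' Recovers one effective Young's modulus per tissue by minimizing the NRMSE
#' between the measured radial strains and those of a small linear-elastic
#' pressure increment (default 5 mmHg) applied on the imaged (lower-pressure)
#' configuration. Poisson ratios are fixed (0.49 soft tissues, 0.333
#' calcifications); the initial poll mesh is 1 (1% of each range).
#'
#' The calcification modulus is only weakly identifiable (strains inside a
#' stiff inclusion are tiny); after the search a profile sweep over each
#' calcification range flags tissues whose modulus moves the cost by less
#' than 1% as `weakly_identifiable`.
#'
#' @param measured a `strain_field` (typically noised) on the imaged mesh.
#' @param mesh `labeled_mesh` whose nodes are the imaged (p_lo) coordinates.
#' @param dP pressure increment between the frames, mmHg.
#' @param space search space (default [linear_search_space()]).
#' @param config a [gss_config()] (default: initial mesh 1, 200 evaluations).
#' @param truth optional named vector of true moduli (kPa) per label for
#'   success-rate reporting.
#' @return object of class `inverse_result`.
#' @export
characterize_linear <- function(measured, mesh, dP = 5,
                                space = linear_search_space(mesh$labels),
                                config = gss_config(initial_mesh = 1,
                                                    max_evaluations = 200L),
                                truth = NULL) {
  stopifnot(inherits(measured, "strain_field"), inherits(mesh, "labeled_mesh"))
  labs <- space$label
  nu_by_label <- stats::setNames(
    ifelse(startsWith(labs, "calcification"), 0.333, 0.49), labs)
  unit <- linear_unit_stiffness(mesh, mesh$nodes, nu_by_label)
  f <- lumen_forces(mesh$lumen_edges, mesh$nodes, mmHg_to_kPa(dP), unit$pre$ndof)
  fixed <- default_fixed_dofs(mesh)
  free <- setdiff(seq_len(unit$pre$ndof), fixed)
  center <- lumen_centroid(mesh)

  err_model <- function(E) {
    K <- Reduce(`+`, Map(function(l, e) e * unit$Khat[[l]], labs, E))
    u <- numeric(unit$pre$ndof)
    u[free] <- as.numeric(Matrix::solve(K[free, free, drop = FALSE], f[free]))
    strain_fields(mesh, matrix(u, ncol = 2, byrow = TRUE), center)$err
  }
  cost <- function(E) nrmse_cost(measured$err, err_model(E))

  fit <- gss_minimize(cost, space$lower, space$upper, config)
  E_best <- stats::setNames(fit$par, labs)

  sr <- NULL
  if (!is.null(truth)) {
    common <- intersect(names(truth), labs)
    sr <- vapply(common, function(l) success_rate(truth[[l]], E_best[[l]]), 0)
  }
  weak <- character(0)
  for (l in labs[startsWith(labs, "calcification")]) {
    i <- which(labs == l)
    probe <- seq(space$lower[i], space$upper[i], length.out = 5)
    J <- vapply(probe, function(v) { E <- fit$par; E[i] <- v; cost(E) }, 0)
    if ((max(J) - min(J)) < 0.01 * max(fit$value, 1e-12))
      weak <- c(weak, l)
  }

  structure(list(
    mode = "linear", parameters = E_best, J0 = fit$value,
    history = fit$history, termination = fit$termination,
    n_evaluations = fit$n_evaluations, sr = sr,
    weakly_identifiable = weak, space = space
  ), class = "inverse_result")
}

# --- nonlinear pipeline -----------------------------------------------------

#' Non-linear hyperelastic characterization with embedded Pull-Back
#'
#' Each cost evaluation: (1) one Pull-Back step at fixed `K = 1` on the
#' imaged geometry with the candidate materials, (2) inflation of the ZP
#' candidate to both frame pressures, (3) NRMSE between the measured radial
#' strains and the model's relative strains between the frames. The fibrotic
#' tissue is GOH (`D = 0.005`, `kappa = 0.3333` fixed), lipids Neo-Hookean,
#' calcifications linear elastic. The initial poll mesh of 100 makes the
#' first polls full-range jumps (the cost landscape has local minima). After
#' termination the full Pull-Back with free K is run once with the best
#' materials.
#'
#' Solver failures at poll points (divergence, candidate inversion) count as
#' infinite cost and the search continues.
#'
#' @param measured a `strain_field` on the imaged mesh (radial strains of the
#'   p_lo to p_hi increment).
#' @param mesh `labeled_mesh` whose nodes are the imaged (p_lo) coordinates.
#' @param p_lo,p_hi frame pressures, mmHg.
#' @param space search space (default [nonlinear_search_space()]).
#' @param config a [gss_config()] (default: initial mesh 100, 40
#'   evaluations).
#' @param solver a [solver_config()].
#' @param truth optional [material_set()] of the true materials for
#'   behavior-curve R^2 reporting.
#' @param lambda_max stretch range for the reported behavior curves.
#' @return object of class `inverse_result`, additionally carrying
#'   `materials`, `zp_coordinates`, `K_zp`, `pullback`, and `curve_r2` per
#'   fibrotic tissue when `truth` is given.
#' @export
characterize_nonlinear <- function(measured, mesh, p_lo = 110, p_hi = 115,
                                   space = nonlinear_search_space(mesh$labels),
                                   config = gss_config(initial_mesh = 100,
                                                       max_evaluations = 40L),
                                   solver = solver_config(),
                                   truth = NULL, lambda_max = 1.3) {
  stopifnot(inherits(measured, "strain_field"), inherits(mesh, "labeled_mesh"))
  pre <- fe_precompute(mesh$nodes, mesh$triangles)
  fixed <- default_fixed_dofs(mesh)

  model_err <- function(par) {
    mats <- nonlinear_materials_from_par(par, space)
    groups <- material_groups(mesh, mats)
    # Step 1: pull-back at fixed K = 1
    pb <- nonlinear_solve(pre, groups, mesh, mesh$nodes, mmHg_to_kPa(p_lo),
                          solver, fixed)
    zp <- mesh$nodes - matrix(pb$u, ncol = 2, byrow = TRUE)
    if (min(tri_signed_areas(zp, mesh$triangles)) <= 0) return(NULL)
    # Step 2: inflate the ZP candidate to both frame pressures
    pre_zp <- fe_precompute(zp, mesh$triangles)
    lo <- nonlinear_solve(pre_zp, groups, mesh, zp, mmHg_to_kPa(p_lo),
                          solver, fixed)
    hi <- nonlinear_solve(pre_zp, groups, mesh, zp, mmHg_to_kPa(p_hi),
                          solver, fixed, u0 = lo$u,
                          p_start = mmHg_to_kPa(p_lo))
    u_lo <- matrix(lo$u, ncol = 2, byrow = TRUE)
    rel <- matrix(hi$u, ncol = 2, byrow = TRUE) - u_lo
    coords_lo <- zp + u_lo
    strain_fields(mesh, rel, center = lumen_centroid(mesh, coords_lo),
                  coords = coords_lo)$err
  }
  cost <- function(par) {
    err <- model_err(par)
    if (is.null(err)) return(Inf)
    nrmse_cost(measured$err, err)
  }

  fit <- gss_minimize(cost, space$lower, space$upper, config)
  best_mats <- nonlinear_materials_from_par(fit$par, space)

  # Step 3: full Pull-Back with free recovery factor
  pb <- tryCatch(
    pullback_optimize(mesh, best_mats, p_img = p_lo, config = solver),
    error = function(e) NULL)

  r2 <- NULL
  if (!is.null(truth)) {
    fib_labels <- unique(space$label[space$role %in% c("k1", "k2")])
    r2 <- vapply(fib_labels, function(l) {
      ref <- uniaxial_curve(truth[[l]], lambda_max = lambda_max)
      est <- uniaxial_curve(best_mats[[l]], lambda_max = lambda_max)
      curve_r2(ref, est)
    }, 0)
  }

  structure(list(
    mode = "nonlinear",
    parameters = stats::setNames(fit$par, space$name),
    materials = best_mats, J0 = fit$value,
    history = fit$history, termination = fit$termination,
    n_evaluations = fit$n_evaluations,
    zp_coordinates = if (!is.null(pb)) pb$zp_coordinates else NULL,
    K_zp = if (!is.null(pb)) pb$K_zp else NA_real_,
    pullback = pb, curve_r2 = r2, space = space
  ), class = "inverse_result")
}

#' @export
print.inverse_result <- function(x, ...) {
  cat(sprintf("<inverse_result> %s characterization, J0 = %.2f%% after %d evaluations\n",
              x$mode, x$J0, x$n_evaluations))
  if (x$mode == "linear") {
    print(round(x$parameters, 2))
    if (!is.null(x$sr)) cat("success rate (%):",
                            paste(sprintf("%s %.1f", names(x$sr), x$sr),
                                  collapse = ", "), "\n")
    if (length(x$weakly_identifiable))
      cat("weakly identifiable:", paste(x$weakly_identifiable, collapse = ", "), "\n")
  } else {
    print(round(x$parameters, 4))
    if (!is.na(x$K_zp)) cat(sprintf("K_zp = %.3f\n", x$K_zp))
    if (!is.null(x$curve_r2))
      cat("behavior-curve R^2:",
          paste(sprintf("%s %.3f", names(x$curve_r2), x$curve_r2),
                collapse = ", "), "\n")
  }
  invisible(x)
}
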