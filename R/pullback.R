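# Pull-Back recovery of the zero-pressure (ZP) configuration. Clinical images
# are acquired under pressure; hyperelastic analysis needs the unloaded state.
# The algorithm inflates the imaged (pressurized) geometry by the imaging
# pressure, collects the nodal displacements u, and takes X_zp = X - K * u
# for a scalar recovery factor K. Imposing -K u as a displacement boundary
# condition on a copy of the geometry yields exactly this coordinate update,
# so the direct update is used. K = 1 is the fixed default inside the inverse
# loop; the full scalar optimization of K runs once after the materials have
# converged.

#' One Pull-Back step at a fixed recovery factor
#'
#' @param pressurized_mesh `labeled_mesh` whose nodes are the imaged
#'   (pressurized) coordinates.
#' @param materials a [material_set()].
#' @param p_img imaging pressure, mmHg.
#' @param K recovery factor (dimensionless); `K = 0` returns the input
#'   coordinates unchanged.
#' @param config a [solver_config()].
#' @param displacement optionally, a precomputed N x 2 inflation displacement
#'   of the pressurized geometry at `p_img` (avoids re-solving when scanning
#'   over `K`).
#' @return list with `coords` (N x 2 ZP candidate) and `displacement`.
#'   Candidate meshes with inverted elements raise a `pullback_inversion`
#'   error carrying the offending element ids.
#' @export
pullback_step <- function(pressurized_mesh, materials, p_img, K = 1,
                          config = solver_config(), displacement = NULL) {
  stopifnot(inherits(pressurized_mesh, "labeled_mesh"))
  if (is.null(displacement)) {
    sol <- inflate(pressurized_mesh, materials, p_img, config)
    displacement <- sol$displacements
  }
  zp <- pressurized_mesh$nodes - K * displacement
  ar <- tri_signed_areas(zp, pressurized_mesh$triangles)
  if (min(ar) <= 0) {
    bad <- which(ar <= 0)
    cond <- structure(
      class = c("pullback_inversion", "atheroIFEM_error", "error", "condition"),
      list(message = sprintf("ZP candidate has %d inverted element(s) at K = %.3f",
                             length(bad), K),
           call = sys.call(-1), elements = bad))
    stop(cond)
  }
  list(coords = zp, displacement = displacement)
}

#' Re-pressurization error of a ZP candidate
#'
#' Root-mean-square nodal distance between the candidate geometry inflated to
#' the imaging pressure and the target (imaged) coordinates.
#'
#' @param zp_coords N x 2 candidate zero-pressure coordinates.
#' @param mesh `labeled_mesh` providing topology, labels and lumen edges.
#' @param materials a [material_set()].
#' @param p_img imaging pressure, mmHg.
#' @param target_coords N x 2 imaged coordinates.
#' @param config a [solver_config()].
#' @return rms distance, mm.
#' @export
repressurize_error <- function(zp_coords, mesh, materials, p_img,
                               target_coords, config = solver_config()) {
  sol <- inflate(mesh, materials, p_img, config, coords = zp_coords)
  xy <- zp_coords + sol$displacements
  sqrt(mean(rowSums((xy - target_coords)^2)))
}

#' Optimize the Pull-Back recovery factor
#'
#' Golden-section search of the scalar recovery factor K minimizing the
#' re-pressurization error. One inflation of the pressurized geometry
#' provides the pull-back displacement family `X - K u`; each K evaluation
#' costs one forward inflation. Candidates producing inverted elements are
#' treated as infinitely bad.
#'
#' @param pressurized_mesh `labeled_mesh` at the imaged configuration.
#' @param materials a [material_set()].
#' @param p_img imaging pressure, mmHg.
#' @param K_bounds search interval for K, inside `[0, 2]`.
#' @param tol absolute tolerance on K.
#' @param rms_plateau stop when the bracket's rms improvement falls below
#'   this value, mm.
#' @param config a [solver_config()].
#' @return object of class `pullback_result`: `zp_coordinates`, `K_zp`,
#'   `residual_rms` (mm), `iterations`, `converged`, `history`.
#' @export
pullback_optimize <- function(pressurized_mesh, materials, p_img = 110,
                              K_bounds = c(0.5, 1.5), tol = 1e-3,
                              rms_plateau = 1e-4, config = solver_config()) {
  stopifnot(length(K_bounds) == 2, K_bounds[1] < K_bounds[2],
            K_bounds[1] >= 0, K_bounds[2] <= 2)
  base <- inflate(pressurized_mesh, materials, p_img, config)
  u <- base$displacements
  target <- pressurized_mesh$nodes
  history <- list()
  eval_K <- function(K) {
    rms <- tryCatch({
      cand <- pullback_step(pressurized_mesh, materials, p_img, K, config,
                            displacement = u)
      repressurize_error(cand$coords, pressurized_mesh, materials, p_img,
                         target, config)
    }, error = function(e) Inf)
    history[[length(history) + 1L]] <<- c(K = K, rms = rms)
    rms
  }

  gr <- (sqrt(5) - 1) / 2
  a <- K_bounds[1]; b <- K_bounds[2]
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- eval_K(x1); f2 <- eval_K(x2)
  it <- 2L
  while ((b - a) > tol && abs(f1 - f2) > rms_plateau) {
    if (f1 <= f2) { b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- eval_K(x1)
    } else { a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- eval_K(x2)
    }
    it <- it + 1L
  }
  hist_mat <- do.call(rbind, history)
  if (!any(is.finite(hist_mat[, "rms"])))
    stopf("all candidate recovery factors produced inverted meshes",
          class = "pullback_failure")
  best <- which.min(hist_mat[, "rms"])
  K_best <- hist_mat[best, "K"]
  zp <- pullback_step(pressurized_mesh, materials, p_img, K_best, config,
                      displacement = u)$coords
  structure(list(
    zp_coordinates = zp, K_zp = unname(K_best),
    residual_rms = unname(hist_mat[best, "rms"]),
    iterations = it, converged = (b - a) <= tol || abs(f1 - f2) <= rms_plateau,
    history = hist_mat
  ), class = "pullback_result")
}

#' @export
print.pullback_result <- function(x, ...) {
  cat(sprintf("<pullback_result> K_zp = %.4f, rms = %.4e mm, %d evaluations\n",
              x$K_zp, x$residual_rms, x$iterations))
  invisible(x)
}
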