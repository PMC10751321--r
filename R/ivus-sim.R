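# Two-pressure-frame IVUS measurement simulation: nodal coordinates at the
# lower pressure, relative displacements to the upper pressure, infinitesimal
# strains of the increment, and additive Gaussian noise at a target SNR.
# Frames share the mesh connectivity (ground-truth correspondence); speckle
# tracking itself is out of scope.

#' Simulate a two-pressure IVUS frame pair
#'
#' Inflates the zero-pressure mesh to `p_lo` and `p_hi` with a shared solver
#' configuration (the `p_hi` state is continued from the `p_lo` state) and
#' records the measurement an IVUS displacement estimator would deliver: the
#' nodal coordinates of the lower-pressure frame and the relative nodal
#' displacements between frames. With purely linear-elastic materials the
#' states follow by superposition of a single unit solve, making the relative
#' displacement independent of the pressure level exactly.
#'
#' @param zp_mesh `labeled_mesh` in the unpressurized configuration (the
#'   reference for nonlinear materials).
#' @param materials a [material_set()].
#' @param p_lo,p_hi frame pressures, mmHg (`p_lo < p_hi`).
#' @param config a [solver_config()].
#' @return object of class `frame_pair`: `coords` (N x 2 at `p_lo`),
#'   `rel_disp` (N x 2, `u(p_hi) - u(p_lo)`), `p_lo`, `p_hi`, `mesh`.
#' @export
simulate_frame_pair <- function(zp_mesh, materials, p_lo = 110, p_hi = 115,
                                config = solver_config()) {
  stopifnot(inherits(zp_mesh, "labeled_mesh"))
  if (!(p_hi > p_lo)) stopf("p_hi must exceed p_lo")
  all_linear <- all(vapply(materials, inherits, TRUE, "linear_elastic"))
  if (all_linear) {
    u1 <- inflate_linear_increment(zp_mesh, materials, 1)
    u_lo <- u1 * p_lo; u_hi <- u1 * p_hi
  } else {
    pre <- fe_precompute(zp_mesh$nodes, zp_mesh$triangles)
    groups <- material_groups(zp_mesh, materials)
    fixed <- default_fixed_dofs(zp_mesh)
    lo <- nonlinear_solve(pre, groups, zp_mesh, zp_mesh$nodes,
                          mmHg_to_kPa(p_lo), config, fixed)
    hi <- nonlinear_solve(pre, groups, zp_mesh, zp_mesh$nodes,
                          mmHg_to_kPa(p_hi), config, fixed, u0 = lo$u,
                          p_start = mmHg_to_kPa(p_lo))
    u_lo <- matrix(lo$u, ncol = 2, byrow = TRUE)
    u_hi <- matrix(hi$u, ncol = 2, byrow = TRUE)
  }
  structure(list(coords = zp_mesh$nodes + u_lo, rel_disp = u_hi - u_lo,
                 p_lo = p_lo, p_hi = p_hi, mesh = zp_mesh),
            class = "frame_pair")
}

#' @export
print.frame_pair <- function(x, ...) {
  cat(sprintf("<frame_pair> %g -> %g mmHg, max |du| = %.4f mm\n",
              x$p_lo, x$p_hi, max(sqrt(rowSums(x$rel_disp^2)))))
  invisible(x)
}

#' Infinitesimal strains of a frame pair
#'
#' Strains of the relative displacement field on the lower-pressure
#' configuration, with the cylindrical origin at the lumen centroid of that
#' frame (the radial direction IVUS elastography measures).
#'
#' @param pair a [simulate_frame_pair()] result.
#' @return a `strain_field`.
#' @export
frame_strains <- function(pair) {
  stopifnot(inherits(pair, "frame_pair"))
  strain_fields(pair$mesh, pair$rel_disp,
                center = lumen_centroid(pair$mesh, pair$coords),
                coords = pair$coords)
}

#' Add measurement noise to a strain field at a target SNR
#'
#' Adds independent zero-mean Gaussian noise to each Cartesian strain
#' component, with per-component variance `mean(signal^2) / 10^(snr_db/10)`,
#' then recomputes the cylindrical, principal and equivalent components from
#' the noised tensor so all rotation identities still hold. `snr_db = Inf`
#' disables the noise.
#'
#' @param field a `strain_field`.
#' @param snr_db target signal-to-noise ratio, dB.
#' @param seed integer seed (noise realization).
#' @return a `strain_field`.
#' @export
add_noise <- function(field, snr_db = 20, seed = 1L) {
  stopifnot(inherits(field, "strain_field"), is.finite(snr_db) || snr_db == Inf)
  if (identical(snr_db, Inf)) return(field)
  n <- length(field$exx)
  pw <- c(mean(field$exx^2), mean(field$eyy^2), mean(field$exy^2))
  if (sum(pw) <= 0) stopf("zero signal power: SNR undefined")
  fac <- 10^(snr_db / 10)
  noise <- with_seed(seed, matrix(stats::rnorm(3 * n), n, 3))
  strain_field_from_cartesian(
    field$exx + noise[, 1] * sqrt(pw[1] / fac),
    field$eyy + noise[, 2] * sqrt(pw[2] / fac),
    field$exy + noise[, 3] * sqrt(pw[3] / fac),
    field$centroids, field$center, field$labels)
}

#' Measure the SNR between a clean and a noisy strain field
#'
#' `10 log10(sum(clean^2) / sum((noisy - clean)^2))` over the Cartesian
#' components jointly; identical fields return `Inf`.
#'
#' @param clean,noisy `strain_field`s of equal shape.
#' @return SNR in dB.
#' @export
measure_snr <- function(clean, noisy) {
  stopifnot(length(clean$exx) == length(noisy$exx))
  sig <- sum(clean$exx^2 + clean$eyy^2 + clean$exy^2)
  err <- sum((noisy$exx - clean$exx)^2 + (noisy$eyy - clean$eyy)^2 +
               (noisy$exy - clean$exy)^2)
  if (err == 0) return(Inf)
  10 * log10(sig / err)
}
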