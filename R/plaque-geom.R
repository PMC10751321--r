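# Parametric synthetic plaque cross-sections. Real IVUS-segmented plaque
# contours are replaced by a seedable surrogate: an eccentric-lumen fibrotic
# annulus with elliptical lipid pools and calcifications, plus optional smooth
# low-order Fourier perturbation of the outer and lumen contours.

#' Specify a synthetic plaque cross-section
#'
#' Describes the surrogate geometry in mm: a roughly circular outer wall, an
#' eccentric lumen, and elliptical tissue inclusions (soft lipid pools, stiff
#' calcifications) embedded in the fibrotic annulus. The fibrous cap (minimum
#' lumen-to-lipid distance) is the key vulnerability dimension and is enforced
#' at generation time, never silently clipped.
#'
#' @param outer_radius outer wall radius, mm.
#' @param lumen_radius lumen radius, mm.
#' @param lumen_offset 2-vector, lumen center relative to the outer center, mm.
#' @param inclusions list of inclusions, each a list with fields
#'   `kind` ("lipid" or "calcification"), `center` (2-vector, mm),
#'   `semi_axes` (2-vector, mm) and `rotation` (rad).
#' @param min_cap_thickness minimum admissible lumen-to-lipid distance, mm.
#' @param contour_noise_amplitude peak radial perturbation of the outer and
#'   lumen contours, mm (0 disables).
#' @param contour_spacing target vertex spacing of the generated contour
#'   polygons, mm; defaults to `min_cap_thickness / 3` so contours are
#'   resolved at the finest admissible mesh size.
#' @param seed integer seed controlling the contour perturbation.
#' @return an object of class `plaque_spec`.
#' @export
plaque_spec <- function(outer_radius = 2,
                        lumen_radius = 0.9,
                        lumen_offset = c(0.4, 0),
                        inclusions = list(
                          list(kind = "lipid", center = c(-1.25, 0.1),
                               semi_axes = c(0.35, 0.22), rotation = 0.3),
                          list(kind = "calcification", center = c(0.7, 1.25),
                               semi_axes = c(0.22, 0.14), rotation = -0.5)
                        ),
                        min_cap_thickness = 0.35,
                        contour_noise_amplitude = 0.03,
                        contour_spacing = NULL,
                        seed = 1L) {
  stopifnot(outer_radius > 0, lumen_radius > 0, min_cap_thickness > 0,
            length(lumen_offset) == 2)
  if (outer_radius <= lumen_radius + sqrt(sum(lumen_offset^2)))
    stopf("outer_radius must exceed lumen_radius + |lumen_offset|")
  for (inc in inclusions) {
    stopifnot(inc$kind %in% c("lipid", "calcification"),
              length(inc$center) == 2, all(inc$semi_axes > 0))
  }
  structure(list(
    outer_radius = outer_radius, lumen_radius = lumen_radius,
    lumen_offset = lumen_offset, inclusions = inclusions,
    min_cap_thickness = min_cap_thickness,
    contour_noise_amplitude = contour_noise_amplitude,
    contour_spacing = contour_spacing %||% (min_cap_thickness / 3),
    seed = as.integer(seed)
  ), class = "plaque_spec")
}

# Smooth low-order Fourier radial perturbation, peak-normalized to `amp`.
fourier_perturbation <- function(theta, amp, modes = 2:5) {
  if (amp <= 0) return(rep(0, length(theta)))
  a <- stats::runif(length(modes), -1, 1)
  phi <- stats::runif(length(modes), 0, 2 * pi)
  d <- rowSums(sapply(seq_along(modes), function(k) {
    a[k] * cos(modes[k] * theta + phi[k])
  }))
  if (max(abs(d)) < 1e-12) return(rep(0, length(theta)))
  amp * d / max(abs(d))
}

#' Generate a plaque geometry from a specification
#'
#' Produces closed contour polygons for the outer wall, the lumen, and every
#' inclusion, recentred so the origin sits at the outer-contour centroid.
#' All geometric invariants (simple contours, containment, disjoint
#' inclusions, fibrous-cap clearance) are verified; an infeasible
#' specification raises a placement failure rather than being clipped.
#'
#' @param spec a [plaque_spec()].
#' @return an object of class `plaque_geometry` with fields `outer`, `lumen`
#'   (n x 2 polygons) and `inclusions` (list of `list(kind, poly)`).
#' @export
generate_plaque <- function(spec) {
  stopifnot(inherits(spec, "plaque_spec"))
  h <- spec$contour_spacing
  geom <- with_seed(spec$seed, {
    n_out <- max(48L, ceiling(2 * pi * spec$outer_radius / h))
    th_o <- seq(0, 2 * pi, length.out = n_out + 1)[-(n_out + 1)]
    r_o <- spec$outer_radius + fourier_perturbation(th_o, spec$contour_noise_amplitude)
    outer <- cbind(r_o * cos(th_o), r_o * sin(th_o))

    n_lum <- max(40L, ceiling(2 * pi * spec$lumen_radius / h))
    th_l <- seq(0, 2 * pi, length.out = n_lum + 1)[-(n_lum + 1)]
    r_l <- spec$lumen_radius + fourier_perturbation(th_l, spec$contour_noise_amplitude)
    lumen <- cbind(spec$lumen_offset[1] + r_l * cos(th_l),
                   spec$lumen_offset[2] + r_l * sin(th_l))

    incs <- lapply(spec$inclusions, function(inc) {
      list(kind = inc$kind,
           poly = ellipse_polygon(inc$center, inc$semi_axes, inc$rotation, h))
    })
    list(outer = outer, lumen = lumen, inclusions = incs)
  })

  ctr <- polygon_centroid(geom$outer)
  shift <- function(p) sweep(p, 2, ctr)
  geom$outer <- shift(geom$outer)
  geom$lumen <- shift(geom$lumen)
  geom$inclusions <- lapply(geom$inclusions, function(i) {
    i$poly <- shift(i$poly); i
  })

  out <- structure(geom, class = "plaque_geometry",
                   min_cap_thickness = spec$min_cap_thickness)
  validate_plaque_geometry(out, spec$min_cap_thickness)
  out
}

#' Validate the invariants of a plaque geometry
#'
#' Checks that all contours are simple polygons, the lumen lies strictly in
#' the outer contour, every inclusion lies in the wall ring, inclusions are
#' pairwise disjoint, and every lipid clears the lumen by at least the
#' fibrous-cap thickness.
#'
#' @param geom a `plaque_geometry`.
#' @param min_cap_thickness fibrous-cap bound, mm; defaults to the value the
#'   geometry was generated with.
#' @return invisibly `TRUE`; raises a `plaque_placement_error` otherwise.
#' @export
validate_plaque_geometry <- function(geom,
                                     min_cap_thickness = attr(geom, "min_cap_thickness")) {
  fail <- function(...) stopf(..., class = "plaque_placement_error")
  if (!polygon_is_simple(geom$outer)) fail("outer contour self-intersects")
  if (!polygon_is_simple(geom$lumen)) fail("lumen contour self-intersects")
  if (!polygon_inside(geom$lumen, geom$outer))
    fail("lumen is not strictly inside the outer contour")
  n_inc <- length(geom$inclusions)
  for (i in seq_len(n_inc)) {
    inc <- geom$inclusions[[i]]
    if (!polygon_is_simple(inc$poly))
      fail("inclusion %d contour self-intersects", i)
    if (!polygon_inside(inc$poly, geom$outer))
      fail("inclusion %d (%s) extends outside the wall", i, inc$kind)
    if (any(point_in_polygon(inc$poly, geom$lumen)) ||
        polygons_cross(inc$poly, geom$lumen))
      fail("inclusion %d (%s) intersects the lumen", i, inc$kind)
    if (inc$kind == "lipid" && !is.null(min_cap_thickness)) {
      cap <- polygon_distance(inc$poly, geom$lumen)
      if (cap < min_cap_thickness - 1e-9)
        fail("fibrous cap of lipid %d is %.4f mm, below the %.4f mm minimum",
             i, cap, min_cap_thickness)
    }
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        other <- geom$inclusions[[j]]$poly
        if (any(point_in_polygon(inc$poly, other)) ||
            polygons_cross(inc$poly, other))
          fail("inclusions %d and %d overlap", j, i)
      }
    }
  }
  invisible(TRUE)
}

#' Geometric vulnerability markers of a plaque
#'
#' Computes the fibrous cap thickness (minimum lumen-to-lipid boundary
#' distance), the total lipid pool area, and the degree of stenosis
#' `1 - lumen_area / outer_area`. With no lipid present the cap thickness is
#' reported as `NA` (undefined), never 0.
#'
#' @param geom a `plaque_geometry`.
#' @return list with `cap_thickness` (mm or `NA`), `lipid_area` (mm^2) and
#'   `stenosis_fraction`.
#' @export
geometry_metrics <- function(geom) {
  lipids <- Filter(function(i) i$kind == "lipid", geom$inclusions)
  cap <- if (length(lipids) == 0) NA_real_ else
    min(vapply(lipids, function(i) polygon_distance(i$poly, geom$lumen), 0))
  list(
    cap_thickness = cap,
    lipid_area = sum(vapply(lipids, function(i) abs(polygon_area(i$poly)), 0)),
    stenosis_fraction = 1 - abs(polygon_area(geom$lumen)) / abs(polygon_area(geom$outer))
  )
}

#' @export
print.plaque_geometry <- function(x, ...) {
  m <- geometry_metrics(x)
  cat(sprintf(
    "<plaque_geometry> outer area %.2f mm^2, stenosis %.1f%%, %d inclusion(s)\n",
    abs(polygon_area(x$outer)), 100 * m$stenosis_fraction, length(x$inclusions)))
  if (!is.na(m$cap_thickness))
    cat(sprintf("  fibrous cap %.3f mm, lipid area %.3f mm^2\n",
                m$cap_thickness, m$lipid_area))
  invisible(x)
}
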