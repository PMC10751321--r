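# Conforming labeled triangle meshes. The triangulator is an incremental
# Bowyer-Watson Delaunay kernel (vectorized cavity search) with boundary-edge
# recovery by midpoint insertion; material interfaces always coincide with
# element edges, so no element straddles two tissues.

#' Delaunay triangulation of a planar point set
#'
#' Incremental Bowyer-Watson construction. Intended for the well-spaced point
#' sets produced by the mesher (boundary-resampled contours plus a hexagonal
#' interior lattice); it is not a guaranteed-robust kernel for adversarially
#' degenerate input.
#'
#' @param pts n x 2 matrix of points (n >= 3).
#' @return m x 3 matrix of vertex indices, counter-clockwise.
#' @export
delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stopf("need at least 3 points")
  ctr <- colMeans(pts)
  scale <- max(max(abs(sweep(pts, 2, ctr))), 1e-9) * 64
  sup <- rbind(ctr + c(-3 * scale, -scale), ctr + c(3 * scale, -scale),
               ctr + c(0, 3 * scale))
  P <- rbind(pts, sup)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  cap <- max(4L * n + 16L, 64L)
  T1 <- integer(cap); T2 <- integer(cap); T3 <- integer(cap)
  CX <- numeric(cap); CY <- numeric(cap); R2 <- numeric(cap)
  alive <- logical(cap)
  ntri <- 0L

  circum <- function(a, b, c) {
    ax <- P[a, 1]; ay <- P[a, 2]; bx <- P[b, 1]; by <- P[b, 2]
    cx <- P[c, 1]; cy <- P[c, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    cbind(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }

  push <- function(a, b, c) {
    k <- length(a)
    if (ntri + k > cap) {
      newcap <- max(cap * 2L, ntri + k)
      length(T1) <<- newcap; length(T2) <<- newcap; length(T3) <<- newcap
      length(CX) <<- newcap; length(CY) <<- newcap; length(R2) <<- newcap
      al <- logical(newcap); al[seq_len(cap)] <- alive; alive <<- al
      cap <<- newcap
    }
    idx <- ntri + seq_len(k)
    cc <- circum(a, b, c)
    T1[idx] <<- a; T2[idx] <<- b; T3[idx] <<- c
    CX[idx] <<- cc[, 1]; CY[idx] <<- cc[, 2]; R2[idx] <<- cc[, 3]
    alive[idx] <<- TRUE
    ntri <<- ntri + k
  }

  push(s1, s2, s3)

  for (p in seq_len(n)) {
    px <- P[p, 1]; py <- P[p, 2]
    live <- which(alive[seq_len(ntri)])
    bad <- live[(px - CX[live])^2 + (py - CY[live])^2 <= R2[live] * (1 + 1e-12)]
    if (length(bad) == 0) {  # numerically marooned point: nearest circumcircle
      bad <- live[which.min((px - CX[live])^2 + (py - CY[live])^2 - R2[live])]
    }
    ea <- c(T1[bad], T2[bad], T3[bad])
    eb <- c(T2[bad], T3[bad], T1[bad])
    key <- paste(pmin(ea, eb), pmax(ea, eb))
    keep <- !(key %in% key[duplicated(key)])
    alive[bad] <- FALSE
    push(ea[keep], eb[keep], rep.int(p, sum(keep)))
  }

  live <- which(alive[seq_len(ntri)])
  tri <- cbind(T1[live], T2[live], T3[live])
  tri[tri[, 1] <= n & tri[, 2] <= n & tri[, 3] <= n, , drop = FALSE]
}

tri_signed_areas <- function(nodes, tri) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

tri_centroids <- function(nodes, tri) {
  cbind((nodes[tri[, 1], 1] + nodes[tri[, 2], 1] + nodes[tri[, 3], 1]) / 3,
        (nodes[tri[, 1], 2] + nodes[tri[, 2], 2] + nodes[tri[, 3], 2]) / 3)
}

# Undirected edge keys "lo hi" for all element edges (3 per triangle).
mesh_edge_keys <- function(tri) {
  ea <- c(tri[, 1], tri[, 2], tri[, 3])
  eb <- c(tri[, 2], tri[, 3], tri[, 1])
  paste(pmin(ea, eb), pmax(ea, eb))
}

labeled_mesh <- function(nodes, triangles, labels, lumen_edges, outer_nodes,
                         fixed_nodes, lumen_nodes = integer(0)) {
  dimnames(nodes) <- NULL; dimnames(triangles) <- NULL
  dimnames(lumen_edges) <- NULL
  structure(list(
    nodes = nodes, triangles = triangles, labels = labels,
    lumen_edges = lumen_edges, outer_nodes = outer_nodes,
    fixed_nodes = fixed_nodes, lumen_nodes = lumen_nodes
  ), class = "labeled_mesh")
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat(sprintf("<labeled_mesh> %d nodes, %d triangles\n",
              nrow(x$nodes), nrow(x$triangles)))
  print(table(x$labels))
  invisible(x)
}

#' Mesh a plaque geometry with labeled linear triangles
#'
#' Resamples every contour at the target edge length (subdividing polygon
#' edges, so contour geometry is preserved exactly), fills the domain with a
#' hexagonal interior lattice, triangulates, recovers any missing contour edge
#' by midpoint insertion, classifies elements by centroid, and smooths
#' interior vertices. Tissue interfaces therefore coincide with element edges
#' and every element carries exactly one tissue label (`fibrotic`, `lipid_i`,
#' `calcification_i`).
#'
#' Rigid-body motion is controlled as in IVUS plaque models: the three outer
#' contour nodes closest to 0, 120 and 240 degrees from the section centroid
#' are pinned in both components.
#'
#' @param geom a `plaque_geometry`.
#' @param target_edge_length mm; must not exceed a third of the fibrous-cap
#'   thickness so at least three element layers span every cap.
#' @param smooth_iters Laplacian smoothing sweeps for interior vertices.
#' @return a `labeled_mesh`.
#' @export
mesh_plaque <- function(geom, target_edge_length, smooth_iters = 3L) {
  stopifnot(inherits(geom, "plaque_geometry"), target_edge_length > 0)
  h <- target_edge_length
  cap0 <- attr(geom, "min_cap_thickness")
  if (!is.null(cap0) && length(Filter(function(i) i$kind == "lipid", geom$inclusions)) &&
      h > cap0 / 3 + 1e-12)
    stopf("target_edge_length %.4f exceeds min_cap_thickness/3 = %.4f", h, cap0 / 3)

  contours <- c(list(geom$outer, geom$lumen),
                lapply(geom$inclusions, `[[`, "poly"))
  contours <- lapply(contours, polygon_subdivide, h = h)

  build <- function(contours) {
    bnodes <- do.call(rbind, contours)
    csize <- vapply(contours, nrow, 0L)
    coff <- cumsum(c(0L, csize[-length(csize)]))

    # hexagonal interior lattice, kept clear of all contours
    bb <- apply(geom$outer, 2, range)
    dx <- h; dy <- h * sqrt(3) / 2
    ys <- seq(bb[1, 2] - dy, bb[2, 2] + dy, by = dy)
    grid <- do.call(rbind, lapply(seq_along(ys), function(i) {
      xs <- seq(bb[1, 1] - dx, bb[2, 1] + dx, by = dx) +
        (i %% 2) * dx / 2
      cbind(xs, ys[i])
    }))
    keep <- point_in_polygon(grid, geom$outer) &
      !point_in_polygon(grid, geom$lumen)
    grid <- grid[keep, , drop = FALSE]
    allseg <- list(a = do.call(rbind, lapply(contours, function(p) poly_segments(p)$a)),
                   b = do.call(rbind, lapply(contours, function(p) poly_segments(p)$b)))
    grid <- grid[points_segments_dist(grid, allseg) > 0.55 * h, , drop = FALSE]

    pts <- rbind(bnodes, grid)
    tri <- delaunay_triangulate(pts)
    list(pts = pts, tri = tri, csize = csize, coff = coff, nb = nrow(bnodes))
  }

  # boundary-edge recovery loop: subdivide any contour edge missing from the
  # triangulation and retriangulate (terminates quickly for sane inputs)
  for (attempt in 1:6) {
    m <- build(contours)
    keys <- unique(mesh_edge_keys(m$tri))
    missing <- FALSE
    for (ci in seq_along(contours)) {
      nc <- m$csize[ci]
      ids <- m$coff[ci] + seq_len(nc)
      nxt <- c(ids[-1], ids[1])
      want <- paste(pmin(ids, nxt), pmax(ids, nxt))
      miss <- which(!(want %in% keys))
      if (length(miss)) {
        missing <- TRUE
        poly <- contours[[ci]]
        nn <- nrow(poly)
        nxtv <- c(seq_len(nn)[-1], 1)
        mids <- (poly[miss, , drop = FALSE] + poly[nxtv[miss], , drop = FALSE]) / 2
        newpoly <- vector("list", nn)
        for (i in seq_len(nn)) {
          newpoly[[i]] <- poly[i, , drop = FALSE]
          if (i %in% miss)
            newpoly[[i]] <- rbind(newpoly[[i]], mids[match(i, miss), ])
        }
        contours[[ci]] <- do.call(rbind, newpoly)
      }
    }
    if (!missing) break
    if (attempt == 6) stopf("boundary edge recovery failed", class = "mesh_error")
  }

  pts <- m$pts; tri <- m$tri
  # orient CCW before classification
  ar <- tri_signed_areas(pts, tri)
  tri[ar < 0, c(2, 3)] <- tri[ar < 0, c(3, 2)]

  cent <- tri_centroids(pts, tri)
  inside <- point_in_polygon(cent, geom$outer) & !point_in_polygon(cent, geom$lumen)
  tri <- tri[inside, , drop = FALSE]
  cent <- cent[inside, , drop = FALSE]

  labels <- rep("fibrotic", nrow(tri))
  kind_count <- c(lipid = 0L, calcification = 0L)
  for (inc in geom$inclusions) {
    kind_count[inc$kind] <- kind_count[inc$kind] + 1L
    lab <- paste0(inc$kind, "_", kind_count[inc$kind])
    labels[point_in_polygon(cent, inc$poly)] <- lab
  }

  # drop unused points, remap indices
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(pts)); remap[used] <- seq_along(used)
  nodes <- pts[used, , drop = FALSE]
  tri <- matrix(remap[tri], ncol = 3)
  nb <- m$nb
  is_boundary_node <- used <= nb    # contour nodes are listed first
  lumen_ids <- which(used > m$coff[2] & used <= m$coff[2] + m$csize[2])
  outer_ids <- which(used <= m$csize[1])

  # Laplacian smoothing of interior vertices (contour vertices fixed)
  if (smooth_iters > 0) {
    adj_i <- c(tri[, 1], tri[, 2], tri[, 3], tri[, 2], tri[, 3], tri[, 1])
    adj_j <- c(tri[, 2], tri[, 3], tri[, 1], tri[, 1], tri[, 2], tri[, 3])
    interior <- !is_boundary_node
    for (it in seq_len(smooth_iters)) {
      sx <- tapply(nodes[adj_j, 1], adj_i, mean)
      sy <- tapply(nodes[adj_j, 2], adj_i, mean)
      cand <- nodes
      ids <- as.integer(names(sx))
      sel <- interior[ids]
      cand[ids[sel], 1] <- sx[sel]
      cand[ids[sel], 2] <- sy[sel]
      if (min(tri_signed_areas(cand, tri)) > 1e-12) nodes <- cand else break
    }
  }

  ar <- tri_signed_areas(nodes, tri)
  if (min(ar) <= 0) stopf("mesher produced inverted elements", class = "mesh_error")

  # boundary edges (appearing in exactly one triangle), oriented as in their
  # triangle so that rot90(b - a) is the inward surface traction direction
  ea <- c(tri[, 1], tri[, 2], tri[, 3])
  eb <- c(tri[, 2], tri[, 3], tri[, 1])
  key <- paste(pmin(ea, eb), pmax(ea, eb))
  single <- !(key %in% key[duplicated(key)])
  is_lumen_node <- logical(nrow(nodes)); is_lumen_node[lumen_ids] <- TRUE
  lum_e <- single & is_lumen_node[ea] & is_lumen_node[eb]
  lumen_edges <- cbind(ea[lum_e], eb[lum_e])

  octr <- polygon_centroid(geom$outer)
  ang <- atan2(nodes[outer_ids, 2] - octr[2], nodes[outer_ids, 1] - octr[1])
  fixed <- vapply(c(0, 2 * pi / 3, -2 * pi / 3), function(a) {
    d <- abs(((ang - a + pi) %% (2 * pi)) - pi)
    outer_ids[which.min(d)]
  }, 0L)

  mesh <- labeled_mesh(nodes, tri, labels, lumen_edges,
                       outer_nodes = outer_ids, fixed_nodes = fixed,
                       lumen_nodes = lumen_ids)
  audit_mesh(mesh, geom)
  if (any(startsWith(labels, "lipid"))) {
    layers <- cap_element_layers(mesh)
    if (is.finite(layers) && layers < 3)
      stopf("only %d element layer(s) across the fibrous cap (need >= 3)",
            layers, class = "mesh_error")
  }
  mesh
}

#' Audit the structural invariants of a labeled mesh
#'
#' Verifies positive element orientation, conformity (each edge shared by at
#' most two elements, boundary edges lying on the geometry contours), full
#' label coverage, and agreement of element labels with a point-in-polygon
#' classification of centroids against the generating geometry.
#'
#' @param mesh a `labeled_mesh`.
#' @param geom optionally, the generating `plaque_geometry` for label and
#'   boundary checks.
#' @return invisibly `TRUE`; errors on any violation.
#' @export
audit_mesh <- function(mesh, geom = NULL) {
  tri <- mesh$triangles
  if (min(tri_signed_areas(mesh$nodes, tri)) <= 0)
    stopf("non-positive element area", class = "mesh_audit_error")
  if (length(mesh$labels) != nrow(tri) || anyNA(mesh$labels))
    stopf("label coverage violated", class = "mesh_audit_error")
  key <- mesh_edge_keys(tri)
  cnt <- table(key)
  if (any(cnt > 2))
    stopf("non-conforming mesh: edge shared by >2 elements", class = "mesh_audit_error")
  if (length(mesh$fixed_nodes) != 3)
    stopf("exactly 3 fixed nodes required", class = "mesh_audit_error")
  if (!all(mesh$fixed_nodes %in% mesh$outer_nodes))
    stopf("fixed nodes must lie on the outer contour", class = "mesh_audit_error")
  if (!is.null(geom)) {
    cent <- tri_centroids(mesh$nodes, tri)
    expected <- rep("fibrotic", nrow(tri))
    kc <- c(lipid = 0L, calcification = 0L)
    for (inc in geom$inclusions) {
      kc[inc$kind] <- kc[inc$kind] + 1L
      expected[point_in_polygon(cent, inc$poly)] <- paste0(inc$kind, "_", kc[inc$kind])
    }
    if (!all(expected == mesh$labels))
      stopf("element labels disagree with centroid point-in-polygon classification",
            class = "mesh_audit_error")
  }
  invisible(TRUE)
}

#' Count element layers across the fibrous cap
#'
#' Breadth-first search over the fibrotic element adjacency graph from
#' lumen-touching elements to lipid-interface elements; the returned count is
#' the minimum number of fibrotic elements crossed, i.e. the cap thickness in
#' element layers.
#'
#' @param mesh a `labeled_mesh` containing at least one lipid element.
#' @return integer layer count (`Inf` if no lipid).
#' @export
cap_element_layers <- function(mesh) {
  tri <- mesh$triangles
  lip <- startsWith(mesh$labels, "lipid")
  if (!any(lip)) return(Inf)
  fib <- mesh$labels == "fibrotic"
  # element adjacency via shared edges
  key <- mesh_edge_keys(tri)
  eid <- rep(seq_len(nrow(tri)), 3)
  ord <- order(key)
  key <- key[ord]; eid <- eid[ord]
  same <- key[-1] == key[-length(key)]
  pairs <- cbind(eid[c(same, FALSE)], eid[c(FALSE, same)])

  lipn <- unique(as.vector(tri[lip, ]))
  lumn <- mesh$lumen_nodes
  start <- which(fib & (tri[, 1] %in% lumn | tri[, 2] %in% lumn | tri[, 3] %in% lumn))
  goal <- which(fib & (tri[, 1] %in% lipn | tri[, 2] %in% lipn | tri[, 3] %in% lipn))
  if (!length(start) || !length(goal)) return(Inf)

  # BFS restricted to fibrotic elements
  keepp <- fib[pairs[, 1]] & fib[pairs[, 2]]
  pairs <- pairs[keepp, , drop = FALSE]
  adj <- split(c(pairs[, 2], pairs[, 1]), c(pairs[, 1], pairs[, 2]))
  dist <- rep(NA_integer_, nrow(tri))
  dist[start] <- 1L
  frontier <- start
  while (length(frontier)) {
    if (any(!is.na(dist[goal]))) break
    nbrs <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    nbrs <- nbrs[!is.na(nbrs)]
    nbrs <- nbrs[is.na(dist[nbrs])]
    dist[nbrs] <- min(dist[frontier]) + 1L
    frontier <- nbrs
  }
  d <- dist[goal]
  if (all(is.na(d))) Inf else min(d, na.rm = TRUE)
}

#' Structured annulus mesh (analytic-oracle support)
#'
#' Mapped polar-grid mesh of a circular annulus in a crisscross pattern (each
#' quadrilateral cell split into four triangles about its midpoint), which
#' behaves well for nearly incompressible plane-strain problems. Either the
#' full ring or a quarter (symmetry) sector.
#'
#' @param a,b inner and outer radii, mm (`a < b`).
#' @param nr,nt radial and tangential cell counts.
#' @param quarter if `TRUE`, mesh the first quadrant only; symmetry roller
#'   conditions are returned in attribute `sym_fixed_dofs`.
#' @param label tissue label applied to every element.
#' @return a `labeled_mesh`; lumen (pressure) edges are the inner boundary.
#' @export
annulus_mesh <- function(a, b, nr = 8, nt = 48, quarter = FALSE,
                         label = "fibrotic") {
  stopifnot(a > 0, b > a)
  th_max <- if (quarter) pi / 2 else 2 * pi
  nth <- if (quarter) nt + 1L else nt
  th <- seq(0, th_max, length.out = if (quarter) nth else nt + 1L)[seq_len(nth)]
  r <- seq(a, b, length.out = nr + 1)
  ring <- function(rr) cbind(rr * cos(th), rr * sin(th))
  nodes <- do.call(rbind, lapply(r, ring))
  id <- function(i, j) {  # radial i in 1..nr+1, angular j
    jj <- if (quarter) j else ((j - 1L) %% nt) + 1L
    (i - 1L) * nth + jj
  }
  tris <- list(); cn <- list()
  ncenter <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nt)) {
      n1 <- id(i, j); n2 <- id(i, j + 1L)
      n3 <- id(i + 1L, j + 1L); n4 <- id(i + 1L, j)
      ncenter <- ncenter + 1L
      cn[[ncenter]] <- colMeans(nodes[c(n1, n2, n3, n4), ])
      cidx <- ncenter + (nr + 1L) * nth
      tris[[length(tris) + 1L]] <- rbind(
        c(n1, n2, cidx), c(n2, n3, cidx), c(n3, n4, cidx), c(n4, n1, cidx))
    }
  }
  nodes <- rbind(nodes, do.call(rbind, cn))
  tri <- do.call(rbind, tris)
  ar <- tri_signed_areas(nodes, tri)
  tri[ar < 0, c(2, 3)] <- tri[ar < 0, c(3, 2)]

  inner <- which(sqrt(rowSums(nodes^2)) < a + 1e-9 * b)
  outer <- which(sqrt(rowSums(nodes^2)) > b - 1e-9 * b)
  # inner boundary edges oriented so rot90(b - a) points into the wall
  ea <- c(tri[, 1], tri[, 2], tri[, 3]); eb <- c(tri[, 2], tri[, 3], tri[, 1])
  key <- paste(pmin(ea, eb), pmax(ea, eb))
  single <- !(key %in% key[duplicated(key)])
  on_in <- logical(nrow(nodes)); on_in[inner] <- TRUE
  le <- single & on_in[ea] & on_in[eb]
  lumen_edges <- cbind(ea[le], eb[le])

  ang <- atan2(nodes[outer, 2], nodes[outer, 1])
  fixed <- vapply(c(0, 2 * pi / 3, -2 * pi / 3), function(aa) {
    outer[which.min(abs(((ang - aa + pi) %% (2 * pi)) - pi))]
  }, 0L)

  mesh <- labeled_mesh(nodes, tri, rep(label, nrow(tri)), lumen_edges,
                       outer_nodes = outer, fixed_nodes = fixed,
                       lumen_nodes = inner)
  if (quarter) {
    on_x <- which(abs(nodes[, 2]) < 1e-9 * b)  # y = 0 edge: u_y = 0
    on_y <- which(abs(nodes[, 1]) < 1e-9 * b)  # x = 0 edge: u_x = 0
    attr(mesh, "sym_fixed_dofs") <- sort(c(2L * on_x, 2L * on_y - 1L))
  }
  mesh
}
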