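# Serialization and the end-to-end reproduction driver. Meshes travel as
# Gmsh MSH v2.2 ASCII (physical groups = tissue labels) or VTU (cell-data
# label array); fields as CSV; configurations as YAML; summaries as JSON.

#' Write a labeled mesh as Gmsh MSH (v2.2 ASCII)
#'
#' Tissue labels become physical surface groups; triangles are element type 2.
#'
#' @param mesh a `labeled_mesh`.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_msh <- function(mesh, path) {
  labs <- sort(unique(mesh$labels))
  lab_id <- stats::setNames(seq_along(labs), labs)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("$MeshFormat", "2.2 0 8", "$EndMeshFormat")
  w("$PhysicalNames", as.character(length(labs)))
  w(sprintf('2 %d "%s"', lab_id, labs))
  w("$EndPhysicalNames")
  n <- nrow(mesh$nodes)
  w("$Nodes", as.character(n))
  w(sprintf("%d %.15g %.15g 0", seq_len(n), mesh$nodes[, 1], mesh$nodes[, 2]))
  w("$EndNodes")
  m <- nrow(mesh$triangles)
  w("$Elements", as.character(m))
  ids <- lab_id[mesh$labels]
  w(sprintf("%d 2 2 %d %d %d %d %d", seq_len(m), ids, ids,
            mesh$triangles[, 1], mesh$triangles[, 2], mesh$triangles[, 3]))
  w("$EndElements")
  invisible(path)
}

#' Read a labeled mesh from Gmsh MSH (v2.2 ASCII)
#'
#' Reads nodes, triangles and physical-group labels written by [write_msh()].
#' Boundary bookkeeping (lumen edges, fixed nodes) is reconstructed from the
#' triangulation: boundary edges on the inner (lumen) loop are identified by
#' enclosing-loop area, and fixed nodes are re-derived from the outer loop.
#'
#' @param path MSH file.
#' @return a `labeled_mesh`.
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(tag) {
    i0 <- which(lines == paste0("$", tag)) + 1L
    i1 <- which(lines == paste0("$End", tag)) - 1L
    lines[i0:i1]
  }
  pn <- sec("PhysicalNames")[-1]
  pn_id <- as.integer(sub('^\\d+ (\\d+) .*$', '\\1', pn))
  pn_name <- sub('^\\d+ \\d+ "(.*)"$', '\\1', pn)
  nd <- utils::read.table(text = sec("Nodes")[-1])
  nodes <- as.matrix(nd[order(nd[[1]]), 2:3])
  dimnames(nodes) <- NULL
  el <- utils::read.table(text = sec("Elements")[-1])
  el <- el[el[[2]] == 2, , drop = FALSE]
  tri <- as.matrix(el[, (ncol(el) - 2):ncol(el)])
  dimnames(tri) <- NULL
  labels <- pn_name[match(el[[4]], pn_id)]
  mesh_from_triangulation(nodes, tri, labels)
}

# Rebuild boundary bookkeeping (lumen edges, outer/fixed nodes) from a bare
# labeled triangulation.
mesh_from_triangulation <- function(nodes, tri, labels) {
  ar <- tri_signed_areas(nodes, tri)
  tri[ar < 0, c(2, 3)] <- tri[ar < 0, c(3, 2)]
  ea <- c(tri[, 1], tri[, 2], tri[, 3]); eb <- c(tri[, 2], tri[, 3], tri[, 1])
  key <- paste(pmin(ea, eb), pmax(ea, eb))
  single <- !(key %in% key[duplicated(key)])
  bea <- ea[single]; beb <- eb[single]
  # split boundary edges into loops
  loops <- list()
  remaining <- seq_along(bea)
  while (length(remaining)) {
    cur <- remaining[1]; loop <- cur
    repeat {
      nxt <- remaining[match(beb[cur], bea[remaining])]
      if (is.na(nxt) || nxt == loop[1]) break
      loop <- c(loop, nxt); cur <- nxt
    }
    loops[[length(loops) + 1L]] <- loop
    remaining <- setdiff(remaining, loop)
  }
  area <- vapply(loops, function(l) {
    p <- nodes[bea[l], , drop = FALSE]
    abs(polygon_area(p))
  }, 0)
  outer_loop <- loops[[which.max(area)]]
  # lumen = largest interior loop (holes of inclusions do not exist: they are
  # meshed; the only interior boundary is the lumen)
  inner_loops <- loops[-which.max(area)]
  if (!length(inner_loops)) stopf("mesh has no interior (lumen) boundary")
  lumen_loop <- inner_loops[[which.max(vapply(inner_loops, function(l)
    abs(polygon_area(nodes[bea[l], , drop = FALSE])), 0))]]
  lumen_edges <- cbind(bea[lumen_loop], beb[lumen_loop])
  outer_ids <- unique(as.vector(cbind(bea[outer_loop], beb[outer_loop])))
  octr <- colMeans(nodes[outer_ids, , drop = FALSE])
  ang <- atan2(nodes[outer_ids, 2] - octr[2], nodes[outer_ids, 1] - octr[1])
  fixed <- vapply(c(0, 2 * pi / 3, -2 * pi / 3), function(a) {
    outer_ids[which.min(abs(((ang - a + pi) %% (2 * pi)) - pi))]
  }, 0L)
  labeled_mesh(nodes, tri, labels, lumen_edges, outer_ids, fixed,
               lumen_nodes = unique(as.vector(lumen_edges)))
}

#' Write a mesh (with optional cell data) as ASCII VTU
#'
#' @param mesh a `labeled_mesh`.
#' @param path output file.
#' @param cell_data optional named list of per-element numeric vectors.
#' @return invisibly `path`.
#' @export
write_vtu <- function(mesh, path, cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$triangles)
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(sprintf("%.10g %.10g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(sprintf("%d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(as.character(3L * seq_len(m)), con)
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(rep("5", m), con)
  w('</DataArray></Cells>')
  w('<CellData>')
  labs <- sort(unique(mesh$labels))
  cell_data <- c(list(label = match(mesh$labels, labs)), cell_data)
  for (nm in names(cell_data)) {
    w('<DataArray type="Float64" Name="%s" format="ascii">', nm)
    writeLines(sprintf("%.10g", cell_data[[nm]]), con)
    w('</DataArray>')
  }
  w('</CellData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}

#' Write / read a strain field as CSV
#'
#' Columns: element id, centroid, all strain components, label; the
#' cylindrical center travels in a `# center` comment line.
#'
#' @param field a `strain_field`.
#' @param path output file.
#' @return invisibly `path` (write) / a `strain_field` (read).
#' @export
write_strain_csv <- function(field, path) {
  df <- data.frame(element = seq_along(field$err),
                   cx = field$centroids[, 1], cy = field$centroids[, 2],
                   exx = field$exx, eyy = field$eyy, exy = field$exy,
                   err = field$err, ett = field$ett, ert = field$ert,
                   e1 = field$e1, e2 = field$e2, evm = field$evm,
                   label = field$labels %||% NA)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# center %.12g %.12g", field$center[1], field$center[2]), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_strain_csv
#' @export
read_strain_csv <- function(path) {
  first <- readLines(path, n = 1)
  center <- as.numeric(strsplit(sub("^# center ", "", first), " ")[[1]])
  df <- utils::read.csv(path, comment.char = "#")
  strain_field_from_cartesian(df$exx, df$eyy, df$exy,
                              cbind(df$cx, df$cy), center,
                              labels = if (all(is.na(df$label))) NULL else df$label)
}

#' Write / read a simulated frame pair as CSV
#'
#' Columns: node id, coordinates at the lower pressure, relative
#' displacements to the upper pressure; the pressures travel in a comment
#' line. Reading requires the matching mesh (connectivity is not stored).
#'
#' @param pair a `frame_pair`.
#' @param path output file.
#' @param mesh the `labeled_mesh` the pair was simulated on.
#' @return invisibly `path` (write) / a `frame_pair` (read).
#' @export
write_frame_csv <- function(pair, path) {
  df <- data.frame(node = seq_len(nrow(pair$coords)),
                   x = pair$coords[, 1], y = pair$coords[, 2],
                   ux = pair$rel_disp[, 1], uy = pair$rel_disp[, 2])
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# pressures %.10g %.10g", pair$p_lo, pair$p_hi), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_csv
#' @export
read_frame_csv <- function(path, mesh) {
  first <- readLines(path, n = 1)
  pr <- as.numeric(strsplit(sub("^# pressures ", "", first), " ")[[1]])
  df <- utils::read.csv(path, comment.char = "#")
  df <- df[order(df$node), ]
  structure(list(coords = cbind(df$x, df$y), rel_disp = cbind(df$ux, df$uy),
                 p_lo = pr[1], p_hi = pr[2], mesh = mesh),
            class = "frame_pair")
}

#' Run the full in-silico characterization pipeline
#'
#' Geometry generation, meshing, ground-truth frame simulation, strain
#' noising, inverse characterization (linear or nonlinear), and maximum
#' principal stress mapping at the upper frame pressure with the recovered
#' materials — with every artifact written into one output directory and a
#' machine-readable JSON summary carrying full provenance (configuration
#' hash, package version, seeds).
#'
#' @param config list (or YAML path) with optional entries: `mode`
#'   ("linear" or "nonlinear"), `pressures` (c(p_lo, p_hi), mmHg), `snr_db`,
#'   `seed`, `spec` (arguments to [plaque_spec()]), `edge_length` (mm),
#'   `truth` (for linear: named E list; for nonlinear: fibrotic GOH name),
#'   `max_evaluations`, `out_dir`.
#' @return list with all stage outputs (`mesh`, `frames`, `measured`,
#'   `result`, `stress`, `summary`), invisibly writing artifacts when
#'   `out_dir` is set.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mode <- config$mode %||% "linear"
  pr <- config$pressures %||% c(110, 115)
  snr <- config$snr_db %||% 20
  seed <- config$seed %||% 1L
  edge <- config$edge_length %||% NULL

  spec <- do.call(plaque_spec, c(config$spec %||% list(), list(seed = seed)))
  geom <- generate_plaque(spec)
  mesh <- mesh_plaque(geom, edge %||% (spec$min_cap_thickness / 3))

  if (mode == "linear") {
    E_true <- config$truth %||% list(fibrotic = 600, lipid = 10, calcification = 5000)
    truth_E <- stats::setNames(vapply(mesh_label_kinds(mesh), function(k)
      as.numeric(E_true[[k]]), 0), unique(mesh$labels))
    mats <- material_set(.list = lapply(stats::setNames(nm = unique(mesh$labels)),
      function(l) {
        k <- label_kind(l)
        if (k == "calcification") linear_elastic(truth_E[[l]], 0.333)
        else {
          nh <- neo_hooke_from_linear(truth_E[[l]], 0.45)
          neo_hooke(nh$C10, nh$D1)
        }
      }))
  } else {
    fib <- fibrotic_goh(config$truth %||% "calcified1")
    mats <- material_set(.list = lapply(stats::setNames(nm = unique(mesh$labels)),
      function(l) {
        k <- label_kind(l)
        if (k == "fibrotic") fib
        else if (k == "lipid") neo_hooke(1.72, 0.06)
        else linear_elastic(5000, 0.333)
      }))
  }

  frames <- simulate_frame_pair(mesh, mats, pr[1], pr[2])
  clean <- frame_strains(frames)
  measured <- add_noise(clean, snr_db = snr, seed = seed)
  imaged <- labeled_mesh(frames$coords, mesh$triangles, mesh$labels,
                         mesh$lumen_edges, mesh$outer_nodes, mesh$fixed_nodes,
                         mesh$lumen_nodes)

  if (mode == "linear") {
    result <- characterize_linear(
      measured, imaged, dP = pr[2] - pr[1],
      config = gss_config(initial_mesh = 1,
                          max_evaluations = config$max_evaluations %||% 200L),
      truth = truth_E)
    est_mats <- material_set(.list = lapply(stats::setNames(nm = unique(mesh$labels)),
      function(l) linear_elastic(result$parameters[[l]],
                                 if (label_kind(l) == "calcification") 0.333 else 0.49)))
    stress_sol <- suppressWarnings(
      inflate(imaged, est_mats, pr[2] - pr[1]))
  } else {
    result <- characterize_nonlinear(
      measured, imaged, p_lo = pr[1], p_hi = pr[2],
      config = gss_config(initial_mesh = 100,
                          max_evaluations = config$max_evaluations %||% 40L),
      truth = mats)
    stress_sol <- inflate(imaged, result$materials, pr[2],
                          coords = result$zp_coordinates %||% imaged$nodes)
  }
  stress <- max_principal_stress(stress_sol)

  summary <- list(
    package_version = as.character(utils::packageVersion("atheroIFEM")),
    mode = mode, pressures = pr, snr_db = snr, seed = seed,
    config_hash = config_hash(config[setdiff(names(config), "out_dir")]),
    J0 = result$J0,
    parameters = as.list(result$parameters),
    sr = if (!is.null(result$sr)) as.list(result$sr),
    curve_r2 = if (!is.null(result$curve_r2)) as.list(result$curve_r2),
    K_zp = if (mode == "nonlinear") result$K_zp,
    sigma_max_peak = max(stress$sigma_max),
    n_elements = nrow(mesh$triangles), n_evaluations = result$n_evaluations)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_msh(mesh, p("zp_mesh.msh"))
    write_msh(imaged, p("imaged_mesh.msh"))
    write_strain_csv(measured, p("measured_strains.csv"))
    write_vtu(imaged, p("stress.vtu"),
              cell_data = list(sigma_max = stress$sigma_max,
                               err_measured = measured$err))
    jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  invisible(list(mesh = mesh, geometry = geom, frames = frames,
                 measured = measured, result = result, stress = stress,
                 summary = summary))
}

label_kind <- function(label) sub("_\\d+$", "", label)
mesh_label_kinds <- function(mesh) label_kind(unique(mesh$labels))

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash; avoids a digest dependency
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Tabulate an inverse-characterization report
#'
#' Flattens a pipeline bundle into plain data frames (cost history, recovered
#' parameters, and per-tissue metrics) ready for plotting or export, and
#' optionally draws the cost-history and behavior-curve figures when ggplot2
#' is available.
#'
#' @param bundle a [run_pipeline()] result.
#' @param out_dir optional directory for CSV tables (and PDF figures).
#' @return list of data frames (`history`, `parameters`, `metrics`).
#' @export
render_report <- function(bundle, out_dir = NULL) {
  result <- bundle$result
  if (is.null(result) || nrow(result$history) == 0)
    stopf("empty characterization history")
  history <- result$history
  params <- data.frame(name = names(result$parameters),
                       value = as.numeric(result$parameters))
  metrics <- if (!is.null(result$sr)) {
    data.frame(label = names(result$sr), metric = "sr", value = as.numeric(result$sr))
  } else if (!is.null(result$curve_r2)) {
    data.frame(label = names(result$curve_r2), metric = "curve_r2",
               value = as.numeric(result$curve_r2))
  } else data.frame(label = character(0), metric = character(0), value = numeric(0))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(history, file.path(out_dir, "history.csv"), row.names = FALSE)
    utils::write.csv(params, file.path(out_dir, "parameters.csv"), row.names = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    if (requireNamespace("ggplot2", quietly = TRUE)) {
      g <- ggplot2::ggplot(history,
                           ggplot2::aes(x = .data$evaluation,
                                        y = cummin(.data$J0))) +
        ggplot2::geom_step() +
        ggplot2::labs(x = "evaluation", y = "best J0 [%]")
      ggplot2::ggsave(file.path(out_dir, "cost_history.pdf"), g,
                      width = 5, height = 4)
    }
  }
  list(history = history, parameters = params, metrics = metrics)
}
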