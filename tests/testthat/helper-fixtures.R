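# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# A small, quick plaque: one lipid, one calcification, coarse cap.
small_plaque_spec <- function(seed = 1L) {
  plaque_spec(outer_radius = 2, lumen_radius = 0.9, lumen_offset = c(0.4, 0),
              min_cap_thickness = 0.4, contour_noise_amplitude = 0.02,
              inclusions = list(
                list(kind = "lipid", center = c(-1.32, 0.1),
                     semi_axes = c(0.3, 0.2), rotation = 0.3),
                list(kind = "calcification", center = c(0.7, 1.25),
                     semi_axes = c(0.2, 0.13), rotation = -0.5)),
              seed = seed)
}

small_plaque_mesh <- function() {
  fixture("small_plaque_mesh", function() {
    sp <- small_plaque_spec()
    mesh_plaque(generate_plaque(sp), sp$min_cap_thickness / 3)
  })
}

# The default study plaque at its standard mesh resolution.
study_mesh <- function() {
  fixture("study_mesh", function() {
    sp <- plaque_spec()
    mesh_plaque(generate_plaque(sp), sp$min_cap_thickness / 3)
  })
}

table1_materials <- function(mesh) {
  nh_f <- neo_hooke_from_linear(600, 0.45)
  nh_l <- neo_hooke_from_linear(10, 0.45)
  mats <- lapply(stats::setNames(nm = unique(mesh$labels)), function(l) {
    if (l == "fibrotic") neo_hooke(nh_f$C10, nh_f$D1)
    else if (startsWith(l, "lipid")) neo_hooke(nh_l$C10, nh_l$D1)
    else linear_elastic(5000, 0.333)
  })
  material_set(.list = mats)
}

goh_materials <- function(mesh, fibrotic = "calcified1") {
  mats <- lapply(stats::setNames(nm = unique(mesh$labels)), function(l) {
    if (l == "fibrotic") fibrotic_goh(fibrotic)
    else if (startsWith(l, "lipid")) neo_hooke(1.72, 0.06)
    else linear_elastic(5000, 0.333)
  })
  material_set(.list = mats)
}

# Imaged mesh: same topology with nodes moved to the lower-pressure frame.
imaged_mesh <- function(mesh, frames) {
  atheroIFEM:::labeled_mesh(frames$coords, mesh$triangles, mesh$labels,
                            mesh$lumen_edges, mesh$outer_nodes,
                            mesh$fixed_nodes, mesh$lumen_nodes)
}

# GOH-simulated frame pair + noisy measurement on the study plaque, shared by
# the nonlinear-recovery and approach-comparison tests.
goh_study_case <- function() {
  fixture("goh_study_case", function() {
    mesh <- study_mesh()
    truth <- goh_materials(mesh)
    cfg <- solver_config(load_steps = 4)
    frames <- simulate_frame_pair(mesh, truth, 110, 115, cfg)
    clean <- frame_strains(frames)
    list(mesh = mesh, truth = truth, solver = cfg, frames = frames,
         clean = clean, measured = add_noise(clean, 20, seed = 7L),
         imaged = imaged_mesh(mesh, frames))
  })
}

expect_no_error <- function(expr) expect_error(expr, NA)
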