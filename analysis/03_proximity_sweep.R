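#!/usr/bin/env Rscript
# Proximity sweeps: impedance versus carrier offset along the x axis
# (towards the modiolar wall) and the y axis (towards the basilar membrane),
# recorded for E1, E6, E11 and E16, plus the grid-wide map for E1.
# Outputs under results/proximity/.

suppressPackageStartupMessages(library(cochleaVC))
outdir <- "results/proximity"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

params <- cochlea_params()
array <- electrode_array_spec()
cond <- conductivity_table()
cfg <- default_config()
mesh_opts <- mesh_options(target_size_near_m = 2e-4, target_size_far_m = 8e-4)

for (axis in c("x", "y")) {
  ray <- make_proximity_ray(params, array, axis = axis, n_positions = 8L)
  sw <- run_proximity_sweep(params, array, cond, ray, mesh_opts = mesh_opts)
  for (ct in unique(sw$contact)) {
    z <- sw$Z_ohm[sw$contact == ct]
    message(sprintf("%s-axis %s: %.2f -> %.2f kOhm (x%.2f) mid-scala -> near wall",
                    axis, ct, z[1] / 1e3, z[length(z)] / 1e3, z[length(z)] / z[1]))
  }
  export_results(sw, outdir, prefix = paste0("sweep_", axis), cfg = cfg,
                 seed = cfg$seed)
  png(file.path(outdir, paste0("sweep_", axis, ".png")),
      width = 900, height = 600, res = 120)
  print(plot_proximity_profiles(sw, axis = axis))
  dev.off()
}

# full 12 x 12 grid (valid placements only are solved), recorded for E1
grid <- make_proximity_grid(params, array)
sw_grid <- run_proximity_sweep(params, array, cond, grid,
                               recorded_contacts = "E1",
                               mesh_opts = mesh_opts)
message(sprintf("grid sweep: %d of %d candidate placements solved",
                nrow(sw_grid), length(grid$placements)))
export_results(sw_grid, outdir, prefix = "grid_E1", cfg = cfg, seed = cfg$seed)
message("proximity results written to ", outdir)
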