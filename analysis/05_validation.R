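#!/usr/bin/env Rscript
# Verification suite: analytic oracles (disk spreading resistance,
# concentric spheres, layered bar), mesh-convergence study, and reciprocity
# and linearity checks on the full cochlea geometry.  Outputs under
# results/validation/.

suppressPackageStartupMessages(library(cochleaVC))
outdir <- "results/validation"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

sig <- conductivity_table()$sigma_S_per_m[["scala_tympani"]]
rows <- list()

# disk contact on a half-space
a <- 2.5e-4
oracle <- disk_spreading_resistance(sig, a)
src <- source_spec("CONTACT_DISK", 1e-3)
condm <- conductivity_table(c(medium = sig))
for (na in c(5L, 8L)) {
  f <- solve_potential(make_disk_block_mesh(a, n_a = na), condm, src)
  Z <- compute_impedance(f, "CONTACT_DISK", src)$Z_ohm
  rows[[length(rows) + 1]] <- data.frame(
    problem = "disk_half_space", refinement = na, Z_ohm = Z,
    oracle_ohm = oracle, rel_error = abs(Z - oracle) / oracle)
}

# concentric spheres
oracle <- concentric_spheres_resistance(sig, 1e-3, 5e-3)
srcs <- source_spec("CONTACT_INNER", 1e-3)
for (ns in c(4L, 8L)) {
  f <- solve_potential(make_spherical_shell_mesh(1e-3, 5e-3, ns, 2L * ns),
                       condm, srcs)
  Z <- compute_impedance(f, "CONTACT_INNER", srcs)$Z_ohm
  rows[[length(rows) + 1]] <- data.frame(
    problem = "concentric_spheres", refinement = ns, Z_ohm = Z,
    oracle_ohm = oracle, rel_error = abs(Z - oracle) / oracle)
}

# layered bar with a thin resistive interface
ab <- c(1e-3, 2e-3); L <- 1e-2; z0 <- 4e-3; sig2 <- 0.3
sig_s <- 0.0053; t_s <- 3e-5
oracle <- z0 / (sig * prod(ab)) + t_s / (sig_s * prod(ab)) +
  (L - z0) / (sig2 * prod(ab))
condb <- conductivity_table(c(bar_lower = sig, bar_upper = sig2,
                              stria_vascularis = sig_s),
                            stria_thickness_m = t_s)
srcb <- source_spec("CONTACT_BAR", 1e-3)
for (nz in c(5L, 10L)) {
  mesh <- make_bar_mesh(ab[1], ab[2], L, n = c(3, 3, nz), split_z = z0,
                        thin_layer = TRUE)
  f <- solve_potential(mesh, condb, srcb)
  Z <- compute_impedance(f, "CONTACT_BAR", srcb)$Z_ohm
  rows[[length(rows) + 1]] <- data.frame(
    problem = "layered_bar_thin_layer", refinement = nz, Z_ohm = Z,
    oracle_ohm = oracle, rel_error = abs(Z - oracle) / oracle)
}

oracles <- do.call(rbind, rows)
print(oracles, digits = 4)
write.csv(oracles, file.path(outdir, "oracles.csv"), row.names = FALSE)

# convergence order on the smooth spheres problem
fac <- function(h) make_spherical_shell_mesh(
  1e-3, 5e-3, n_surf = max(3L, round(1e-3 / h)),
  n_rad = max(3L, 2L * round(1e-3 / h)))
rep <- run_convergence_study(fac, condm, srcs, 1e-3 / c(3, 4, 6, 8),
                             oracle = concentric_spheres_resistance(sig, 1e-3, 5e-3))
print(rep)
export_results(rep, outdir, prefix = "convergence_spheres")

# reciprocity and linearity on the full cochlea geometry at coarse resolution
params <- cochlea_params(); array <- electrode_array_spec()
cond <- conductivity_table()
geom <- build_cochlea_geometry(params, array, placement(0, 0, 16))
mesh <- generate_mesh(geom, mesh_options(2e-4, 8e-4))
opts <- solver_options(ground_mode = "patch")
Z <- transfer_impedance_matrix(mesh, cond, opts = opts)
recip <- max(abs(Z - t(Z))) / max(diag(Z))
src1 <- source_spec("CONTACT_E8")
f1 <- solve_potential(mesh, cond, src1, opts)
k <- 2
f2 <- solve_potential(mesh, perturb_conductivity(cond, "all", k), src1, opts)
lin <- max(abs(f2$values_V * k - f1$values_V)) / max(abs(f1$values_V))
message(sprintf("cochlea reciprocity defect: %.2e; sigma-linearity defect: %.2e",
                recip, lin))
jsonlite::write_json(list(reciprocity_rel = recip, linearity_rel = lin,
                          n_contacts = ncol(Z)),
                     file.path(outdir, "cochlea_checks.json"),
                     auto_unbox = TRUE, digits = NA)
message("validation results written to ", outdir)
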