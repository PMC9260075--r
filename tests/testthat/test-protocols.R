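# Protocol drivers on a short 4-contact array (cheap) plus structural
# checks that scale to the full 16-contact protocol.

test_that("sequential insertion records exactly k contacts per step, E1..Ek", {
  map <- cached("seq4", run_sequential_insertion(
    cochlea_params(), small_array(), conductivity_table(),
    mesh_opts = coarse_opts()))
  n <- small_array()$n_contacts
  for (mode in c("floating", "grounded")) {
    sub <- map[map$mode == mode, ]
    expect_identical(nrow(sub), (n * (n + 1L)) %/% 2L)
    for (k in seq_len(n)) {
      stepk <- sub[sub$step_k == k, ]
      expect_setequal(stepk$contact, paste0("E", seq_len(k)))
    }
  }
  expect_true(all(map$Z_ohm > 0))
  expect_identical(map$Z_ohm, map$V_V / map$I_A)
})

test_that("grounded-inactive impedances never exceed floating ones", {
  map <- cached("seq4", run_sequential_insertion(
    cochlea_params(), small_array(), conductivity_table(),
    mesh_opts = coarse_opts()))
  fl <- map[map$mode == "floating", ]
  gr <- map[map$mode == "grounded", ]
  m <- merge(as.data.frame(fl), as.data.frame(gr),
             by = c("step_k", "contact"), suffixes = c("_fl", "_gr"))
  # grounding the neighbours adds parallel sinks, so Z can only drop
  expect_true(all(m$Z_ohm_gr <= m$Z_ohm_fl * (1 + 1e-9)))
})

test_that("depth profile has one record per contact and matches the full-step slice", {
  prof <- run_insertion_depth_profile(cochlea_params(), small_array(),
                                      conductivity_table(),
                                      pl = placement(0, 0, 4L),
                                      mesh_opts = coarse_opts())
  expect_identical(nrow(prof), 4L)
  map <- cached("seq4", run_sequential_insertion(
    cochlea_params(), small_array(), conductivity_table(),
    mesh_opts = coarse_opts()))
  last <- map[map$step_k == 4L & map$mode == "floating", ]
  expect_equal(prof$Z_ohm[match(last$contact, prof$contact)], last$Z_ohm,
               tolerance = 1e-9)
})

test_that("full-insertion depth profile is stable under mesh refinement", {
  p <- cochlea_params(); arr <- electrode_array_spec()
  prof_c <- run_insertion_depth_profile(p, arr, conductivity_table(),
                                        mesh_opts = mesh_options(2e-4, 8e-4))
  prof_f <- cached("prof16_default",
                   run_insertion_depth_profile(p, arr, conductivity_table()))
  d <- abs(prof_c$Z_ohm - prof_f$Z_ohm) / prof_f$Z_ohm
  expect_lt(max(d), 0.05)
})

test_that("proximity sweep records only requested contacts and skips invalid placements", {
  p <- cochlea_params(); arr <- electrode_array_spec()
  ray <- make_proximity_ray(p, arr, axis = "y", n_positions = 3)
  # append a deliberately invalid placement: it must be skipped, not recorded
  bad <- placement(0, p$st_semi_axes_apex_m[2], 16, grid_index = c(99L, 99L))
  sw <- run_proximity_sweep(p, arr, conductivity_table(), c(ray, list(bad)),
                            recorded_contacts = c("E1", "E6", "E11", "E16"),
                            mesh_opts = coarse_opts())
  expect_setequal(unique(sw$contact), c("E1", "E6", "E11", "E16"))
  expect_identical(nrow(sw), 3L * 4L)
  md <- map_metadata(sw)
  expect_identical(md$n_skipped, 1L)
  expect_true(all(sw$Z_ohm > 0))
  expect_identical(sw$Z_ohm, sw$V_V / sw$I_A)
})

test_that("impedance is mirror-symmetric in a symmetric straight channel", {
  cond <- conductivity_table()
  src <- source_spec("CONTACT_E2")
  Z <- vapply(c(2e-4, -2e-4), function(off) {
    mesh <- generate_mesh(toy_with_array(y_offset = off),
                          mesh_options(1e-4, 4e-4))
    compute_impedance(solve_potential(mesh, cond, src), "CONTACT_E2", src)$Z_ohm
  }, numeric(1))
  expect_lt(abs(Z[1] - Z[2]) / Z[1], 0.01)
})

test_that("near-wall impedance exceeds mid-scala impedance for every recorded contact", {
  p <- cochlea_params(); arr <- electrode_array_spec()
  ray <- make_proximity_ray(p, arr, axis = "x", n_positions = 3)
  sw <- cached("ray_x3", run_proximity_sweep(
    p, arr, conductivity_table(), ray, mesh_opts = coarse_opts()))
  for (ct in unique(sw$contact)) {
    z <- sw$Z_ohm[sw$contact == ct]
    expect_gt(z[length(z)], z[1])
    expect_true(all(diff(z) > -1e-9 * z[1]))
  }
})

test_that("conductivity sensitivity reports baseline-anchored normalised profiles", {
  sens <- cached("sens_small", run_conductivity_sensitivity(
    cochlea_params(), electrode_array_spec(), conductivity_table(),
    n_positions = 4L, mesh_opts = coarse_opts()))
  expect_identical(sens$factors, c(0.90, 0.95, 1.00, 1.05, 1.10))
  expect_true(1 %in% sens$factors)
  expect_gte(sens$normalized_deviation, 0)
  # global scaling of every conductivity leaves the normalised profile intact
  sens_all <- run_conductivity_sensitivity(
    cochlea_params(), electrode_array_spec(), conductivity_table(),
    layer = "all", factors = c(1, 2), n_positions = 3L,
    mesh_opts = coarse_opts())
  prof <- sens_all$profiles
  n1 <- prof$Z_normalized[prof$factor == 1]
  n2 <- prof$Z_normalized[prof$factor == 2]
  expect_equal(n1, n2, tolerance = 1e-9)
  z1 <- prof$Z_ohm[prof$factor == 1]
  z2 <- prof$Z_ohm[prof$factor == 2]
  expect_equal(z1, 2 * z2, tolerance = 1e-9)
  expect_error(run_conductivity_sensitivity(
    cochlea_params(), electrode_array_spec(), conductivity_table(),
    factors = c(0.9, 1.1)), "baseline")
})
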