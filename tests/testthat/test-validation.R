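# Analytic oracles and the convergence machinery.

test_that("disk spreading resistance closed form", {
  expect_equal(disk_spreading_resistance(1, 1), 0.25)
  expect_equal(disk_spreading_resistance(1.43, 2.5e-4), 1 / (4 * 1.43 * 2.5e-4))
  expect_equal(disk_spreading_resistance(1.43, 2.5e-4), 699.3, tolerance = 1e-4)
  expect_error(disk_spreading_resistance(-1, 1), "positive")
  expect_error(disk_spreading_resistance(1, 0), "positive")
})

test_that("concentric spheres closed form and half-space limit", {
  expect_equal(concentric_spheres_resistance(1, 1, 2), 0.039789, tolerance = 1e-4)
  expect_equal(concentric_spheres_resistance(2, 1e-3, 1e9),
               1 / (4 * pi * 2 * 1e-3), tolerance = 1e-6)
  expect_error(concentric_spheres_resistance(1, 2, 1), "a < b")
})

test_that("FEM concentric spheres converge to the closed form within 2%", {
  a <- 1e-3; b <- 5e-3; sig <- 1.43
  cond <- conductivity_table(c(medium = sig))
  src <- source_spec("CONTACT_INNER", 1e-3)
  mesh <- make_spherical_shell_mesh(a, b, n_surf = 8, n_rad = 10)
  f <- solve_potential(mesh, cond, src)
  Z <- compute_impedance(f, "CONTACT_INNER", src)$Z_ohm
  expect_lt(abs(Z - concentric_spheres_resistance(sig, a, b)) /
              concentric_spheres_resistance(sig, a, b), 0.02)
})

test_that("FEM disk contact approaches the spreading resistance within 5%", {
  a <- 2.5e-4; sig <- 1.43
  cond <- conductivity_table(c(medium = sig))
  src <- source_spec("CONTACT_DISK", 1e-3)
  mesh <- make_disk_block_mesh(a, n_a = 8)
  f <- solve_potential(mesh, cond, src)
  Z <- compute_impedance(f, "CONTACT_DISK", src)$Z_ohm
  expect_lt(abs(Z - disk_spreading_resistance(sig, a)) /
              disk_spreading_resistance(sig, a), 0.05)
})

test_that("convergence study: bar error stays at solver tolerance, runs are deterministic", {
  sig <- 1.43
  cond <- conductivity_table(c(bar_lower = sig))
  src <- source_spec("CONTACT_BAR", 1e-3)
  fac <- function(h) make_bar_mesh(1e-3, 2e-3, 10e-3,
                                   n = c(2, 2, max(3L, round(10e-3 / h))))
  rep <- run_convergence_study(fac, cond, src, c(2e-3, 1e-3, 5e-4),
                               oracle = 10e-3 / (sig * 1e-3 * 2e-3))
  expect_true(all(rep$rel_error < 1e-8))
  rep2 <- run_convergence_study(fac, cond, src, c(2e-3, 1e-3, 5e-4))
  expect_identical(rep$results$Z_ohm, rep2$results$Z_ohm)
  expect_error(run_convergence_study(fac, cond, src, c(1e-3, 2e-3, 5e-4)),
               "decreasing")
})

test_that("observed convergence order on a smooth problem is at least 1.5", {
  a <- 1e-3; b <- 5e-3; sig <- 1.43
  cond <- conductivity_table(c(medium = sig))
  src <- source_spec("CONTACT_INNER", 1e-3)
  fac <- function(h) make_spherical_shell_mesh(
    a, b, n_surf = max(3L, round(a / h)), n_rad = max(3L, 2L * round(a / h)))
  rep <- run_convergence_study(fac, cond, src, a / c(3, 4, 6, 8),
                               oracle = concentric_spheres_resistance(sig, a, b))
  expect_gte(rep$observed_order, 1.5)
  expect_lt(abs(rep$Z_extrapolated - rep$oracle) / rep$oracle, 0.01)
  # discretisation error decreases monotonically under refinement
  expect_true(all(diff(rep$rel_error) < 0))
})
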