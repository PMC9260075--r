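# FEM solver: closed-form resistance oracles, linearity, reciprocity,
# passivity, conservation, the two contact models and both linear solvers.

test_that("homogeneous bar reproduces L / (sigma A)", {
  a <- 1e-3; b <- 2e-3; L <- 10e-3; sig <- 1.43
  cond <- conductivity_table(c(bar_lower = sig))
  src <- source_spec("CONTACT_BAR", 1e-3)
  for (n in list(c(2, 2, 5), c(3, 3, 10))) {
    mesh <- make_bar_mesh(a, b, L, n = n)
    f <- solve_potential(mesh, cond, src)
    Z <- compute_impedance(f, "CONTACT_BAR", src)$Z_ohm
    # the exact solution is linear, so P1 reproduces it to solver tolerance
    expect_lt(abs(Z - L / (sig * a * b)) / (L / (sig * a * b)), 0.01)
    expect_lt(abs(Z - L / (sig * a * b)) / (L / (sig * a * b)), 1e-8)
  }
})

test_that("thin resistive layer adds t / (sigma_s A) in series", {
  a <- 1e-3; b <- 2e-3; L <- 10e-3; z0 <- 4e-3
  sig1 <- 1.43; sig2 <- 0.3; sig_s <- 0.0053; t_s <- 3e-5
  mesh <- make_bar_mesh(a, b, L, n = c(3, 3, 10), split_z = z0,
                        thin_layer = TRUE)
  cond <- conductivity_table(c(bar_lower = sig1, bar_upper = sig2,
                               stria_vascularis = sig_s),
                             stria_thickness_m = t_s)
  src <- source_spec("CONTACT_BAR", 1e-3)
  f <- solve_potential(mesh, cond, src)
  Z <- compute_impedance(f, "CONTACT_BAR", src)$Z_ohm
  Z_oracle <- z0 / (sig1 * a * b) + t_s / (sig_s * a * b) +
    (L - z0) / (sig2 * a * b)
  expect_lt(abs(Z - Z_oracle) / Z_oracle, 0.01)
  # flux continuity: the same current reaches ground
  expect_equal(ground_current(mesh, cond, f, src),
               src$injected_current_A, tolerance = 1e-8)
})

test_that("impedance definition and linearity in the injected current", {
  mesh <- small_cochlea_mesh()
  cond <- conductivity_table()
  src1 <- source_spec("CONTACT_E2", 34e-6)
  src2 <- source_spec("CONTACT_E2", 68e-6)
  f1 <- solve_potential(mesh, cond, src1, patch_opts())
  f2 <- solve_potential(mesh, cond, src2, patch_opts())
  r1 <- compute_impedance(f1, "CONTACT_E2", src1)
  r2 <- compute_impedance(f2, "CONTACT_E2", src2)
  expect_identical(r1$Z_ohm, r1$V_V / r1$I_A)
  expect_gt(r1$Z_ohm, 0)
  # doubling I doubles V and leaves Z unchanged
  expect_equal(r2$V_V, 2 * r1$V_V, tolerance = 1e-9)
  expect_equal(r2$Z_ohm, r1$Z_ohm, tolerance = 1e-9)
  # 0.0952 V at 34 uA is 2800 ohm
  fake <- structure(list(contact_potentials_V = c(CONTACT_X = 0.0952)),
                    class = "potential_field")
  expect_equal(compute_impedance(fake, "CONTACT_X",
                                 source_spec("CONTACT_X", 34e-6))$Z_ohm, 2800)
})

test_that("scaling all conductivities by k scales V and Z by 1/k", {
  mesh <- small_cochlea_mesh()
  cond <- conductivity_table()
  src <- source_spec("CONTACT_E3")
  f1 <- solve_potential(mesh, cond, src, patch_opts())
  k <- 2.7
  f2 <- solve_potential(mesh, perturb_conductivity(cond, "all", k), src,
                        patch_opts())
  expect_equal(f2$values_V * k, f1$values_V, tolerance = 1e-9)
})

test_that("transfer-impedance matrix is reciprocal and passive", {
  mesh <- small_cochlea_mesh()
  Z <- cached("Zmat_small", transfer_impedance_matrix(mesh,
                                                      conductivity_table(),
                                                      opts = patch_opts()))
  expect_identical(dim(Z), c(4L, 4L))
  expect_lt(max(abs(Z - t(Z))) / max(diag(Z)), 1e-6)
  for (j in seq_len(ncol(Z))) {
    expect_true(all(Z[, j] >= 0))
    expect_true(all(Z[j, j] >= Z[, j]))
  }
  # single contact reduces to compute_impedance
  src <- source_spec("CONTACT_E1")
  f <- solve_potential(mesh, conductivity_table(), src, patch_opts())
  Z1 <- transfer_impedance_matrix(mesh, conductivity_table(),
                                  contacts = "CONTACT_E1", opts = patch_opts())
  expect_equal(unname(Z1[1, 1]),
               compute_impedance(f, "CONTACT_E1", src)$Z_ohm,
               tolerance = 1e-10)
})

test_that("passivity holds for an exhaustively solved resistor network", {
  # independent oracle: a random resistor grid solved with dense algebra
  set.seed(42)
  nx <- 4; ny <- 4
  id <- function(i, j) i + (j - 1) * nx
  edges <- NULL
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (i < nx) edges <- rbind(edges, c(id(i, j), id(i + 1, j)))
    if (j < ny) edges <- rbind(edges, c(id(i, j), id(i, j + 1)))
  }
  g <- runif(nrow(edges), 0.2, 2)
  n <- nx * ny
  Lap <- matrix(0, n, n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    Lap[i, i] <- Lap[i, i] + g[e]; Lap[j, j] <- Lap[j, j] + g[e]
    Lap[i, j] <- Lap[i, j] - g[e]; Lap[j, i] <- Lap[j, i] - g[e]
  }
  ground <- id(1, 1)
  keep <- setdiff(seq_len(n), ground)
  Zfull <- solve(Lap[keep, keep])
  terms <- match(c(id(4, 4), id(2, 3), id(4, 1)), keep)
  Z <- Zfull[terms, terms]
  expect_true(all(abs(Z - t(Z)) < 1e-12))
  for (j in seq_along(terms)) {
    expect_true(all(Z[, j] > 0))
    expect_true(all(Z[j, j] >= Z[, j]))
  }
})

test_that("current is conserved and the maximum principle holds", {
  mesh <- small_cochlea_mesh()
  cond <- conductivity_table()
  src <- source_spec("CONTACT_E1")
  f <- solve_potential(mesh, cond, src, patch_opts())
  expect_equal(ground_current(mesh, cond, f, src, patch_opts()),
               src$injected_current_A,
               tolerance = 0.005 * src$injected_current_A)
  expect_gte(min(f$values_V), 0)
  expect_lte(max(f$values_V),
             max(f$contact_potentials_V, na.rm = TRUE) * (1 + 1e-9))
})

test_that("conjugate gradients agrees with the direct solver", {
  mesh <- generate_mesh(toy_with_array(), coarse_opts())
  cond <- conductivity_table()
  src <- source_spec("CONTACT_E2", 1e-4)
  f1 <- solve_potential(mesh, cond, src)
  f2 <- solve_potential(mesh, cond, src, solver_options(method = "cg"))
  expect_lt(max(abs(f1$values_V - f2$values_V)) / max(abs(f1$values_V)), 1e-7)
  expect_gt(f2$solve_stats$iterations, 0)
  expect_lte(f2$solve_stats$residual, 1e-10)
})

test_that("uniform-current-density contacts agree with equipotential contacts", {
  mesh <- small_cochlea_mesh()
  cond <- conductivity_table()
  src <- source_spec("CONTACT_E2")
  Z_eq <- compute_impedance(solve_potential(mesh, cond, src, patch_opts()),
                            "CONTACT_E2", src)$Z_ohm
  opts_uc <- solver_options(contact_mode = "uniform_current",
                            ground_mode = "patch")
  Z_uc <- compute_impedance(solve_potential(mesh, cond, src, opts_uc),
                            "CONTACT_E2", src)$Z_ohm
  expect_lt(abs(Z_uc - Z_eq) / Z_eq, 0.04)
})

test_that("scaling all lengths by L scales every impedance by 1/L", {
  sc <- 2
  scale_params <- function(s) cochlea_params(
    base_radius_m = 2.6e-3 * s, apex_radius_m = 1.0e-3 * s,
    axial_pitch_m = 2.1e-3 * s,
    st_semi_axes_base_m = c(1.0e-3, 0.8e-3) * s,
    st_semi_axes_apex_m = c(0.5e-3, 0.4e-3) * s,
    wall_thickness_m = 1e-4 * s, membrane_thickness_m = 5e-5 * s,
    ligament_thickness_m = 1.5e-4 * s, bone_margin_m = 3e-4 * s,
    stria_thickness_m = 3e-5 * s)
  scale_array <- function(s) electrode_array_spec(
    n_contacts = 4L, contact_length_m = 3e-4 * s, contact_width_m = 4e-4 * s,
    pitch_m = 8.5e-4 * s, carrier_semi_axes_m = c(3e-4, 3e-4) * s,
    tip_clearance_m = 5e-4 * s)
  src <- source_spec("CONTACT_E2")
  Zs <- vapply(c(1, sc), function(s) {
    geom <- build_cochlea_geometry(scale_params(s), scale_array(s),
                                   placement(0, 0, 4))
    mesh <- generate_mesh(geom, mesh_options(3e-4 * s, 1.2e-3 * s))
    cond <- conductivity_table(stria_thickness_m = 3e-5 * s)
    opts <- solver_options(ground_mode = "patch",
                           ground_patch_length_m = 2e-3 * s)
    compute_impedance(solve_potential(mesh, cond, src, opts),
                      "CONTACT_E2", src)$Z_ohm
  }, numeric(1))
  expect_equal(Zs[2] * sc, Zs[1], tolerance = 1e-6)
})

test_that("missing ground and missing conductivities are explicit errors", {
  mesh <- small_cochlea_mesh()
  expect_error(solve_potential(mesh, conductivity_table(),
                               source_spec("CONTACT_E1", ground = "NOWHERE")),
               "singular")
  cond_bad <- conductivity_table()
  cond_bad$sigma_S_per_m <- cond_bad$sigma_S_per_m[
    setdiff(names(cond_bad$sigma_S_per_m), "bone")]
  expect_error(solve_potential(mesh, cond_bad, source_spec("CONTACT_E1")),
               "bone")
})
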