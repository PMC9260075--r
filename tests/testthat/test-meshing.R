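# Meshing: label conservation, refinement, volume oracles, determinism,
# quality reporting.

test_that("mesh region labels equal the geometry's labelled solids", {
  toy <- make_toy_channel(4e-3, c(1e-3, 8e-4), c(8e-4, 6e-4), 4e-4)
  mesh <- generate_mesh(toy, coarse_opts())
  expect_setequal(mesh$region_labels, toy$solids)
  mesh2 <- small_cochlea_mesh()
  expect_setequal(mesh2$region_labels,
                  c("scala_tympani", "cochlea_wall", "basilar_membrane",
                    "spiral_ligament", "bone", "carrier"))
  expect_setequal(mesh2$contact_labels, paste0("CONTACT_E", 1:4))
})

test_that("halving target sizes strictly increases the element count", {
  toy <- make_toy_channel(4e-3, c(1e-3, 8e-4), c(8e-4, 6e-4), 4e-4)
  n1 <- nrow(generate_mesh(toy, mesh_options(3e-4, 1.2e-3))$tets)
  n2 <- nrow(generate_mesh(toy, mesh_options(1.5e-4, 6e-4))$tets)
  expect_gt(n2, n1)
})

test_that("uniform channel volume matches pi a b L to machine precision", {
  a <- 1e-3; b <- 8e-4; L <- 5e-3
  toy <- make_toy_channel(L, c(a, b), c(a, b), 4e-4)
  v <- mesh_region_volumes(generate_mesh(toy, coarse_opts()))
  expect_lt(abs(v[["scala_tympani"]] - pi * a * b * L) / (pi * a * b * L),
            1e-12)
})

test_that("tapered channel volume matches the quadrature oracle", {
  a0 <- 1e-3; b0 <- 8e-4; a1 <- 5e-4; b1 <- 4e-4; L <- 5e-3
  toy <- make_toy_channel(L, c(a0, b0), c(a1, b1), 4e-4)
  oracle <- stats::integrate(function(s) {
    pi * (a0 + (a1 - a0) * s / L) * (b0 + (b1 - b0) * s / L)
  }, 0, L, rel.tol = 1e-12)$value
  v_coarse <- mesh_region_volumes(generate_mesh(toy, coarse_opts()))
  expect_lt(abs(v_coarse[["scala_tympani"]] - oracle) / oracle, 0.02)
  v_fine <- mesh_region_volumes(generate_mesh(toy, mesh_options(1.5e-4, 6e-4)))
  expect_lt(abs(v_fine[["scala_tympani"]] - oracle) / oracle, 0.002)
  # with the area-corrected rings the mesher is in fact quadrature-exact
  expect_lt(abs(v_fine[["scala_tympani"]] - oracle) / oracle, 1e-6)
})

test_that("per-region volumes sum to the total meshed volume", {
  mesh <- small_cochlea_mesh()
  v <- mesh_region_volumes(mesh)
  total <- sum(abs(cochleaVC:::tet_signed_volumes(mesh$nodes, mesh$tets)))
  expect_lt(abs(sum(v) - total) / total, 1e-10)
})

test_that("scaling all lengths by L scales volumes by L^3", {
  sc <- 2.5
  toy1 <- make_toy_channel(4e-3, c(1e-3, 8e-4), c(6e-4, 5e-4), 4e-4)
  toy2 <- make_toy_channel(4e-3 * sc, c(1e-3, 8e-4) * sc, c(6e-4, 5e-4) * sc,
                           4e-4 * sc)
  v1 <- mesh_region_volumes(generate_mesh(toy1, coarse_opts()))
  v2 <- mesh_region_volumes(generate_mesh(toy2,
                                          mesh_options(3e-4 * sc, 1.2e-3 * sc)))
  expect_equal(unname(v2 / v1), rep(sc^3, length(v1)), tolerance = 1e-10)
})

test_that("meshing is deterministic and labels are unique per boundary face", {
  geom <- build_cochlea_geometry(cochlea_params(), small_array(),
                                 placement(5e-5, -5e-5, 3),
                                 centerline = default_centerline())
  m1 <- generate_mesh(geom, coarse_opts())
  m2 <- generate_mesh(geom, coarse_opts())
  expect_identical(serialize(m1, NULL, version = 2),
                   serialize(m2, NULL, version = 2))
  key <- apply(m1$btris, 1, function(r) paste(sort(r), collapse = "/"))
  expect_false(any(tapply(m1$blabel, key, function(l) length(unique(l)) > 1)))
})

test_that("quality report: canonical element, thresholds, boundary areas", {
  # single regular tetrahedron has radius ratio exactly 1
  nodes <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  mesh1 <- cochleaVC:::new_labeled_mesh(
    nodes, matrix(1:4, 1), 1L, "medium",
    matrix(c(1L, 2L, 3L), 1), 1L, "GROUND_OUTER")
  rep1 <- mesh_quality_report(mesh1)
  expect_equal(unname(rep1$quality["min"]), 1, tolerance = 1e-12)
  expect_equal(rep1$n_flagged, 0L)
  # flagged-list semantics on a stretched tet
  nodes2 <- nodes; nodes2[, 3] <- nodes2[, 3] * 100
  mesh2 <- cochleaVC:::new_labeled_mesh(
    nodes2, matrix(1:4, 1), 1L, "medium",
    matrix(c(1L, 2L, 3L), 1), 1L, "GROUND_OUTER")
  rep2 <- mesh_quality_report(mesh2, floor = 0.5)
  expect_gt(rep2$n_flagged, 0L)
  # contact patch areas on a straight carrier match length x width closely
  mesh3 <- generate_mesh(toy_with_array(), coarse_opts())
  nominal <- small_array()$contact_length_m * small_array()$contact_width_m
  areas <- vapply(mesh3$contact_labels, function(l) boundary_area(mesh3, l),
                  numeric(1))
  expect_true(all(abs(areas / nominal - 1) < 0.05))
  # on the spiral the contacts face the concave side, so their swept area is
  # genuinely smaller than length x width by roughly carrier-radius/spiral-radius
  mesh4 <- small_cochlea_mesh()
  areas4 <- vapply(mesh4$contact_labels, function(l) boundary_area(mesh4, l),
                   numeric(1))
  expect_true(all(areas4 / nominal > 0.8 & areas4 / nominal < 1.02))
})

test_that("second-order elements are rejected explicitly", {
  expect_error(mesh_options(element_order = 2), "linear tetrahedra")
})
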