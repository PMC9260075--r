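# Geometry model: labelled solids, placement validity, clearance oracle,
# toy channel construction.

test_that("default full-insertion model carries all labelled tissue regions", {
  geom <- build_cochlea_geometry(cochlea_params(), electrode_array_spec(),
                                 placement(0, 0, 16),
                                 centerline = default_centerline())
  expect_setequal(geom$solids,
                  c("scala_tympani", "cochlea_wall", "basilar_membrane",
                    "spiral_ligament", "bone", "carrier"))
  expect_setequal(geom$interfaces,
                  c("GROUND_OUTER", "INSULATED_MEMBRANE", "STRIA_INTERFACE"))
  expect_equal(nrow(geom$contact_spans), 16L)
  expect_gt(geom$clearance_m, 0)
})

test_that("insertion step controls which contacts lie inside the scala", {
  arr <- electrode_array_spec()
  for (k in c(1L, 7L, 16L)) {
    geom <- build_cochlea_geometry(cochlea_params(), arr, placement(0, 0, k),
                                   centerline = default_centerline())
    expect_identical(rownames(geom$contact_spans), paste0("E", seq_len(k)))
    expect_true(all(geom$contact_spans > 0 & geom$contact_spans < geom$s_tip))
  }
})

test_that("offsets beyond the lumen raise placement_invalid", {
  p <- cochlea_params()
  arr <- electrode_array_spec()
  expect_error(
    build_cochlea_geometry(p, arr, placement(p$st_semi_axes_apex_m[1], 0, 16),
                           centerline = default_centerline()),
    class = "placement_invalid")
  expect_error(
    build_cochlea_geometry(p, arr, placement(0, -5e-4, 16),
                           centerline = default_centerline()),
    class = "placement_invalid")
})

test_that("zero-offset clearance equals the analytic semi-axis difference", {
  # circular cross-sections make the minimum distance exactly b(s_tip) - r
  p <- cochlea_params(st_semi_axes_base_m = c(1e-3, 1e-3),
                      st_semi_axes_apex_m = c(6e-4, 6e-4))
  arr <- electrode_array_spec()
  geom <- build_cochlea_geometry(p, arr, placement(0, 0, 16))
  f <- geom$s_tip / geom$centerline$length_m
  r_tip <- 1e-3 + (6e-4 - 1e-3) * f
  expect_lt(abs(geom$clearance_m - (r_tip - arr$carrier_semi_axes_m[1])), 1e-9)
})

test_that("validity is monotone along a ray from the centreline", {
  p <- cochlea_params(); arr <- electrode_array_spec()
  cl <- default_centerline()
  offs <- seq(0, p$st_semi_axes_apex_m[2], length.out = 15)
  valid <- vapply(offs, function(o) {
    !inherits(tryCatch(
      build_cochlea_geometry(p, arr, placement(0, o, 16), centerline = cl),
      placement_invalid = function(e) e), "placement_invalid")
  }, logical(1))
  # once invalid, stays invalid further out
  expect_true(all(diff(as.integer(valid)) <= 0))
  expect_true(valid[1])
  expect_false(valid[length(valid)])
})

test_that("toy channel validates inputs and reports its regions", {
  expect_error(make_toy_channel(5e-3, c(-1e-3, 1e-3), c(1e-3, 1e-3), 1e-4),
               "positive")
  expect_error(make_toy_channel(5e-3, c(1e-3, 1e-3), c(0, 1e-3), 1e-4),
               "positive")
  toy <- make_toy_channel(5e-3, c(1e-3, 8e-4), c(5e-4, 4e-4), 3e-4)
  expect_setequal(toy$solids, c("scala_tympani", "bone"))
  toy2 <- toy_with_array()
  expect_setequal(toy2$solids, c("scala_tympani", "bone", "carrier"))
})

test_that("geometry regeneration is deterministic byte-for-byte", {
  g1 <- build_cochlea_geometry(cochlea_params(), electrode_array_spec(),
                               placement(1e-4, -5e-5, 9))
  g2 <- build_cochlea_geometry(cochlea_params(), electrode_array_spec(),
                               placement(1e-4, -5e-5, 9))
  expect_identical(serialize(g1, NULL, version = 2),
                   serialize(g2, NULL, version = 2))
})
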