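# Proximity parametrisation: candidate counts, equal spacing, validity
# flagging and symmetry.

test_that("a 12 x 12 grid yields 144 candidate placements with flags", {
  grid <- cached("grid12", make_proximity_grid(cochlea_params(),
                                               electrode_array_spec()))
  expect_length(grid$placements, 144L)
  valid <- vapply(grid$placements, function(p) isTRUE(p$valid), logical(1))
  # near-touching extremes are flagged invalid, never dropped
  expect_gt(sum(!valid), 0)
  expect_gt(sum(valid), 0)
  expect_true(all(vapply(grid$placements, function(p)
    !is.null(p$grid_index), logical(1))))
})

test_that("offsets form arithmetic sequences with one common spacing d", {
  grid <- cached("grid12", make_proximity_grid(cochlea_params(),
                                               electrode_array_spec()))
  d <- grid$spacing_m
  expect_true(all(abs(diff(grid$offsets_x_m) - d) < 1e-15))
  expect_true(all(abs(diff(grid$offsets_y_m) - d) < 1e-15))
  # centred on the lumen axis
  expect_lt(abs(mean(grid$offsets_x_m)), 1e-15)
  expect_lt(abs(mean(grid$offsets_y_m)), 1e-15)
})

test_that("validity pattern is symmetric under offset negation", {
  grid <- cached("grid12", make_proximity_grid(cochlea_params(),
                                               electrode_array_spec()))
  v <- matrix(vapply(grid$placements, function(p) isTRUE(p$valid), logical(1)),
              grid$n_x, grid$n_y)
  expect_identical(v, v[rev(seq_len(grid$n_x)), rev(seq_len(grid$n_y))])
})

test_that("grid reaches near-touching: outermost valid x sample is close to the wall", {
  grid <- cached("grid12", make_proximity_grid(cochlea_params(),
                                               electrode_array_spec()))
  mid_y <- which.min(abs(grid$offsets_y_m))
  row <- grid$placements[vapply(grid$placements, function(p)
    p$grid_index[2] == mid_y, logical(1))]
  valid <- vapply(row, function(p) isTRUE(p$valid), logical(1))
  cl_last <- min(vapply(row[valid], function(p) p$clearance_m, numeric(1)))
  cl_mid <- max(vapply(row[valid], function(p) p$clearance_m, numeric(1)))
  expect_lt(cl_last, 0.3 * cl_mid)
})

test_that("proximity rays start mid-scala and stay valid to near-touching", {
  ray <- make_proximity_ray(cochlea_params(), electrode_array_spec(),
                            axis = "x", n_positions = 6)
  offs <- vapply(ray, function(p) p$ray_offset_m, numeric(1))
  expect_equal(offs[1], 0)
  expect_true(all(diff(offs) > 0))
  # all valid by construction
  cl <- default_centerline()
  for (p in ray)
    expect_no_error(build_cochlea_geometry(cochlea_params(),
                                           electrode_array_spec(), p,
                                           centerline = cl))
})
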