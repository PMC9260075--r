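# Spiral centreline: arc length against an independent quadrature oracle,
# frame orthonormality and continuity, degenerate fallback.

test_that("arc length matches independent quadrature of the speed integrand", {
  params_list <- list(
    cochlea_params(),
    cochlea_params(n_turns = 1.75, base_radius_m = 3e-3, apex_radius_m = 1.2e-3,
                   axial_pitch_m = 2.4e-3),
    cochlea_params(n_turns = 0.5, axial_pitch_m = 4e-3))
  for (p in params_list) {
    cl <- build_centerline(p)
    # oracle: numeric quadrature of |r'(tau)| written out independently
    speed <- function(tau) {
      th <- 2 * pi * p$n_turns * tau
      R <- p$base_radius_m + (p$apex_radius_m - p$base_radius_m) * tau
      dR <- p$apex_radius_m - p$base_radius_m
      dth <- 2 * pi * p$n_turns
      dz <- p$axial_pitch_m * p$n_turns
      sqrt(dR^2 + (R * dth)^2 + dz^2)
    }
    L_oracle <- stats::integrate(speed, 0, 1, rel.tol = 1e-10)$value
    expect_lt(abs(cl$length_m - L_oracle) / L_oracle, 1e-6)
    expect_true(all(diff(cl$arclength_m) > 0))
  }
})

test_that("local frames are orthonormal and continuous along the spiral", {
  cl <- default_centerline()
  ev <- centerline_at(cl, seq(0, cl$length_m, length.out = 257))
  expect_lt(max(abs(rowSums(ev$tangent * ev$xhat))), 1e-10)
  expect_lt(max(abs(rowSums(ev$tangent * ev$yhat))), 1e-10)
  expect_lt(max(abs(rowSums(ev$xhat * ev$yhat))), 1e-10)
  expect_lt(max(abs(sqrt(rowSums(ev$xhat^2)) - 1)), 1e-10)
  expect_lt(max(abs(sqrt(rowSums(ev$yhat^2)) - 1)), 1e-10)
  # no frame flips: consecutive frame axes stay positively aligned
  n <- nrow(ev$xhat)
  expect_true(all(rowSums(ev$xhat[-1, ] * ev$xhat[-n, ]) > 0))
  expect_true(all(rowSums(ev$yhat[-1, ] * ev$yhat[-n, ]) > 0))
})

test_that("zero-turn spiral degenerates to a straight segment with constant frames", {
  p <- cochlea_params(n_turns = 0, axial_pitch_m = 1e-6)
  cl <- build_centerline(p)
  L_expected <- p$base_radius_m - p$apex_radius_m
  expect_equal(cl$length_m, L_expected, tolerance = 1e-9)
  ev <- centerline_at(cl, seq(0, cl$length_m, length.out = 33))
  expect_lt(max(apply(ev$tangent, 2, function(v) diff(range(v)))), 1e-12)
  expect_lt(max(apply(ev$xhat, 2, function(v) diff(range(v)))), 1e-12)
})

test_that("orientation convention: xhat points at the modiolar wall, yhat apically upward", {
  cl <- default_centerline()
  ev <- centerline_at(cl, cl$length_m / 2)
  # inward radial: xhat opposes the radial position of the point
  radial <- c(ev$point[1, 1:2], 0)
  expect_lt(sum(ev$xhat[1, ] * radial), 0)
  expect_gt(ev$yhat[1, 3], 0.5)
})
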