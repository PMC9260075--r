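# Shared fixtures.  Everything is generated in code; expensive objects are
# cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# coarse mesh options used throughout the unit tests
coarse_opts <- function() mesh_options(target_size_near_m = 3e-4,
                                       target_size_far_m = 1.2e-3)

# a short 4-contact array keeps cochlea solves cheap
small_array <- function() electrode_array_spec(n_contacts = 4L)

default_centerline <- function() cached("centerline",
                                        build_centerline(cochlea_params()))

# coarse fully inserted 4-contact cochlea mesh
small_cochlea_mesh <- function() cached("small_cochlea_mesh", {
  geom <- build_cochlea_geometry(cochlea_params(), small_array(),
                                 placement(0, 0, 4L),
                                 centerline = default_centerline())
  generate_mesh(geom, coarse_opts())
})

# straight two-region toy channel with a short carrier, mirror-symmetric in y
toy_with_array <- function(y_offset = 0) {
  make_toy_channel(6e-3, c(1e-3, 1e-3), c(1e-3, 1e-3), 5e-4,
                   array = small_array(),
                   placement = placement(0, y_offset, 4L))
}

patch_opts <- function() solver_options(ground_mode = "patch")
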