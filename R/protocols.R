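# Experiment drivers: sequential-insertion impedance recording, proximity
# sweeps, full-insertion depth profiles, conductivity sensitivity.  Every
# record satisfies Z = V / I exactly and carries enough keys (grid indices,
# insertion step, contact) to be reassembled order-independently.

new_impedance_map <- function(records, metadata) {
  out <- records
  attr(out, "metadata") <- metadata
  class(out) <- c("impedance_map", class(tibble::tibble()))
  out
}

#' Metadata of an impedance map
#' @param map an `impedance_map`.
#' @return The metadata list (protocol, spacing, options, skipped placements).
#' @export
map_metadata <- function(map) attr(map, "metadata")

#' Full-insertion per-contact impedance profile (depth profile)
#'
#' One geometry and one factorisation: the fully inserted array at the given
#' placement, each contact activated in turn (34 uA, others floating), giving
#' one electrode-to-ground impedance per contact from the apical E1 to the
#' basal E16.
#'
#' @param params a [cochlea_params()].
#' @param array an [electrode_array_spec()].
#' @param cond a [conductivity_table()].
#' @param pl a [placement()] (default mid-scala, full insertion).
#' @param mesh_opts a [mesh_options()].
#' @param solver_opts a [solver_options()].
#' @param I injected current (A).
#' @return An `impedance_map` tibble: contact, arc-length position of the
#'   contact centre, apical rank (1 = most apical), I, V, Z.
#' @export
run_insertion_depth_profile <- function(params, array, cond,
                                        pl = placement(0, 0, array$n_contacts),
                                        mesh_opts = mesh_options(),
                                        solver_opts = solver_options(ground_mode = "patch"),
                                        I = 34e-6) {
  geom <- build_cochlea_geometry(params, array, pl)
  mesh <- generate_mesh(geom, mesh_opts)
  Z <- transfer_impedance_matrix(mesh, cond, opts = solver_opts, I = I)
  contacts <- mesh$contact_labels
  ids <- sub("^CONTACT_", "", contacts)
  centers <- contact_centers_s(array, pl$insertion_step, geom$s_tip)
  rec <- tibble::tibble(
    contact = ids,
    s_center_m = centers[match(ids, array$contact_ids)],
    apical_rank = match(ids, array$contact_ids),
    I_A = I,
    V_V = diag(Z) * I,
    Z_ohm = diag(Z))
  new_impedance_map(rec, list(
    protocol = "insertion_depth_profile",
    placement = pl, mesh = list(n_nodes = nrow(mesh$nodes),
                                n_tets = nrow(mesh$tets)),
    mesh_opts = mesh_opts, solver_opts = solver_opts))
}

#' Sequential-insertion impedance recording
#'
#' Reproduces the sequential measurement protocol: for each insertion step
#' `k = 1..n_contacts` the geometry is rebuilt with exactly `k` contacts
#' (E1..Ek) inside the scala and the impedance to ground of every inserted
#' contact is recorded, giving `sum(k) = n (n + 1) / 2` records (136 for a
#' 16-contact array) per inactive-contact mode.  Two conventions for the
#' contacts that are inserted but not activated are reported: `"floating"`
#' (tied equipotential, zero net current) and `"grounded"` (derived exactly
#' from the floating transfer-impedance matrix as `1 / (Z^-1)[j, j]`).
#'
#' @inheritParams run_insertion_depth_profile
#' @param placement_offsets in-plane offsets `c(x, y)` (m) applied at every
#'   step.
#' @param modes subset of `c("floating", "grounded")`.
#' @return An `impedance_map` tibble with columns step_k, contact, mode,
#'   I_A, V_V, Z_ohm.
#' @export
run_sequential_insertion <- function(params, array, cond,
                                     placement_offsets = c(0, 0),
                                     modes = c("floating", "grounded"),
                                     mesh_opts = mesh_options(),
                                     solver_opts = solver_options(ground_mode = "patch"),
                                     I = 34e-6) {
  modes <- match.arg(modes, several.ok = TRUE)
  cl <- build_centerline(params)
  rows <- list()
  for (k in seq_len(array$n_contacts)) {
    pl <- placement(placement_offsets[1], placement_offsets[2], k)
    geom <- tryCatch(
      build_cochlea_geometry(params, array, pl, centerline = cl),
      placement_invalid = function(e)
        stop(sprintf("placement invalid at insertion step %d: %s",
                     k, conditionMessage(e)), call. = FALSE))
    mesh <- generate_mesh(geom, mesh_opts)
    Z <- transfer_impedance_matrix(mesh, cond, opts = solver_opts, I = I)
    ids <- sub("^CONTACT_", "", rownames(Z))
    if ("floating" %in% modes) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        step_k = k, contact = ids, mode = "floating",
        I_A = I, V_V = diag(Z) * I, Z_ohm = diag(Z))
    }
    if ("grounded" %in% modes) {
      Zg <- 1 / diag(solve(Z))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        step_k = k, contact = ids, mode = "grounded",
        I_A = I, V_V = Zg * I, Z_ohm = Zg)
    }
  }
  rec <- do.call(rbind, rows)
  new_impedance_map(rec, list(
    protocol = "sequential_insertion",
    placement_offsets = placement_offsets,
    n_records_per_mode = array$n_contacts * (array$n_contacts + 1) / 2,
    modes = modes, mesh_opts = mesh_opts, solver_opts = solver_opts))
}

#' Proximity sweep over placements
#'
#' One solve set per valid placement; impedance recorded for the requested
#' contacts only.  Invalid placements (carrier touching or crossing the scala
#' boundary) are skipped and logged in the metadata, never recorded.
#'
#' @inheritParams run_insertion_depth_profile
#' @param placements a [make_proximity_grid()] result, or a list of
#'   [placement()] objects (e.g. from [make_proximity_ray()]).
#' @param recorded_contacts contact ids to record (default the four contacts
#'   conventionally reported for the sweep towards the basilar membrane).
#' @return An `impedance_map` tibble with columns grid_i, grid_j,
#'   x_offset_m, y_offset_m, contact, I_A, V_V, Z_ohm.
#' @export
run_proximity_sweep <- function(params, array, cond, placements,
                                recorded_contacts = c("E1", "E6", "E11", "E16"),
                                mesh_opts = mesh_options(),
                                solver_opts = solver_options(ground_mode = "patch"),
                                I = 34e-6) {
  pls <- if (inherits(placements, "proximity_grid")) placements$placements
         else placements
  cl <- build_centerline(params)
  labs <- paste0("CONTACT_", recorded_contacts)
  rows <- list(); skipped <- list()
  for (pl in pls) {
    if (!is.null(pl$valid) && !pl$valid) {
      skipped[[length(skipped) + 1L]] <- pl
      next
    }
    geom <- tryCatch(
      build_cochlea_geometry(params, array, pl, centerline = cl),
      placement_invalid = function(e) e)
    if (inherits(geom, "placement_invalid")) {
      skipped[[length(skipped) + 1L]] <- pl
      next
    }
    if (any(!recorded_contacts %in% array$contact_ids[seq_len(pl$insertion_step)]))
      stop("recorded_contacts must all be inserted", call. = FALSE)
    mesh <- generate_mesh(geom, mesh_opts)
    Z <- transfer_impedance_matrix(mesh, cond, contacts = labs,
                                   opts = solver_opts, I = I)
    gi <- if (is.null(pl$grid_index)) c(NA_integer_, NA_integer_) else pl$grid_index
    rows[[length(rows) + 1L]] <- tibble::tibble(
      grid_i = gi[1], grid_j = gi[2],
      x_offset_m = pl$x_offset_m, y_offset_m = pl$y_offset_m,
      contact = recorded_contacts,
      I_A = I, V_V = diag(Z) * I, Z_ohm = diag(Z))
  }
  rec <- if (length(rows)) do.call(rbind, rows) else tibble::tibble(
    grid_i = integer(), grid_j = integer(), x_offset_m = numeric(),
    y_offset_m = numeric(), contact = character(), I_A = numeric(),
    V_V = numeric(), Z_ohm = numeric())
  new_impedance_map(rec, list(
    protocol = "proximity_sweep",
    spacing_m = if (inherits(placements, "proximity_grid"))
      placements$spacing_m else NA_real_,
    n_candidates = length(pls),
    n_skipped = length(skipped),
    skipped = skipped,
    recorded_contacts = recorded_contacts,
    mesh_opts = mesh_opts, solver_opts = solver_opts))
}

#' Conductivity-sensitivity analysis
#'
#' Recomputes an impedance-vs-position profile with the conductivity of one
#' tissue layer scaled in steps (default +/-5% up to +/-10% around the table
#' value), then measures how much the profile *shape* changes: each profile
#' is normalised by its own mid-scala value and the maximum relative
#' deviation from the baseline normalised profile is reported.  The absolute
#' impedance shift is reported alongside.
#'
#' @inheritParams run_insertion_depth_profile
#' @param layer tissue layer to perturb.
#' @param factors conductivity scale factors; must include 1.
#' @param axis,n_positions,frac_max sweep definition passed to
#'   [make_proximity_ray()]; position 1 is mid-scala.
#' @param recorded_contact contact whose impedance defines the profile.
#' @return An object of class `sensitivity_result`: `profiles` (tibble:
#'   factor, position, offset_m, Z_ohm, Z_normalized),
#'   `normalized_deviation` (max relative change of the normalised profile,
#'   as a fraction), `max_absolute_shift` (max relative change of Z itself)
#'   and the sweep definition.
#' @export
run_conductivity_sensitivity <- function(params, array, cond,
                                         layer = "scala_tympani",
                                         factors = c(0.90, 0.95, 1.00, 1.05, 1.10),
                                         axis = "x", n_positions = 8L,
                                         frac_max = 0.95,
                                         recorded_contact = "E16",
                                         mesh_opts = mesh_options(),
                                         solver_opts = solver_options(ground_mode = "patch"),
                                         I = 34e-6) {
  if (!any(abs(factors - 1) < 1e-12))
    stop("factors must include the baseline 1.0", call. = FALSE)
  if (!identical(layer, "all") && !layer %in% names(cond$sigma_S_per_m))
    stop("unknown layer '", layer, "'", call. = FALSE)
  rays <- make_proximity_ray(params, array, axis = axis,
                             n_positions = n_positions, frac_max = frac_max)
  lab <- paste0("CONTACT_", recorded_contact)
  cl <- build_centerline(params)
  Zmat <- matrix(NA_real_, length(factors), length(rays))
  offsets <- vapply(rays, function(p) p$ray_offset_m, numeric(1))
  for (ip in seq_along(rays)) {
    geom <- build_cochlea_geometry(params, array, rays[[ip]], centerline = cl)
    mesh <- generate_mesh(geom, mesh_opts)
    asm <- fem_assembly(mesh)
    src <- source_spec(lab, I)
    for (jf in seq_along(factors)) {
      cond_f <- perturb_conductivity(cond, layer, factors[jf])
      sys <- fem_system(mesh, cond_f, src, solver_opts, asm = asm)
      b <- numeric(sys$red$n_red)
      b[sys$red$term_dof[lab]] <- I
      sol <- fem_solve_rhs(sys, b)
      Zmat[jf, ip] <- sol$x[sys$red$term_dof[lab]] / I
    }
  }
  base <- which(abs(factors - 1) < 1e-12)[1]
  Nmat <- Zmat / Zmat[, 1]  # normalise each profile by its mid-scala value
  dev <- abs(sweep(Nmat, 2, Nmat[base, ], "/") - 1)
  abs_shift <- abs(Zmat / rep(Zmat[base, ], each = nrow(Zmat)) - 1)
  profiles <- tibble::tibble(
    factor = rep(factors, times = length(rays)),
    position = rep(seq_along(rays), each = length(factors)),
    offset_m = rep(offsets, each = length(factors)),
    Z_ohm = as.vector(Zmat),
    Z_normalized = as.vector(Nmat))
  structure(list(
    layer = layer,
    factors = factors,
    offsets_m = offsets,
    recorded_contact = recorded_contact,
    axis = axis,
    profiles = profiles,
    normalized_deviation = max(dev),
    max_absolute_shift = max(abs_shift),
    metadata = list(mesh_opts = mesh_opts, solver_opts = solver_opts, I = I)
  ), class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> layer %s, factors %s\n", x$layer,
              paste(x$factors, collapse = ", ")))
  cat(sprintf("  profile (%s-axis, contact %s, %d positions)\n",
              x$axis, x$recorded_contact, length(x$offsets_m)))
  cat(sprintf("  max normalised-profile deviation: %.4g%%\n",
              100 * x$normalized_deviation))
  cat(sprintf("  max absolute impedance shift:     %.4g%%\n",
              100 * x$max_absolute_shift))
  invisible(x)
}

#' @export
print.impedance_map <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("<impedance_map> %s: %d records\n",
              if (!is.null(md$protocol)) md$protocol else "?", nrow(x)))
  NextMethod()
}
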