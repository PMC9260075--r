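#' Parametric description of the geometric cochlea
#'
#' Defines the spiral scala tympani and its surrounding tissue layers.  The
#' lumen is an elliptical tube swept along a conical helix: its centreline
#' radius interpolates linearly from `base_radius_m` to `apex_radius_m` over
#' `n_turns` turns while rising `axial_pitch_m` per turn, and the elliptical
#' cross-section tapers linearly (in arc length) from the basal to the apical
#' semi-axes.  The lumen is wrapped by a cochlea-wall layer (replaced by a
#' basilar-membrane layer on the scala-media side and a spiral-ligament layer
#' on the lateral side) and by a bone sheath of thickness `bone_margin_m`
#' whose outer surface is the model ground.
#'
#' No published figure fixes these dimensions numerically; the defaults are
#' literature-typical human values (about 2.5 turns, basal lumen semi-axes
#' 1.0 x 0.8 mm tapering to 0.5 x 0.4 mm) and every length is configurable,
#' so absolute impedances are configuration-dependent by design.
#'
#' @param n_turns number of spiral turns (dimensionless, >= 0).
#' @param base_radius_m,apex_radius_m centreline spiral radius at base/apex (m);
#'   the apex radius must be smaller.
#' @param axial_pitch_m axial rise of the centreline per turn (m).
#' @param st_semi_axes_base_m,st_semi_axes_apex_m length-2 vectors `(a, b)`:
#'   scala tympani elliptical cross-section semi-axes at base and apex (m),
#'   linearly tapered along arc length.  `a` is the in-plane axis pointing at
#'   the modiolar wall, `b` the axis pointing at the basilar membrane.
#' @param wall_thickness_m cochlea-wall layer thickness (m).
#' @param membrane_thickness_m basilar-membrane layer thickness (m).
#' @param ligament_thickness_m spiral-ligament layer thickness (m).
#' @param bone_margin_m thickness of the enclosing bone sheath (m); its outer
#'   surface carries the Dirichlet ground.
#' @param stria_thickness_m thickness of the stria vascularis thin layer used
#'   by the contact-impedance interface condition (m).  The stria is never
#'   meshed volumetrically.
#'
#' @return An object of class `cochlea_params`.
#' @export
#' @examples
#' p <- cochlea_params()
#' p$n_turns
cochlea_params <- function(n_turns = 2.5,
                           base_radius_m = 2.6e-3,
                           apex_radius_m = 1.0e-3,
                           axial_pitch_m = 2.1e-3,
                           st_semi_axes_base_m = c(1.0e-3, 0.8e-3),
                           st_semi_axes_apex_m = c(0.5e-3, 0.4e-3),
                           wall_thickness_m = 1.0e-4,
                           membrane_thickness_m = 5.0e-5,
                           ligament_thickness_m = 1.5e-4,
                           bone_margin_m = 3.0e-4,
                           stria_thickness_m = 3.0e-5) {
  stopifnot(length(st_semi_axes_base_m) == 2, length(st_semi_axes_apex_m) == 2)
  lens <- c(base_radius_m, apex_radius_m, st_semi_axes_base_m,
            st_semi_axes_apex_m, wall_thickness_m, membrane_thickness_m,
            ligament_thickness_m, bone_margin_m, stria_thickness_m)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all length parameters must be positive and finite", call. = FALSE)
  if (!is.finite(n_turns) || n_turns < 0)
    stop("n_turns must be >= 0", call. = FALSE)
  if (!is.finite(axial_pitch_m) || axial_pitch_m < 0)
    stop("axial_pitch_m must be >= 0", call. = FALSE)
  if (apex_radius_m >= base_radius_m)
    stop("apex_radius_m must be smaller than base_radius_m", call. = FALSE)
  if (any(st_semi_axes_apex_m > st_semi_axes_base_m))
    stop("apex semi-axes must not exceed base semi-axes (taper towards apex)",
         call. = FALSE)
  structure(list(
    n_turns = n_turns,
    base_radius_m = base_radius_m,
    apex_radius_m = apex_radius_m,
    axial_pitch_m = axial_pitch_m,
    st_semi_axes_base_m = as.numeric(st_semi_axes_base_m),
    st_semi_axes_apex_m = as.numeric(st_semi_axes_apex_m),
    wall_thickness_m = wall_thickness_m,
    membrane_thickness_m = membrane_thickness_m,
    ligament_thickness_m = ligament_thickness_m,
    bone_margin_m = bone_margin_m,
    stria_thickness_m = stria_thickness_m
  ), class = "cochlea_params")
}

#' Electrode-array specification
#'
#' A silicone carrier of elliptical cross-section holding `n_contacts`
#' rectangular platinum contact patches on the surface facing the modiolar
#' (inner) cochlea wall.  Contacts are labelled `E1` at the apical end through
#' `E<n>` at the basal end.  Contact plates are thin and are modelled as
#' boundary surface patches on the carrier, not as solids.
#'
#' @param n_contacts number of contacts (default 16).
#' @param contact_length_m contact patch extent along the carrier (m).
#' @param contact_width_m contact patch extent around the carrier (m).
#' @param pitch_m centre-to-centre contact spacing along the carrier (m);
#'   must exceed `contact_length_m`.
#' @param carrier_semi_axes_m length-2 vector: silicone carrier cross-section
#'   semi-axes (m).
#' @param silicone_sigma_S_per_m carrier conductivity (S/m).
#' @param tip_clearance_m carrier length apical of the centre of the most
#'   apical contact (m).
#'
#' @return An object of class `electrode_array`.
#' @export
electrode_array_spec <- function(n_contacts = 16L,
                                 contact_length_m = 3.0e-4,
                                 contact_width_m = 4.0e-4,
                                 pitch_m = 8.5e-4,
                                 carrier_semi_axes_m = c(3.0e-4, 3.0e-4),
                                 silicone_sigma_S_per_m = 1e-7,
                                 tip_clearance_m = 5.0e-4) {
  n_contacts <- as.integer(n_contacts)
  if (is.na(n_contacts) || n_contacts < 1L)
    stop("n_contacts must be >= 1", call. = FALSE)
  stopifnot(length(carrier_semi_axes_m) == 2)
  lens <- c(contact_length_m, contact_width_m, pitch_m, carrier_semi_axes_m,
            tip_clearance_m)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all array dimensions must be positive and finite", call. = FALSE)
  if (pitch_m <= contact_length_m)
    stop("pitch_m must exceed contact_length_m", call. = FALSE)
  if (!is.finite(silicone_sigma_S_per_m) || silicone_sigma_S_per_m <= 0)
    stop("silicone_sigma_S_per_m must be positive", call. = FALSE)
  structure(list(
    n_contacts = n_contacts,
    contact_ids = paste0("E", seq_len(n_contacts)),
    contact_length_m = contact_length_m,
    contact_width_m = contact_width_m,
    pitch_m = pitch_m,
    carrier_semi_axes_m = as.numeric(carrier_semi_axes_m),
    silicone_sigma_S_per_m = silicone_sigma_S_per_m,
    tip_clearance_m = tip_clearance_m
  ), class = "electrode_array")
}

#' Electrode-array placement in the scala tympani
#'
#' In-plane displacement of the carrier axis from the scala centreline,
#' expressed in the local cross-section frame: `x_offset_m` along the axis
#' pointing at the modiolar (inner) cochlea wall, `y_offset_m` along the axis
#' pointing at the basilar-membrane side.  `insertion_step = k` means contacts
#' `E1..Ek` lie inside the scala (k = n_contacts is full insertion).
#'
#' @param x_offset_m,y_offset_m in-plane offsets (m).
#' @param insertion_step integer in `1..n_contacts`.
#' @param grid_index optional integer pair `(i, j)` locating the placement on
#'   a proximity grid.
#'
#' @return An object of class `placement`.
#' @export
placement <- function(x_offset_m = 0, y_offset_m = 0,
                      insertion_step = 16L, grid_index = NULL) {
  if (!is.finite(x_offset_m) || !is.finite(y_offset_m))
    stop("offsets must be finite", call. = FALSE)
  insertion_step <- as.integer(insertion_step)
  if (is.na(insertion_step) || insertion_step < 1L)
    stop("insertion_step must be a positive integer", call. = FALSE)
  if (!is.null(grid_index)) {
    grid_index <- as.integer(grid_index)
    stopifnot(length(grid_index) == 2)
  }
  structure(list(
    x_offset_m = x_offset_m,
    y_offset_m = y_offset_m,
    insertion_step = insertion_step,
    grid_index = grid_index
  ), class = "placement")
}

#' @export
print.cochlea_params <- function(x, ...) {
  cat("<cochlea_params>\n")
  cat(sprintf("  turns: %.3g, radius %.3g -> %.3g mm, pitch %.3g mm/turn\n",
              x$n_turns, x$base_radius_m * 1e3, x$apex_radius_m * 1e3,
              x$axial_pitch_m * 1e3))
  cat(sprintf("  lumen semi-axes: %.3g x %.3g -> %.3g x %.3g mm\n",
              x$st_semi_axes_base_m[1] * 1e3, x$st_semi_axes_base_m[2] * 1e3,
              x$st_semi_axes_apex_m[1] * 1e3, x$st_semi_axes_apex_m[2] * 1e3))
  cat(sprintf("  layers (mm): wall %.3g, membrane %.3g, ligament %.3g, bone %.3g\n",
              x$wall_thickness_m * 1e3, x$membrane_thickness_m * 1e3,
              x$ligament_thickness_m * 1e3, x$bone_margin_m * 1e3))
  invisible(x)
}

#' @export
print.electrode_array <- function(x, ...) {
  cat("<electrode_array>\n")
  cat(sprintf("  %d contacts (%s apical .. %s basal), pitch %.3g mm\n",
              x$n_contacts, x$contact_ids[1], x$contact_ids[x$n_contacts],
              x$pitch_m * 1e3))
  cat(sprintf("  carrier semi-axes %.3g x %.3g mm, silicone sigma %.3g S/m\n",
              x$carrier_semi_axes_m[1] * 1e3, x$carrier_semi_axes_m[2] * 1e3,
              x$silicone_sigma_S_per_m))
  invisible(x)
}

#' @export
print.placement <- function(x, ...) {
  cat(sprintf("<placement> offset (%.3g, %.3g) mm, insertion step %d%s\n",
              x$x_offset_m * 1e3, x$y_offset_m * 1e3, x$insertion_step,
              if (is.null(x$grid_index)) "" else
                sprintf(", grid (%d, %d)", x$grid_index[1], x$grid_index[2])))
  invisible(x)
}
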