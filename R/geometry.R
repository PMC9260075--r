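# Cross-section conventions (local frame at arc length s):
#   +x : towards the inner (modiolar) cochlea wall
#   +y : towards the basilar-membrane side
# The lumen ellipse is centred on the centreline; the carrier ellipse is
# centred at the placement offset.  Angular sectors of the layer wrapped
# around the lumen:
#   basilar membrane : theta in [45, 135] degrees (top)
#   spiral ligament  : theta in [150, 210] degrees (lateral wall)
#   cochlea wall     : elsewhere
SECTOR_MEMBRANE <- c(pi / 4, 3 * pi / 4)
SECTOR_LIGAMENT <- c(5 * pi / 6, 7 * pi / 6)
SECTOR_BLEND <- pi / 36  # 5 degree thickness blend at sector edges

# ---------------------------------------------------------------------------
# ellipse utilities

# signed distance from points (px, py) to the ellipse x^2/A^2 + y^2/B^2 = 1;
# positive inside, negative outside.  Vectorised golden-section search on the
# boundary parameter within the point's quadrant.
point_ellipse_distance <- function(px, py, A, B, iter = 72L) {
  qx <- abs(px); qy <- abs(py)
  lo <- rep(0, length(qx)); hi <- rep(pi / 2, length(qx))
  gr <- (sqrt(5) - 1) / 2
  f <- function(t) (A * cos(t) - qx)^2 + (B * sin(t) - qy)^2
  t1 <- hi - gr * (hi - lo); t2 <- lo + gr * (hi - lo)
  f1 <- f(t1); f2 <- f(t2)
  for (i in seq_len(iter)) {
    sel <- f1 > f2
    lo <- ifelse(sel, t1, lo)
    hi <- ifelse(sel, hi, t2)
    t1 <- ifelse(sel, t2, hi - gr * (hi - lo))
    t2 <- ifelse(sel, lo + gr * (hi - lo), t1)
    fn1 <- ifelse(sel, f2, f(t1))
    fn2 <- ifelse(sel, f(t2), f1)
    f1 <- fn1; f2 <- fn2
  }
  d <- sqrt(pmin(f1, f2))
  inside <- (qx / A)^2 + (qy / B)^2 <= 1
  ifelse(inside, d, -d)
}

# minimum signed clearance between a carrier ellipse (centre cx, cy, semi-axes
# ua, ub) and the containing lumen ellipse (semi-axes a, b); vectorised over
# cross-sections (all arguments recycled to common length).
section_clearance <- function(cx, cy, ua, ub, a, b, n_phi = 64L) {
  n <- max(lengths(list(cx, cy, ua, ub, a, b)))
  cx <- rep_len(cx, n); cy <- rep_len(cy, n)
  ua <- rep_len(ua, n); ub <- rep_len(ub, n)
  a <- rep_len(a, n); b <- rep_len(b, n)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  # one vectorised distance pass over the full (section x phi) grid
  px <- rep(cx, each = n_phi) + rep(ua, each = n_phi) * cos(phi)
  py <- rep(cy, each = n_phi) + rep(ub, each = n_phi) * sin(phi)
  d <- point_ellipse_distance(px, py, rep(a, each = n_phi),
                              rep(b, each = n_phi))
  apply(matrix(d, n_phi, n), 2L, min)
}

# ---------------------------------------------------------------------------
# cross-section profiles

# lumen semi-axes at arc length s (linear taper base -> apex over [0, L])
lumen_semi_axes <- function(params, s, L) {
  f <- s / L
  list(a = params$st_semi_axes_base_m[1] +
         (params$st_semi_axes_apex_m[1] - params$st_semi_axes_base_m[1]) * f,
       b = params$st_semi_axes_base_m[2] +
         (params$st_semi_axes_apex_m[2] - params$st_semi_axes_base_m[2]) * f)
}

# smooth indicator of theta in [lo, hi] with cosine ramps of half-width blend
sector_weight <- function(theta, lo, hi, blend = SECTOR_BLEND) {
  th <- theta %% (2 * pi)
  ramp <- function(x) ifelse(x <= -1, 0, ifelse(x >= 1, 1,
                                                0.5 * (1 + sin(pi * x / 2))))
  ramp((th - lo) / blend) * ramp((hi - th) / blend)
}

# thickness of the layer wrapped around the lumen, as a function of the
# cross-section angle (smoothly blended between wall / membrane / ligament)
layer_thickness <- function(params, theta) {
  wm <- sector_weight(theta, SECTOR_MEMBRANE[1], SECTOR_MEMBRANE[2])
  wl <- sector_weight(theta, SECTOR_LIGAMENT[1], SECTOR_LIGAMENT[2])
  params$wall_thickness_m * (1 - wm - wl) +
    params$membrane_thickness_m * wm +
    params$ligament_thickness_m * wl
}

# crisp sector label for a wall-layer element at mid angle theta
wall_sector_label <- function(theta) {
  th <- theta %% (2 * pi)
  ifelse(th >= SECTOR_MEMBRANE[1] & th <= SECTOR_MEMBRANE[2], "basilar_membrane",
    ifelse(th >= SECTOR_LIGAMENT[1] & th <= SECTOR_LIGAMENT[2],
           "spiral_ligament", "cochlea_wall"))
}

# ---------------------------------------------------------------------------
# placement-invalid condition

stop_placement_invalid <- function(msg, clearance_m = NA_real_) {
  cond <- structure(
    class = c("placement_invalid", "error", "condition"),
    list(message = msg, call = sys.call(-1), clearance_m = clearance_m))
  stop(cond)
}

# ---------------------------------------------------------------------------
# insertion arithmetic

# arc-length position of the carrier tip for insertion step k: exactly the
# contacts E1..Ek lie inside the lumen, Ek sitting half a pitch inside the
# basal opening.
insertion_tip_s <- function(array, k) {
  array$tip_clearance_m + array$contact_length_m / 2 +
    (k - 1) * array$pitch_m + array$pitch_m / 2
}

# contact centres (E1 apical .. Ek basal) for tip position s_tip
contact_centers_s <- function(array, k, s_tip) {
  s_tip - array$tip_clearance_m - array$contact_length_m / 2 -
    (seq_len(k) - 1) * array$pitch_m
}

# angular half-width of the contact band on the carrier surface; the band is
# centred on +x (the contacts face the inner cochlea wall)
contact_band_halfwidth <- function(array) {
  r <- mean(array$carrier_semi_axes_m)
  hw <- (array$contact_width_m / 2) / r
  if (hw >= pi / 2)
    stop("contact_width_m too large for the carrier circumference",
         call. = FALSE)
  hw
}

# ---------------------------------------------------------------------------
# cochlea geometry model

#' Build the geometric cochlea volume conductor with an inserted array
#'
#' Combines the spiral scala tympani (lumen, wall/membrane/ligament layer and
#' bone sheath) with the silicone carrier placed at the given in-plane offset
#' and insertion depth.  Only the first `insertion_step` contacts (E1..Ek)
#' lie inside the scala; the extracochlear remainder of the array is outside
#' the conductive domain.  The placement is validated: if the carrier touches
#' or crosses the scala boundary anywhere along the inserted extent, an error
#' of class `placement_invalid` is raised and no model is returned.
#'
#' @param params a [cochlea_params()].
#' @param array an [electrode_array_spec()].
#' @param placement a [placement()].
#' @param centerline optional precomputed [build_centerline()] (recomputed if
#'   `NULL`).
#' @param n_clearance_s number of arc-length stations used for the clearance
#'   scan along the inserted extent.
#' @return An object of class `cochlea_geometry` / `geometry_model`, with
#'   labelled solids, interface names, the carrier tip position, contact
#'   spans, and the minimum carrier-to-wall clearance (m).
#' @export
build_cochlea_geometry <- function(params, array, placement,
                                   centerline = NULL, n_clearance_s = 33L) {
  stopifnot(inherits(params, "cochlea_params"),
            inherits(array, "electrode_array"),
            inherits(placement, "placement"))
  if (placement$insertion_step > array$n_contacts)
    stop("insertion_step exceeds n_contacts", call. = FALSE)
  cl <- if (is.null(centerline)) build_centerline(params) else centerline
  k <- placement$insertion_step
  s_tip <- insertion_tip_s(array, k)
  if (s_tip >= cl$length_m)
    stop("electrode array is longer than the scala tympani at this insertion",
         call. = FALSE)
  centers <- contact_centers_s(array, k, s_tip)
  spans <- cbind(start = centers - array$contact_length_m / 2,
                 end = centers + array$contact_length_m / 2)
  rownames(spans) <- array$contact_ids[seq_len(k)]

  # clearance scan over the inserted extent
  ss <- seq(0, s_tip, length.out = n_clearance_s)
  ax <- lumen_semi_axes(params, ss, cl$length_m)
  cle <- section_clearance(placement$x_offset_m, placement$y_offset_m,
                           array$carrier_semi_axes_m[1],
                           array$carrier_semi_axes_m[2],
                           ax$a, ax$b)
  clearance <- min(cle)
  if (clearance <= 1e-9)
    stop_placement_invalid(sprintf(
      "carrier touches or crosses the scala boundary (clearance %.3g m at offset (%.3g, %.3g) m)",
      clearance, placement$x_offset_m, placement$y_offset_m), clearance)

  structure(list(
    kind = "cochlea",
    params = params,
    array = array,
    placement = placement,
    centerline = cl,
    s_tip = s_tip,
    contact_spans = spans,
    contact_halfwidth_rad = contact_band_halfwidth(array),
    clearance_m = clearance,
    solids = c("scala_tympani", "cochlea_wall", "basilar_membrane",
               "spiral_ligament", "bone", "carrier"),
    interfaces = c("GROUND_OUTER", "INSULATED_MEMBRANE", "STRIA_INTERFACE"),
    provenance = list(params = params, array = array, placement = placement)
  ), class = c("cochlea_geometry", "geometry_model"))
}

# carrier inner-curve description at arc length s (vector-safe over scalars):
# at and below the tip the curve is the carrier at the placement offset;
# apical of the tip it blends smoothly into a small concentric ellipse so the
# swept mesh keeps one topology.
cochlea_inner_curve <- function(geom, s) {
  p <- geom$params; a <- geom$array; pl <- geom$placement
  L <- geom$centerline$length_m
  ax <- lumen_semi_axes(p, s, L)
  blend_len <- 1.5e-3
  w <- pmin(pmax((s - geom$s_tip) / blend_len, 0), 1)
  w <- w * w * (3 - 2 * w)  # smoothstep
  frac <- 0.35
  list(cx = (1 - w) * pl$x_offset_m,
       cy = (1 - w) * pl$y_offset_m,
       ua = (1 - w) * a$carrier_semi_axes_m[1] + w * frac * ax$a,
       ub = (1 - w) * a$carrier_semi_axes_m[2] + w * frac * ax$b,
       lumen_a = ax$a, lumen_b = ax$b,
       carrier = s <= geom$s_tip + 1e-12)
}

#' Minimum carrier-to-wall clearance of a geometry model
#'
#' The minimum distance (m) between the carrier surface and the scala
#' boundary over the inserted extent, computed numerically on the elliptical
#' cross-sections.
#'
#' @param geom a `cochlea_geometry`.
#' @return Clearance in metres (positive for a valid placement).
#' @export
carrier_clearance <- function(geom) {
  stopifnot(inherits(geom, "cochlea_geometry"))
  geom$clearance_m
}

#' @export
print.cochlea_geometry <- function(x, ...) {
  cat("<cochlea_geometry>\n")
  cat(sprintf("  insertion step %d/%d, tip at s = %.3g mm of %.3g mm\n",
              x$placement$insertion_step, x$array$n_contacts,
              x$s_tip * 1e3, x$centerline$length_m * 1e3))
  cat(sprintf("  offsets (%.3g, %.3g) mm, clearance %.3g mm\n",
              x$placement$x_offset_m * 1e3, x$placement$y_offset_m * 1e3,
              x$clearance_m * 1e3))
  cat("  solids:", paste(x$solids, collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# proximity grid and rays

# largest valid offset along +axis (zero on the other axis) for the given
# insertion, found by bisection on the sampled clearance
max_valid_offset <- function(params, array, axis = c("x", "y"),
                             insertion_step = array$n_contacts,
                             centerline = NULL, n_s = 33L) {
  axis <- match.arg(axis)
  cl <- if (is.null(centerline)) build_centerline(params) else centerline
  s_tip <- insertion_tip_s(array, insertion_step)
  ss <- seq(0, s_tip, length.out = n_s)
  ax <- lumen_semi_axes(params, ss, cl$length_m)
  clr <- function(off) {
    min(section_clearance(if (axis == "x") off else 0,
                          if (axis == "y") off else 0,
                          array$carrier_semi_axes_m[1],
                          array$carrier_semi_axes_m[2], ax$a, ax$b))
  }
  hi <- if (axis == "x") min(ax$a) else min(ax$b)  # certainly invalid
  lo <- 0
  if (clr(0) <= 0)
    stop("carrier does not fit the scala even at zero offset", call. = FALSE)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (clr(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Build the in-plane proximity sample grid
#'
#' An `n_x` by `n_y` grid of candidate carrier placements with one common
#' spacing `d` on both in-plane axes, centred on the scala centreline.  The
#' grid is sized from the widest axis (x): its extreme samples sit just
#' beyond the touching offset, so the grid spans mid-scala to near-touching
#' in both directions and the outermost candidates are invalid.  Every
#' candidate is tested by [build_cochlea_geometry()]; invalid placements are
#' flagged, never dropped.
#'
#' @param params a [cochlea_params()].
#' @param array an [electrode_array_spec()].
#' @param n_x,n_y sample counts per axis (default 12 x 12 = 144 candidates).
#' @param insertion_step insertion depth used for validity testing (default
#'   full insertion).
#' @param range_factor half-range of the grid as a multiple of the touching
#'   offset along x (default 1.05: extremes just beyond touching).
#' @return An object of class `proximity_grid`: spacing `spacing_m`, offsets
#'   per axis, and a list `placements` of [placement()] objects carrying
#'   `valid` flags and sampled clearances.
#' @export
make_proximity_grid <- function(params, array, n_x = 12L, n_y = 12L,
                                insertion_step = array$n_contacts,
                                range_factor = 1.05) {
  stopifnot(n_x >= 1L, n_y >= 1L)
  cl <- build_centerline(params)
  o_x <- max_valid_offset(params, array, "x", insertion_step, cl)
  d <- if (n_x > 1L) 2 * range_factor * o_x / (n_x - 1) else o_x
  off_x <- (seq_len(n_x) - (n_x + 1) / 2) * d
  off_y <- (seq_len(n_y) - (n_y + 1) / 2) * d
  placements <- vector("list", n_x * n_y)
  idx <- 0L
  for (j in seq_len(n_y)) {
    for (i in seq_len(n_x)) {
      idx <- idx + 1L
      pl <- placement(off_x[i], off_y[j], insertion_step, grid_index = c(i, j))
      g <- tryCatch(build_cochlea_geometry(params, array, pl, centerline = cl),
                    placement_invalid = function(e) e)
      if (inherits(g, "placement_invalid")) {
        pl$valid <- FALSE
        pl$clearance_m <- g$clearance_m
      } else {
        pl$valid <- TRUE
        pl$clearance_m <- g$clearance_m
      }
      placements[[idx]] <- pl
    }
  }
  structure(list(
    spacing_m = d,
    n_x = n_x, n_y = n_y,
    offsets_x_m = off_x, offsets_y_m = off_y,
    placements = placements,
    insertion_step = insertion_step,
    params = params, array = array
  ), class = "proximity_grid")
}

#' @export
print.proximity_grid <- function(x, ...) {
  nv <- sum(vapply(x$placements, function(p) isTRUE(p$valid), logical(1)))
  cat(sprintf("<proximity_grid> %d x %d = %d candidates (%d valid), d = %.3g mm\n",
              x$n_x, x$n_y, length(x$placements), nv, x$spacing_m * 1e3))
  invisible(x)
}

#' Build a one-dimensional proximity ray
#'
#' Placements from mid-scala outward along one in-plane axis, up to
#' `frac_max` of the touching offset (so the last sample is nearly touching
#' but still valid).  Used by the axis sweep and sensitivity protocols.
#'
#' @inheritParams make_proximity_grid
#' @param axis `"x"` (towards the modiolar wall) or `"y"` (towards the
#'   basilar membrane).
#' @param direction `+1` or `-1`.
#' @param n_positions number of samples including the mid-scala start.
#' @param frac_max furthest sample as a fraction of the touching offset.
#' @return A list of [placement()] objects (all valid by construction).
#' @export
make_proximity_ray <- function(params, array, axis = c("x", "y"),
                               direction = 1, n_positions = 8L,
                               frac_max = 0.95,
                               insertion_step = array$n_contacts) {
  axis <- match.arg(axis)
  stopifnot(n_positions >= 2L, frac_max > 0, frac_max < 1)
  cl <- build_centerline(params)
  o_max <- max_valid_offset(params, array, axis, insertion_step, cl)
  offs <- direction * seq(0, frac_max * o_max, length.out = n_positions)
  lapply(seq_along(offs), function(i) {
    pl <- placement(if (axis == "x") offs[i] else 0,
                    if (axis == "y") offs[i] else 0,
                    insertion_step, grid_index = c(i, 0L))
    pl$valid <- TRUE
    pl$ray_offset_m <- offs[i]
    pl
  })
}

# ---------------------------------------------------------------------------
# toy channel

#' Straight tapered channel in a bone block (test fixture geometry)
#'
#' An "uncoiled" stand-in for the scala tympani: a straight elliptical
#' channel at perilymph conductivity, tapering linearly from
#' `semi_axes_base_m` to `semi_axes_end_m`, wrapped in a bone layer of
#' thickness `block_margin_m`.  The far end face (`s = length_m`) is labelled
#' as ground; everything else is insulated.  Optionally carries an electrode
#' array, placed like in the cochlea model.
#'
#' @param length_m channel length (m).
#' @param semi_axes_base_m,semi_axes_end_m length-2 vectors: channel
#'   cross-section semi-axes at the two ends (m).
#' @param block_margin_m bone layer thickness (m).
#' @param array optional [electrode_array_spec()].
#' @param placement optional [placement()] (required with `array`).
#' @return An object of class `toy_channel_geometry` / `geometry_model`.
#' @export
make_toy_channel <- function(length_m, semi_axes_base_m, semi_axes_end_m,
                             block_margin_m, array = NULL, placement = NULL) {
  stopifnot(length(semi_axes_base_m) == 2, length(semi_axes_end_m) == 2)
  dims <- c(length_m, semi_axes_base_m, semi_axes_end_m, block_margin_m)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all toy-channel dimensions must be positive", call. = FALSE)
  solids <- c("scala_tympani", "bone")
  s_tip <- NULL; spans <- NULL; hw <- NULL
  clearance <- NA_real_
  if (!is.null(array)) {
    stopifnot(inherits(array, "electrode_array"))
    if (is.null(placement)) placement <- placement()
    k <- placement$insertion_step
    if (k > array$n_contacts) stop("insertion_step exceeds n_contacts",
                                   call. = FALSE)
    s_tip <- insertion_tip_s(array, k)
    if (s_tip >= length_m)
      stop("array longer than the toy channel", call. = FALSE)
    centers <- contact_centers_s(array, k, s_tip)
    spans <- cbind(start = centers - array$contact_length_m / 2,
                   end = centers + array$contact_length_m / 2)
    rownames(spans) <- array$contact_ids[seq_len(k)]
    hw <- contact_band_halfwidth(array)
    ss <- seq(0, s_tip, length.out = 17L)
    f <- ss / length_m
    aa <- semi_axes_base_m[1] + (semi_axes_end_m[1] - semi_axes_base_m[1]) * f
    bb <- semi_axes_base_m[2] + (semi_axes_end_m[2] - semi_axes_base_m[2]) * f
    clearance <- min(section_clearance(placement$x_offset_m,
                                       placement$y_offset_m,
                                       array$carrier_semi_axes_m[1],
                                       array$carrier_semi_axes_m[2], aa, bb))
    if (clearance <= 1e-9)
      stop_placement_invalid("carrier touches the toy channel wall", clearance)
    solids <- c(solids, "carrier")
  }
  structure(list(
    kind = "toy_channel",
    length_m = length_m,
    semi_axes_base_m = as.numeric(semi_axes_base_m),
    semi_axes_end_m = as.numeric(semi_axes_end_m),
    block_margin_m = block_margin_m,
    array = array,
    placement = placement,
    s_tip = s_tip,
    contact_spans = spans,
    contact_halfwidth_rad = hw,
    clearance_m = clearance,
    centerline = straight_centerline(length_m),
    solids = solids,
    interfaces = "GROUND_OUTER",
    provenance = list(length_m = length_m,
                      semi_axes_base_m = semi_axes_base_m,
                      semi_axes_end_m = semi_axes_end_m,
                      block_margin_m = block_margin_m)
  ), class = c("toy_channel_geometry", "geometry_model"))
}

# inner-curve description for the toy channel (mirrors cochlea_inner_curve)
toy_inner_curve <- function(geom, s) {
  f <- s / geom$length_m
  a <- geom$semi_axes_base_m[1] +
    (geom$semi_axes_end_m[1] - geom$semi_axes_base_m[1]) * f
  b <- geom$semi_axes_base_m[2] +
    (geom$semi_axes_end_m[2] - geom$semi_axes_base_m[2]) * f
  if (is.null(geom$array)) {
    frac <- 0.35
    list(cx = 0 * s, cy = 0 * s, ua = frac * a, ub = frac * b,
         lumen_a = a, lumen_b = b, carrier = rep(FALSE, length(s)))
  } else {
    pl <- geom$placement; arr <- geom$array
    blend_len <- min(1.5e-3, geom$length_m / 4)
    w <- pmin(pmax((s - geom$s_tip) / blend_len, 0), 1)
    w <- w * w * (3 - 2 * w)
    frac <- 0.35
    list(cx = (1 - w) * pl$x_offset_m,
         cy = (1 - w) * pl$y_offset_m,
         ua = (1 - w) * arr$carrier_semi_axes_m[1] + w * frac * a,
         ub = (1 - w) * arr$carrier_semi_axes_m[2] + w * frac * b,
         lumen_a = a, lumen_b = b,
         carrier = s <= geom$s_tip + 1e-12)
  }
}

#' @export
print.toy_channel_geometry <- function(x, ...) {
  cat(sprintf("<toy_channel_geometry> length %.3g mm, semi-axes %.3g x %.3g -> %.3g x %.3g mm%s\n",
              x$length_m * 1e3,
              x$semi_axes_base_m[1] * 1e3, x$semi_axes_base_m[2] * 1e3,
              x$semi_axes_end_m[1] * 1e3, x$semi_axes_end_m[2] * 1e3,
              if (is.null(x$array)) "" else ", with carrier"))
  invisible(x)
}
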