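#' Meshing options
#'
#' Controls the discretisation of the swept-tube mesher (and the validation
#' fixtures).  `target_size_near_m` sets the element size near the electrode
#' contacts (angular resolution of the carrier surface, axial station spacing
#' along the inserted extent, and the fluid-layer count);
#' `target_size_far_m` sets the size in bone and beyond the array, with
#' station spacing growing by `growth_rate` per step in between.  Defaults
#' are deliberately coarse (tens of thousands of elements) so a solve runs in
#' seconds on one CPU; halve the sizes for convergence checks.
#'
#' @param target_size_near_m element size near contacts (m).
#' @param target_size_far_m element size in bone / far field (m).
#' @param growth_rate axial size gradation factor (>= 1).
#' @param element_order finite-element order; only linear tetrahedra
#'   (order 1) are supported.
#' @param mesher_seed integer recorded in the mesh provenance; the mesher is
#'   fully deterministic, so the seed never changes the output.
#' @return An object of class `mesh_options`.
#' @export
mesh_options <- function(target_size_near_m = 1.5e-4,
                         target_size_far_m = 6e-4,
                         growth_rate = 1.4,
                         element_order = 1L,
                         mesher_seed = 1L) {
  if (!is.finite(target_size_near_m) || target_size_near_m <= 0 ||
      !is.finite(target_size_far_m) || target_size_far_m <= 0)
    stop("target sizes must be positive", call. = FALSE)
  if (target_size_near_m > target_size_far_m)
    stop("target_size_near_m must not exceed target_size_far_m", call. = FALSE)
  if (!is.finite(growth_rate) || growth_rate < 1)
    stop("growth_rate must be >= 1", call. = FALSE)
  element_order <- as.integer(element_order)
  if (!identical(element_order, 1L))
    stop("only linear tetrahedra are supported (element_order = 1)",
         call. = FALSE)
  structure(list(target_size_near_m = target_size_near_m,
                 target_size_far_m = target_size_far_m,
                 growth_rate = growth_rate,
                 element_order = element_order,
                 mesher_seed = as.integer(mesher_seed)),
            class = "mesh_options")
}

#' Generate a labelled tetrahedral mesh from a geometry model
#'
#' Discretises the volume conductor with a boundary-fitted structured mesh:
#' the elliptical cross-section (carrier fan, fluid rings, tissue-layer rings,
#' bone rings) is triangulated once and swept along the centreline; prisms
#' are split into tetrahedra with a lowest-vertex-index diagonal rule that
#' guarantees a conforming mesh.  Region labels, contact patches, the outer
#' ground surface, the insulated membrane surface and the stria thin-layer
#' interface are carried through from the geometry.
#'
#' @param geom a `geometry_model` (from [build_cochlea_geometry()] or
#'   [make_toy_channel()]).
#' @param opts a [mesh_options()].
#' @param ... unused.
#' @return A `labeled_mesh`.
#' @export
generate_mesh <- function(geom, opts = mesh_options(), ...) {
  UseMethod("generate_mesh")
}

#' @export
generate_mesh.cochlea_geometry <- function(geom, opts = mesh_options(), ...) {
  stopifnot(inherits(opts, "mesh_options"))
  check_turn_separation(geom)
  mesh_swept(geom, opts)
}

#' @export
generate_mesh.toy_channel_geometry <- function(geom, opts = mesh_options(), ...) {
  stopifnot(inherits(opts, "mesh_options"))
  mesh_swept(geom, opts)
}

# ---------------------------------------------------------------------------
# heuristic guard: sampled outer surfaces of well-separated arc-length
# stations (different turns, or opposite sides of the axis) must not touch
check_turn_separation <- function(geom, n_s = 96L, n_th = 16L) {
  p <- geom$params
  if (p$n_turns < 1.2) return(invisible(TRUE))
  cl <- geom$centerline
  ss <- seq(0, cl$length_m, length.out = n_s)
  ev <- centerline_at(cl, ss)
  th <- seq(0, 2 * pi, length.out = n_th + 1L)[-(n_th + 1L)]
  ax <- lumen_semi_axes(p, ss, cl$length_m)
  tvec <- layer_thickness(p, th)
  in_mem <- th >= SECTOR_MEMBRANE[1] & th <= SECTOR_MEMBRANE[2]
  off <- tvec + ifelse(in_mem, 0, p$bone_margin_m)
  pts <- matrix(0, n_s * n_th, 3L)
  tau <- rep(ev$tau, each = n_th)
  for (j in seq_len(n_s)) {
    a <- ax$a[j]; b <- ax$b[j]
    nx <- b * cos(th); ny <- a * sin(th)
    nn <- sqrt(nx^2 + ny^2)
    X <- a * cos(th) + off * nx / nn
    Y <- b * sin(th) + off * ny / nn
    rows <- (j - 1L) * n_th + seq_len(n_th)
    pts[rows, ] <- rep(ev$point[j, ], each = n_th) +
      outer(X, ev$xhat[j, ]) + outer(Y, ev$yhat[j, ])
  }
  dtau <- abs(outer(tau, tau, "-")) * p$n_turns
  D2 <- as.matrix(stats::dist(pts))^2
  mask <- dtau >= 0.35
  if (any(mask) && min(D2[mask]) < (1e-5)^2)
    stop(paste("adjacent turns of the spiral (including tissue sheaths)",
               "intersect or nearly touch; increase axial_pitch_m or reduce",
               "layer thicknesses"), call. = FALSE)
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# swept-tube mesher shared by the cochlea and toy-channel geometries

# merge uniformly spaced base angles with mandatory special angles
make_theta_stations <- function(m0, special) {
  base <- 2 * pi * (seq_len(m0) - 1L) / m0
  special <- sort(unique(round(special %% (2 * pi), 12)))
  if (length(special)) {
    keep <- vapply(base, function(a) {
      all(pmin(abs(a - special), 2 * pi - abs(a - special)) > 0.3 * 2 * pi / m0)
    }, logical(1))
    base <- base[keep]
  }
  sort(unique(c(base, special)))
}

# subdivide [s0, s1] with spacing growing from h0 by factor g, capped at h1
graded_subdivide <- function(s0, s1, h0, h1, g) {
  len <- s1 - s0
  if (len <= h0 * 1.0001) return(c(s0, s1))
  inc <- h0
  incs <- numeric()
  while (sum(incs) < len) {
    incs <- c(incs, inc)
    inc <- min(inc * g, h1)
  }
  incs <- incs * (len / sum(incs))
  c(s0, s0 + cumsum(incs))
}

# arc-length stations: snap to contact-span edges and the carrier tip, fill
# the array zone at the near size and grade towards the far size beyond
make_s_stations <- function(geom, opts) {
  L <- if (geom$kind == "cochlea") geom$centerline$length_m else geom$length_m
  near <- opts$target_size_near_m
  far <- opts$target_size_far_m
  keys <- c(0, L)
  has_array <- !is.null(geom$contact_spans)
  if (has_array) keys <- c(keys, as.vector(geom$contact_spans), geom$s_tip)
  keys <- sort(unique(pmin(pmax(keys, 0), L)))
  st <- numeric()
  for (i in seq_len(length(keys) - 1L)) {
    k0 <- keys[i]; k1 <- keys[i + 1L]
    if (has_array && k0 >= geom$s_tip - 1e-12) {
      seg <- graded_subdivide(k0, k1, near, far, opts$growth_rate)
    } else {
      n <- max(1L, ceiling((k1 - k0) / near))
      seg <- seq(k0, k1, length.out = n + 1L)
    }
    st <- c(st, seg[-length(seg)])
  }
  c(st, L)
}

mesh_swept <- function(geom, opts) {
  near <- opts$target_size_near_m
  far <- opts$target_size_far_m
  is_cochlea <- geom$kind == "cochlea"
  cl <- geom$centerline
  L <- if (is_cochlea) cl$length_m else geom$length_m
  has_array <- !is.null(geom$contact_spans)
  inner_curve <- if (is_cochlea) cochlea_inner_curve else toy_inner_curve

  # --- angular stations
  ic0 <- inner_curve(geom, 0)
  r_ref <- mean(c(ic0$ua, ic0$ub))
  m0 <- max(12L, ceiling(2 * pi * r_ref / near))
  special <- numeric()
  if (is_cochlea) special <- c(SECTOR_MEMBRANE, SECTOR_LIGAMENT)
  if (has_array) {
    # contact band edges carry a field singularity: cluster stations there
    hw <- geom$contact_halfwidth_rad
    dcl <- 0.35 * 2 * pi / m0
    special <- c(special, hw, hw - dcl, hw + dcl,
                 2 * pi - hw, 2 * pi - hw + dcl, 2 * pi - hw - dcl)
  }
  th <- make_theta_stations(m0, special)
  m <- length(th)
  dth <- diff(c(th, th[1] + 2 * pi))
  corr <- sqrt(2 * pi / sum(sin(dth)))  # polygon-area-preserving radius factor
  mid_th <- (th + dth / 2) %% (2 * pi)
  nxt <- c(seq_len(m)[-1L], 1L)

  # --- radial layer counts (placement-independent so every placement of a
  # sweep meshes with one topology)
  sec_mid <- inner_curve(geom, L / 2)
  u_ref <- if (has_array) geom$array$carrier_semi_axes_m
           else 0.35 * c(sec_mid$lumen_a, sec_mid$lumen_b)
  gap_ref <- mean(c(sec_mid$lumen_a - u_ref[1], sec_mid$lumen_b - u_ref[2]))
  nf <- max(3L, ceiling(gap_ref / (2 * near)))
  if (is_cochlea) {
    nw <- max(2L, ceiling(geom$params$wall_thickness_m / near))
    nbn <- max(2L, ceiling(geom$params$bone_margin_m / far))
  } else {
    nw <- 0L
    nbn <- max(2L, ceiling(geom$block_margin_m / far))
  }
  L_inner <- 1L
  L_lumen <- nf + 1L
  L_wallout <- L_lumen + nw       # equals L_lumen for the toy channel
  n_lev <- L_wallout + nbn
  tid <- function(l, i) 1L + (l - 1L) * m + i
  n_base_t <- 1L + n_lev * m

  # angular-sector membership per column
  in_mem_col <- mid_th >= SECTOR_MEMBRANE[1] & mid_th <= SECTOR_MEMBRANE[2]
  in_lig_col <- mid_th >= SECTOR_LIGAMENT[1] & mid_th <= SECTOR_LIGAMENT[2]
  band_col <- if (has_array) {
    d0 <- pmin(mid_th, 2 * pi - mid_th)
    d0 < geom$contact_halfwidth_rad
  } else rep(FALSE, m)

  # stria interface node duplication (cochlea only): wall-outer nodes strictly
  # inside the ligament sector get a bone-side twin
  dup_stations <- if (is_cochlea) {
    which(th > SECTOR_LIGAMENT[1] + 1e-9 & th < SECTOR_LIGAMENT[2] - 1e-9)
  } else integer()
  dup_of <- rep(NA_integer_, m)
  if (length(dup_stations))
    dup_of[dup_stations] <- n_base_t + seq_along(dup_stations)
  n_t <- n_base_t + length(dup_stations)
  # bone-side template id of a wall-outer node (twin where duplicated)
  plus_id <- function(i) ifelse(is.na(dup_of[i]), tid(L_wallout, i), dup_of[i])

  # --- template triangles
  tri <- list(); zone <- integer(); col <- integer()
  # carrier fan
  tri[[length(tri) + 1L]] <- cbind(1L, tid(1L, seq_len(m)), tid(1L, nxt))
  zone <- c(zone, rep(0L, m)); col <- c(col, seq_len(m))
  for (l in seq_len(n_lev - 1L)) {
    cols <- seq_len(m)
    if (is_cochlea && l >= L_wallout) cols <- cols[!in_mem_col[cols]]
    if (!length(cols)) next
    q1 <- tid(l, cols); q2 <- tid(l, nxt[cols])
    q3 <- tid(l + 1L, nxt[cols]); q4 <- tid(l + 1L, cols)
    if (is_cochlea && l == L_wallout) {
      lig <- in_lig_col[cols]
      q1[lig] <- plus_id(cols[lig])
      q2[lig] <- plus_id(nxt[cols][lig])
    }
    tri[[length(tri) + 1L]] <- cbind(q1, q2, q3)
    tri[[length(tri) + 1L]] <- cbind(q1, q3, q4)
    zone <- c(zone, rep(l, 2L * length(cols)))
    col <- c(col, cols, cols)
  }
  tri <- do.call(rbind, tri)
  nt_tri <- nrow(tri)

  # static part of the region label per template triangle
  lab_static <- character(nt_tri)
  lab_static[zone == 0L] <- "scala_tympani"       # fan; may become carrier
  lab_static[zone >= 1L & zone < L_lumen] <- "scala_tympani"
  if (is_cochlea) {
    wl <- zone >= L_lumen & zone < L_wallout
    lab_static[wl] <- wall_sector_label(mid_th[col[wl]])
    lab_static[zone >= L_wallout] <- "bone"
  } else {
    lab_static[zone >= L_lumen] <- "bone"
  }

  # --- arc-length stations and section coordinates
  s_st <- make_s_stations(geom, opts)
  n_st <- length(s_st)

  section_local <- function(s) {
    ic <- inner_curve(geom, s)
    X <- numeric(n_t); Y <- numeric(n_t)
    X[1L] <- ic$cx; Y[1L] <- ic$cy
    cth <- cos(th); sth <- sin(th)
    ix <- ic$cx + ic$ua * cth * corr
    iy <- ic$cy + ic$ub * sth * corr
    lx <- ic$lumen_a * cth * corr
    ly <- ic$lumen_b * sth * corr
    X[tid(1L, seq_len(m))] <- ix; Y[tid(1L, seq_len(m))] <- iy
    for (l in seq_len(nf - 1L)) {
      # fluid layers graded towards the carrier surface, where the contact
      # edge field is steepest
      f <- (l / nf)^1.7
      X[tid(1L + l, seq_len(m))] <- ix + f * (lx - ix)
      Y[tid(1L + l, seq_len(m))] <- iy + f * (ly - iy)
    }
    X[tid(L_lumen, seq_len(m))] <- lx; Y[tid(L_lumen, seq_len(m))] <- ly
    nx <- ic$lumen_b * cth; ny <- ic$lumen_a * sth
    nn <- sqrt(nx^2 + ny^2); nx <- nx / nn; ny <- ny / nn
    if (is_cochlea) {
      tvec <- layer_thickness(geom$params, th)
      for (j in seq_len(nw)) {
        X[tid(L_lumen + j, seq_len(m))] <- lx + nx * tvec * j / nw
        Y[tid(L_lumen + j, seq_len(m))] <- ly + ny * tvec * j / nw
      }
      wox <- X[tid(L_wallout, seq_len(m))]
      woy <- Y[tid(L_wallout, seq_len(m))]
      bm <- geom$params$bone_margin_m
      for (j in seq_len(nbn)) {
        X[tid(L_wallout + j, seq_len(m))] <- wox + nx * bm * j / nbn
        Y[tid(L_wallout + j, seq_len(m))] <- woy + ny * bm * j / nbn
      }
      if (length(dup_stations)) {
        X[dup_of[dup_stations]] <- X[tid(L_wallout, dup_stations)]
        Y[dup_of[dup_stations]] <- Y[tid(L_wallout, dup_stations)]
      }
    } else {
      bm <- geom$block_margin_m
      for (j in seq_len(nbn)) {
        X[tid(L_lumen + j, seq_len(m))] <- lx + nx * bm * j / nbn
        Y[tid(L_lumen + j, seq_len(m))] <- ly + ny * bm * j / nbn
      }
    }
    cbind(X, Y)
  }

  ev <- frames_at(cl, s_st)
  nodes <- matrix(0, n_st * n_t, 3L)
  for (j in seq_len(n_st)) {
    loc <- section_local(s_st[j])
    rows <- (j - 1L) * n_t + seq_len(n_t)
    nodes[rows, ] <- rep(ev$point[j, ], each = n_t) +
      outer(loc[, 1], ev$xhat[j, ]) + outer(loc[, 2], ev$yhat[j, ])
  }

  # --- extrude template triangles into prisms, prisms into tets
  ns <- n_st - 1L
  bot <- tri[rep(seq_len(nt_tri), ns), , drop = FALSE] +
    rep((seq_len(ns) - 1L) * n_t, each = nt_tri)
  top <- bot + n_t
  tets <- split_prisms(bot, top)

  s_mid <- (s_st[-n_st] + s_st[-1L]) / 2
  lab <- rep(lab_static, ns)
  if (has_array) {
    fan_rows <- rep(zone == 0L, ns)
    carrier_slab <- rep(s_mid <= geom$s_tip + 1e-12, each = nt_tri)
    lab[fan_rows & carrier_slab] <- "carrier"
  }
  region_labels <- intersect(
    c("scala_tympani", "cochlea_wall", "basilar_membrane", "spiral_ligament",
      "bone", "carrier"), unique(lab))
  region <- rep(match(lab, region_labels), each = 3L)

  # --- boundary surfaces
  btris <- list(); blabel <- character()
  add_b <- function(tris, label) {
    btris[[length(btris) + 1L]] <<- tris
    blabel <<- c(blabel, rep(label, nrow(tris)))
  }
  extrude_edges <- function(e1, e2, slabs) {
    a <- rep(e1, length(slabs)) + rep((slabs - 1L) * n_t, each = length(e1))
    b <- rep(e2, length(slabs)) + rep((slabs - 1L) * n_t, each = length(e1))
    split_quads(a, b, b + n_t, a + n_t)
  }
  # end caps
  add_b(tri, "INSULATED_END")
  cap_far <- tri + (n_st - 1L) * n_t
  add_b(cap_far, if (is_cochlea) "INSULATED_END" else "GROUND_OUTER")
  # contact patches
  if (has_array) {
    bc <- which(band_col)
    for (ci in seq_len(nrow(geom$contact_spans))) {
      sp <- geom$contact_spans[ci, ]
      slabs <- which(s_mid > sp[1] - 1e-12 & s_mid < sp[2] + 1e-12)
      if (!length(slabs)) next
      add_b(extrude_edges(tid(1L, bc), tid(1L, nxt[bc]), slabs),
            paste0("CONTACT_", rownames(geom$contact_spans)[ci]))
    }
  }
  if (is_cochlea) {
    oc <- which(!in_mem_col)
    add_b(extrude_edges(tid(n_lev, oc), tid(n_lev, nxt[oc]), seq_len(ns)),
          "GROUND_OUTER")
    mc <- which(in_mem_col)
    add_b(extrude_edges(tid(L_wallout, mc), tid(L_wallout, nxt[mc]),
                        seq_len(ns)), "INSULATED_MEMBRANE")
  }
  btris <- do.call(rbind, btris)
  boundary_labels <- unique(blabel)
  blabel_int <- match(blabel, boundary_labels)

  # --- stria thin-layer interface (cochlea only)
  interface <- NULL
  if (is_cochlea) {
    lc <- which(in_lig_col)
    tris_minus <- extrude_edges(tid(L_wallout, lc), tid(L_wallout, nxt[lc]),
                                seq_len(ns))
    pm <- tid(L_wallout, dup_stations)
    pp <- dup_of[dup_stations]
    pairs <- cbind(minus = rep(pm, n_st) + rep((seq_len(n_st) - 1L) * n_t,
                                               each = length(pm)),
                   plus = rep(pp, n_st) + rep((seq_len(n_st) - 1L) * n_t,
                                              each = length(pp)))
    interface <- list(label = "STRIA_INTERFACE", tris = tris_minus,
                      pairs = pairs)
  }

  mesh <- new_labeled_mesh(
    nodes = nodes, tets = tets, region = region,
    region_labels = region_labels,
    btris = btris, blabel = blabel_int, boundary_labels = boundary_labels,
    contact_labels = if (has_array)
      paste0("CONTACT_", rownames(geom$contact_spans)) else character(),
    interface = interface,
    node_station = rep(seq_len(n_st), each = n_t),
    station_s = s_st,
    provenance = list(geometry = geom, options = opts))
  mesh
}
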