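# Analytic oracles and verification fixtures.  These replace anatomical
# cross-validation (which would need imaging data): the solver is checked
# against closed-form resistances (disk contact, concentric spheres, layered
# bars), mesh-convergence behaviour, reciprocity and scaling laws.

#' Spreading resistance of a disk contact on a half-space
#'
#' Classical access resistance of an equipotential disk of radius `a` on the
#' surface of a homogeneous half-space of conductivity `sigma`:
#' `R = 1 / (4 * sigma * a)`.
#'
#' @param sigma conductivity (S/m), > 0.
#' @param a disk radius (m), > 0.
#' @return Resistance (ohm).
#' @export
#' @examples
#' disk_spreading_resistance(1, 1)          # 0.25
#' disk_spreading_resistance(1.43, 2.5e-4)  # perilymph, 0.25 mm contact
disk_spreading_resistance <- function(sigma, a) {
  if (!is.finite(sigma) || sigma <= 0 || !is.finite(a) || a <= 0)
    stop("sigma and a must be positive", call. = FALSE)
  1 / (4 * sigma * a)
}

#' Resistance between concentric spheres
#'
#' `R = (1 / (4 * pi * sigma)) * (1/a - 1/b)` for a homogeneous medium of
#' conductivity `sigma` between an inner sphere of radius `a` and an outer
#' grounded sphere of radius `b`.
#'
#' @param sigma conductivity (S/m), > 0.
#' @param a inner radius (m), 0 < a < b.
#' @param b outer radius (m).
#' @return Resistance (ohm).
#' @export
concentric_spheres_resistance <- function(sigma, a, b) {
  if (!is.finite(sigma) || sigma <= 0 || !is.finite(a) || a <= 0)
    stop("sigma and a must be positive", call. = FALSE)
  if (!is.finite(b) || a >= b) stop("need a < b", call. = FALSE)
  (1 / (4 * pi * sigma)) * (1 / a - 1 / b)
}

# ---------------------------------------------------------------------------
# structured box meshes (Kuhn split: globally conforming on tensor grids)

kuhn_split_cells <- function(nx, ny, nz) {
  id <- function(i, j, k) i + (j - 1L) * (nx + 1L) +
    (k - 1L) * (nx + 1L) * (ny + 1L)
  ii <- rep(seq_len(nx), times = ny * nz)
  jj <- rep(rep(seq_len(ny), each = nx), times = nz)
  kk <- rep(seq_len(nz), each = nx * ny)
  c000 <- id(ii, jj, kk);         c100 <- id(ii + 1L, jj, kk)
  c010 <- id(ii, jj + 1L, kk);    c110 <- id(ii + 1L, jj + 1L, kk)
  c001 <- id(ii, jj, kk + 1L);    c101 <- id(ii + 1L, jj, kk + 1L)
  c011 <- id(ii, jj + 1L, kk + 1L); c111 <- id(ii + 1L, jj + 1L, kk + 1L)
  rbind(cbind(c000, c100, c110, c111),
        cbind(c000, c100, c101, c111),
        cbind(c000, c010, c110, c111),
        cbind(c000, c010, c011, c111),
        cbind(c000, c001, c101, c111),
        cbind(c000, c001, c011, c111))
}

# generic tensor-grid box mesh; region/boundary labels via centroid functions
make_box_mesh <- function(xs, ys, zs,
                          region_fun = function(cx, cy, cz) "medium",
                          boundary_fun = function(cx, cy, cz) NA_character_,
                          provenance = list()) {
  nx <- length(xs) - 1L; ny <- length(ys) - 1L; nz <- length(zs) - 1L
  stopifnot(nx >= 1, ny >= 1, nz >= 1)
  nodes <- cbind(rep(xs, times = (ny + 1) * (nz + 1)),
                 rep(rep(ys, each = nx + 1), times = nz + 1),
                 rep(zs, each = (nx + 1) * (ny + 1)))
  tets <- kuhn_split_cells(nx, ny, nz)
  cen <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] +
          nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4
  lab <- region_fun(cen[, 1], cen[, 2], cen[, 3])
  region_labels <- unique(lab)
  region <- match(lab, region_labels)
  bf <- boundary_faces(tets)
  bc <- (nodes[bf[, 1], ] + nodes[bf[, 2], ] + nodes[bf[, 3], ]) / 3
  blab <- boundary_fun(bc[, 1], bc[, 2], bc[, 3])
  keep <- !is.na(blab)
  btris <- bf[keep, , drop = FALSE]
  blab <- blab[keep]
  boundary_labels <- unique(blab)
  new_labeled_mesh(nodes, tets, region, region_labels,
                   btris, match(blab, boundary_labels), boundary_labels,
                   contact_labels = grep("^CONTACT_", boundary_labels,
                                         value = TRUE),
                   provenance = provenance)
}

#' Homogeneous (or layered) bar mesh for solver verification
#'
#' A rectangular bar `[0, a] x [0, b] x [0, L]` whose `z = 0` face is the
#' contact terminal `CONTACT_BAR` and whose `z = L` face is `GROUND_OUTER`;
#' side faces are insulated, so the exact solution is one-dimensional.
#' Optionally the bar is split at `z = split_z` into regions `bar_lower` /
#' `bar_upper` (otherwise a single region `bar_lower`), and a thin resistive
#' layer can be inserted at the split as a duplicated-node interface using
#' the stria contact-impedance machinery (conductivity `stria_vascularis` and
#' thickness `stria_thickness_m` of the conductivity table).
#'
#' @param a,b,L bar dimensions (m).
#' @param n length-3 integer vector of cells per direction.
#' @param split_z optional interface height (m), snapped into the grid.
#' @param thin_layer if `TRUE` (requires `split_z`), insert the thin-layer
#'   interface at the split.
#' @return A `labeled_mesh`.
#' @export
make_bar_mesh <- function(a, b, L, n = c(4L, 4L, 12L),
                          split_z = NULL, thin_layer = FALSE) {
  stopifnot(a > 0, b > 0, L > 0, length(n) == 3)
  xs <- seq(0, a, length.out = n[1] + 1L)
  ys <- seq(0, b, length.out = n[2] + 1L)
  zs <- seq(0, L, length.out = n[3] + 1L)
  if (!is.null(split_z)) {
    stopifnot(split_z > 0, split_z < L)
    zs <- sort(unique(c(zs, split_z)))
  }
  region_fun <- function(cx, cy, cz) {
    if (is.null(split_z)) rep("bar_lower", length(cz))
    else ifelse(cz < split_z, "bar_lower", "bar_upper")
  }
  tolz <- L * 1e-9
  boundary_fun <- function(cx, cy, cz) {
    ifelse(cz < tolz, "CONTACT_BAR",
           ifelse(cz > L - tolz, "GROUND_OUTER", NA_character_))
  }
  mesh <- make_box_mesh(xs, ys, zs, region_fun, boundary_fun,
                        provenance = list(kind = "bar", a = a, b = b, L = L,
                                          n = n, split_z = split_z,
                                          thin_layer = thin_layer))
  if (thin_layer) {
    if (is.null(split_z)) stop("thin_layer requires split_z", call. = FALSE)
    mesh <- insert_plane_interface(mesh, split_z, "STRIA_INTERFACE")
  }
  mesh
}

# duplicate all nodes on the plane z = z0 and re-point the elements above the
# plane at the twins; interface triangles live on the lower (minus) side
insert_plane_interface <- function(mesh, z0, label) {
  tol <- 1e-9 * max(abs(mesh$nodes))
  on_plane <- which(abs(mesh$nodes[, 3] - z0) < tol)
  if (!length(on_plane)) stop("no nodes on the interface plane", call. = FALSE)
  n <- nrow(mesh$nodes)
  twin <- seq_len(n)
  twin[on_plane] <- n + seq_along(on_plane)
  nodes <- rbind(mesh$nodes, mesh$nodes[on_plane, , drop = FALSE])
  cen_z <- (mesh$nodes[mesh$tets[, 1], 3] + mesh$nodes[mesh$tets[, 2], 3] +
            mesh$nodes[mesh$tets[, 3], 3] + mesh$nodes[mesh$tets[, 4], 3]) / 4
  tets <- mesh$tets
  above <- cen_z > z0
  tets[above, ] <- matrix(twin[tets[above, ]], ncol = 4L)
  # boundary tris above the plane follow the elements above
  btris <- mesh$btris
  bcen_z <- (mesh$nodes[btris[, 1], 3] + mesh$nodes[btris[, 2], 3] +
             mesh$nodes[btris[, 3], 3]) / 3
  babove <- bcen_z > z0 + tol
  btris[babove, ] <- matrix(twin[btris[babove, ]], ncol = 3L)
  # interface triangles: faces of lower elements lying in the plane
  faces <- rbind(mesh$tets[, c(2, 3, 4)], mesh$tets[, c(1, 4, 3)],
                 mesh$tets[, c(1, 2, 4)], mesh$tets[, c(1, 3, 2)])
  below <- rep(!above, 4L)
  inplane <- below &
    abs(mesh$nodes[faces[, 1], 3] - z0) < tol &
    abs(mesh$nodes[faces[, 2], 3] - z0) < tol &
    abs(mesh$nodes[faces[, 3], 3] - z0) < tol
  tris_minus <- faces[inplane, , drop = FALSE]
  interface <- list(label = label, tris = tris_minus,
                    pairs = cbind(minus = on_plane,
                                  plus = twin[on_plane]))
  new_labeled_mesh(nodes, tets, mesh$region, mesh$region_labels,
                   btris, mesh$blabel, mesh$boundary_labels,
                   contact_labels = mesh$contact_labels,
                   interface = interface,
                   provenance = c(mesh$provenance, list(interface_z = z0)))
}

#' Disk contact on a homogeneous block (spreading-resistance fixture)
#'
#' A cylinder of radius and depth `extent * a` whose top face carries a
#' boundary-fitted equipotential disk contact of radius `a` (label
#' `CONTACT_DISK`); the bottom and lateral surfaces are grounded,
#' approximating the half-space far field.  The mesh is fine (size `a / n_a`)
#' at the contact and its singular edge, growing geometrically outwards both
#' radially and in depth.
#'
#' @param a disk radius (m).
#' @param n_a rings across the disk radius.
#' @param extent domain radius and depth in units of `a`.
#' @param growth geometric grading factor away from the contact.
#' @return A `labeled_mesh` with region `medium`.
#' @export
make_disk_block_mesh <- function(a, n_a = 6L, extent = 40, growth = 1.4) {
  stopifnot(a > 0, n_a >= 2, extent > 4, growth > 1)
  # rings clustered quadratically at the singular disk edge r = a, growing
  # geometrically outwards from the edge; depths likewise from the surface
  inside <- a * sin((pi / 2) * seq_len(n_a) / n_a)
  h_edge <- a - inside[n_a - 1L]
  grade_out <- function(start, h, lim) {
    out <- start
    while (out[length(out)] < lim) {
      h <- h * growth
      out <- c(out, min(out[length(out)] + h, lim))
    }
    out
  }
  radii <- grade_out(c(inside, a + h_edge), h_edge, extent * a)
  depths <- grade_out(c(0, h_edge), h_edge, extent * a)
  n_ring <- length(radii)
  m <- max(16L, 4L * ceiling(n_a / 2))
  th <- 2 * pi * (seq_len(m) - 1L) / m
  corr <- sqrt(2 * pi / (m * sin(2 * pi / m)))
  nxt <- c(seq_len(m)[-1L], 1L)
  tid <- function(l, i) 1L + (l - 1L) * m + i
  n_t <- 1L + n_ring * m
  # template triangles with their ring level
  tri <- list(cbind(1L, tid(1L, seq_len(m)), tid(1L, nxt)))
  lev <- rep(1L, m)
  for (l in seq_len(n_ring - 1L)) {
    q1 <- tid(l, seq_len(m)); q2 <- tid(l, nxt)
    q3 <- tid(l + 1L, nxt); q4 <- tid(l + 1L, seq_len(m))
    tri <- c(tri, list(cbind(q1, q2, q3), cbind(q1, q3, q4)))
    lev <- c(lev, rep(l + 1L, 2L * m))
  }
  tri <- do.call(rbind, tri)
  loc <- rbind(c(0, 0), cbind(corr * rep(radii, each = m) * cos(th),
                              corr * rep(radii, each = m) * sin(th)))
  nz <- length(depths)
  nodes <- do.call(rbind, lapply(depths, function(d)
    cbind(loc[, 1], loc[, 2], -d)))
  nt_tri <- nrow(tri)
  bot <- tri[rep(seq_len(nt_tri), nz - 1L), , drop = FALSE] +
    rep((seq_len(nz - 1L) - 1L) * n_t, each = nt_tri)
  tets <- split_prisms(bot, bot + n_t)
  # boundaries: contact = top-cap triangles within the disk; ground = bottom
  # cap + outer lateral surface; rest of the top insulated
  disk_tris <- tri[lev <= n_a, , drop = FALSE]
  bottom <- tri + (nz - 1L) * n_t
  e1 <- tid(n_ring, seq_len(m)); e2 <- tid(n_ring, nxt)
  aa <- rep(e1, nz - 1L) + rep((seq_len(nz - 1L) - 1L) * n_t, each = m)
  bb <- rep(e2, nz - 1L) + rep((seq_len(nz - 1L) - 1L) * n_t, each = m)
  lateral <- split_quads(aa, bb, bb + n_t, aa + n_t)
  btris <- rbind(disk_tris, bottom, lateral)
  blab <- c(rep("CONTACT_DISK", nrow(disk_tris)),
            rep("GROUND_OUTER", nrow(bottom) + nrow(lateral)))
  boundary_labels <- unique(blab)
  new_labeled_mesh(nodes, tets, rep(1L, nrow(tets)), "medium",
                   btris, match(blab, boundary_labels), boundary_labels,
                   contact_labels = "CONTACT_DISK",
                   provenance = list(kind = "disk_cylinder", a = a, n_a = n_a,
                                     extent = extent, growth = growth))
}

#' Concentric spherical shell mesh
#'
#' The medium between an inner sphere of radius `a` (equipotential contact
#' `CONTACT_INNER`) and an outer grounded sphere of radius `b`, meshed by
#' projecting a cube-face quad grid onto the sphere and extruding radially
#' with geometric spacing.
#'
#' @param a,b inner and outer radii (m), `a < b`.
#' @param n_surf quads per cube-face edge.
#' @param n_rad radial layers.
#' @return A `labeled_mesh` with region `medium`.
#' @export
make_spherical_shell_mesh <- function(a, b, n_surf = 8L, n_rad = 8L) {
  stopifnot(a > 0, b > a, n_surf >= 2, n_rad >= 2)
  u <- seq(-1, 1, length.out = n_surf + 1L)
  # cube surface points for all 6 faces, deduplicated on exact coordinates
  pts <- list(); quads <- list()
  offset <- 0L
  grid_id <- function(i, j) i + (j - 1L) * (n_surf + 1L)
  for (f in 1:6) {
    U <- rep(u, times = n_surf + 1L)
    V <- rep(u, each = n_surf + 1L)
    P <- switch(f,
                cbind(1, U, V), cbind(-1, U, V),
                cbind(U, 1, V), cbind(U, -1, V),
                cbind(U, V, 1), cbind(U, V, -1))
    pts[[f]] <- P
    ii <- rep(seq_len(n_surf), times = n_surf)
    jj <- rep(seq_len(n_surf), each = n_surf)
    quads[[f]] <- offset + cbind(grid_id(ii, jj), grid_id(ii + 1L, jj),
                                 grid_id(ii + 1L, jj + 1L), grid_id(ii, jj + 1L))
    offset <- offset + (n_surf + 1L)^2
  }
  P <- do.call(rbind, pts)
  Q <- do.call(rbind, quads)
  key <- paste(P[, 1], P[, 2], P[, 3], sep = "/")
  uid <- match(key, unique(key))
  P <- P[!duplicated(key), , drop = FALSE]
  Q <- matrix(uid[Q], ncol = 4L)
  S <- P / sqrt(rowSums(P^2))  # project to unit sphere
  ns <- nrow(S)
  tris <- split_quads(Q[, 1], Q[, 2], Q[, 3], Q[, 4])
  radii <- a * (b / a)^(seq(0, 1, length.out = n_rad + 1L))
  nodes <- do.call(rbind, lapply(radii, function(r) r * S))
  bot <- tris[rep(seq_len(nrow(tris)), n_rad), , drop = FALSE] +
    rep((seq_len(n_rad) - 1L) * ns, each = nrow(tris))
  tets <- split_prisms(bot, bot + ns)
  btris <- rbind(tris, tris + n_rad * ns)
  blab <- c(rep("CONTACT_INNER", nrow(tris)), rep("GROUND_OUTER", nrow(tris)))
  boundary_labels <- unique(blab)
  new_labeled_mesh(nodes, tets, rep(1L, nrow(tets)), "medium",
                   btris, match(blab, boundary_labels), boundary_labels,
                   contact_labels = "CONTACT_INNER",
                   provenance = list(kind = "spherical_shell", a = a, b = b,
                                     n_surf = n_surf, n_rad = n_rad))
}

# ---------------------------------------------------------------------------
# convergence study

#' Mesh-convergence study of an electrode impedance
#'
#' Recomputes the impedance of the first active contact on a sequence of
#' decreasing mesh sizes, Richardson-extrapolates the limit and estimates the
#' observed convergence order from the three finest meshes.
#'
#' @param geom a `geometry_model`, or a function `h -> labeled_mesh`.
#' @param cond a [conductivity_table()].
#' @param src a [source_spec()].
#' @param h_sequence strictly decreasing mesh sizes (m); at least 3.
#' @param opts [solver_options()].
#' @param oracle optional exact impedance for error reporting.
#' @return An object of class `convergence_report`: tibble `results` (h, Z,
#'   n_elements), `Z_extrapolated`, `observed_order`, and `rel_error` vs
#'   `oracle` (if given).
#' @export
run_convergence_study <- function(geom, cond, src, h_sequence,
                                  opts = solver_options(), oracle = NULL) {
  h <- as.numeric(h_sequence)
  if (length(h) < 3 || any(diff(h) >= 0))
    stop("h_sequence must be >= 3 strictly decreasing sizes", call. = FALSE)
  factory <- if (is.function(geom)) geom else function(hh)
    generate_mesh(geom, mesh_options(target_size_near_m = hh,
                                     target_size_far_m = 4 * hh))
  Z <- numeric(length(h))
  nel <- integer(length(h))
  for (i in seq_along(h)) {
    mesh <- factory(h[i])
    nel[i] <- nrow(mesh$tets)
    field <- solve_potential(mesh, cond, src, opts)
    Z[i] <- compute_impedance(field, src$active_contacts[1], src)$Z_ohm
  }
  m <- length(h)
  h1 <- h[m - 2]; h2 <- h[m - 1]; h3 <- h[m]
  Z1 <- Z[m - 2]; Z2 <- Z[m - 1]; Z3 <- Z[m]
  p <- NA_real_; Zstar <- NA_real_
  if (abs(Z2 - Z3) > 0 && sign(Z1 - Z2) == sign(Z2 - Z3)) {
    fp <- function(pp) (Z1 - Z3) / (Z2 - Z3) - (h1^pp - h3^pp) / (h2^pp - h3^pp)
    p <- tryCatch(stats::uniroot(fp, c(0.05, 6))$root, error = function(e) NA_real_)
    if (is.finite(p))
      Zstar <- (Z3 * h2^p - Z2 * h3^p) / (h2^p - h3^p)
  }
  structure(list(
    results = tibble::tibble(h_m = h, Z_ohm = Z, n_elements = nel),
    Z_extrapolated = Zstar,
    observed_order = p,
    oracle = oracle,
    rel_error = if (!is.null(oracle)) abs(Z - oracle) / abs(oracle) else NULL
  ), class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("<convergence_report>\n")
  print(x$results)
  if (is.finite(x$observed_order))
    cat(sprintf("  observed order %.2f, extrapolated Z* = %.6g ohm\n",
                x$observed_order, x$Z_extrapolated))
  if (!is.null(x$oracle))
    cat(sprintf("  oracle %.6g ohm, finest rel. error %.3g\n",
                x$oracle, x$rel_error[length(x$rel_error)]))
  invisible(x)
}
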