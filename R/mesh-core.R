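# Low-level tetrahedral mesh machinery shared by the swept-tube, box and
# spherical-shell meshers.  All meshers are deterministic: identical inputs
# give byte-identical meshes.

# signed volumes of tets (m x 4 index matrix into nodes)
tet_signed_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
   b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
   b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])) / 6
}

# flip node order where needed so all volumes are positive
orient_tets <- function(nodes, tets) {
  v <- tet_signed_volumes(nodes, tets)
  neg <- which(v < 0)
  if (length(neg)) {
    tmp <- tets[neg, 3L]
    tets[neg, 3L] <- tets[neg, 4L]
    tets[neg, 4L] <- tmp
  }
  tets
}

# triangle areas (k x 3 index matrix)
tri_areas <- function(nodes, tris) {
  a <- nodes[tris[, 1], , drop = FALSE]
  u <- nodes[tris[, 2], , drop = FALSE] - a
  v <- nodes[tris[, 3], , drop = FALSE] - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# Split prisms into 3 tets each with the lowest-global-index diagonal rule,
# so that adjacent prisms (and quad boundary faces split with split_quads)
# always agree on the quad-face diagonals.  bot/top are n x 3 matrices of
# node ids, top[, i] vertically adjacent to bot[, i].
split_prisms <- function(bot, top) {
  W <- cbind(bot, top)  # columns V1..V6, V(i+3) above Vi
  n <- nrow(W)
  amin <- max.col(-W, ties.method = "first")
  # relabel so the smallest global id sits at V1 (rotations and the
  # upside-down flip both map prism quads to prism quads)
  perms <- rbind(
    c(1, 2, 3, 4, 5, 6),
    c(2, 3, 1, 5, 6, 4),
    c(3, 1, 2, 6, 4, 5),
    c(4, 6, 5, 1, 3, 2),
    c(5, 4, 6, 2, 1, 3),
    c(6, 5, 4, 3, 2, 1))
  V <- matrix(0L, n, 6L)
  for (p in 1:6) {
    rows <- which(amin == p)
    if (length(rows)) V[rows, ] <- W[rows, perms[p, ], drop = FALSE]
  }
  # remaining free quad (V2, V3, V6, V5): diagonal through its smallest id
  caseA <- pmin(V[, 2], V[, 6]) < pmin(V[, 3], V[, 5])
  tets <- matrix(0L, 3L * n, 4L)
  ia <- which(caseA); ib <- which(!caseA)
  if (length(ia)) {
    A <- V[ia, , drop = FALSE]
    tets[3 * (ia - 1) + 1, ] <- A[, c(1, 2, 3, 6), drop = FALSE]
    tets[3 * (ia - 1) + 2, ] <- A[, c(1, 2, 6, 5), drop = FALSE]
    tets[3 * (ia - 1) + 3, ] <- A[, c(1, 5, 6, 4), drop = FALSE]
  }
  if (length(ib)) {
    B <- V[ib, , drop = FALSE]
    tets[3 * (ib - 1) + 1, ] <- B[, c(1, 2, 3, 5), drop = FALSE]
    tets[3 * (ib - 1) + 2, ] <- B[, c(1, 5, 3, 6), drop = FALSE]
    tets[3 * (ib - 1) + 3, ] <- B[, c(1, 5, 6, 4), drop = FALSE]
  }
  tets
}

# Split quads (cycles a-b-c-d) into 2 triangles with the diagonal through the
# smallest global id; matches the side-face diagonals chosen by split_prisms.
split_quads <- function(a, b, c, d) {
  useAC <- pmin(a, c) < pmin(b, d)
  t1 <- cbind(ifelse(useAC, a, a), ifelse(useAC, b, b), ifelse(useAC, c, d))
  t2 <- cbind(ifelse(useAC, a, b), ifelse(useAC, c, c), ifelse(useAC, d, d))
  rbind(t1, t2)
}

# boundary faces of a tet mesh: faces appearing exactly once
boundary_faces <- function(tets) {
  faces <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 4, 3)],
                 tets[, c(1, 2, 4)], tets[, c(1, 3, 2)])
  k1 <- pmin(faces[, 1], faces[, 2], faces[, 3])
  k3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
  k2 <- as.integer(faces[, 1]) + faces[, 2] + faces[, 3] - k1 - k3
  ord <- order(k1, k2, k3)
  n <- length(ord)
  s1 <- k1[ord]; s2 <- k2[ord]; s3 <- k3[ord]
  same_next <- c(s1[-n] == s1[-1] & s2[-n] == s2[-1] & s3[-n] == s3[-1], FALSE)
  same_prev <- c(FALSE, same_next[-n])
  faces[ord[!(same_next | same_prev)], , drop = FALSE]
}

# per-tet radius ratio quality 3 * inradius / circumradius (regular tet = 1)
tet_radius_ratio <- function(nodes, tets) {
  vol <- abs(tet_signed_volumes(nodes, tets))
  f1 <- tri_areas(nodes, tets[, c(2, 3, 4), drop = FALSE])
  f2 <- tri_areas(nodes, tets[, c(1, 3, 4), drop = FALSE])
  f3 <- tri_areas(nodes, tets[, c(1, 2, 4), drop = FALSE])
  f4 <- tri_areas(nodes, tets[, c(1, 2, 3), drop = FALSE])
  r_in <- 3 * vol / (f1 + f2 + f3 + f4)
  # circumradius via the standard product-of-edge formula
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE]
  c <- nodes[tets[, 3], , drop = FALSE]
  d <- nodes[tets[, 4], , drop = FALSE]
  len <- function(u) sqrt(rowSums(u^2))
  A <- len(d - a) * len(c - b)  # opposite edge products
  B <- len(d - b) * len(c - a)
  C <- len(d - c) * len(b - a)
  p <- sqrt((A + B + C) * (-A + B + C) * (A - B + C) * (A + B - C))
  r_circ <- p / (24 * vol)
  3 * r_in / r_circ
}

# assemble a labeled_mesh object, dropping unused nodes and orienting tets
new_labeled_mesh <- function(nodes, tets, region, region_labels,
                             btris, blabel, boundary_labels,
                             contact_labels = character(),
                             interface = NULL,
                             node_station = NULL, station_s = NULL,
                             provenance = list()) {
  used <- sort(unique(c(as.vector(tets), as.vector(btris),
                        if (!is.null(interface))
                          c(as.vector(interface$tris),
                            as.vector(interface$pairs)))))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  tets <- matrix(remap[tets], ncol = 4L)
  btris <- matrix(remap[btris], ncol = 3L)
  if (!is.null(interface)) {
    interface$tris <- matrix(remap[interface$tris], ncol = 3L)
    interface$pairs <- matrix(remap[interface$pairs], ncol = 2L)
  }
  if (!is.null(node_station)) node_station <- node_station[used]
  tets <- orient_tets(nodes, tets)
  vol <- tet_signed_volumes(nodes, tets)
  if (any(vol <= 0)) {
    bad <- region_labels[region[which(vol <= 0)[1]]]
    stop(sprintf(
      "meshing failure: %d degenerate/inverted elements (first in region '%s')",
      sum(vol <= 0), bad), call. = FALSE)
  }
  structure(list(
    nodes = nodes,
    tets = tets,
    region = as.integer(region),
    region_labels = region_labels,
    btris = btris,
    blabel = as.integer(blabel),
    boundary_labels = boundary_labels,
    contact_labels = contact_labels,
    interface = interface,
    node_station = node_station,
    station_s = station_s,
    provenance = provenance
  ), class = "labeled_mesh")
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat(sprintf("<labeled_mesh> %d nodes, %d tets, %d boundary tris\n",
              nrow(x$nodes), nrow(x$tets), nrow(x$btris)))
  cat("  regions:", paste(x$region_labels, collapse = ", "), "\n")
  cat("  boundaries:", paste(x$boundary_labels, collapse = ", "), "\n")
  if (!is.null(x$interface))
    cat(sprintf("  thin-layer interface: %s (%d node pairs, %d tris)\n",
                x$interface$label, nrow(x$interface$pairs),
                nrow(x$interface$tris)))
  invisible(x)
}

# nodes belonging to boundary triangles of a given label
boundary_nodes <- function(mesh, label) {
  id <- match(label, mesh$boundary_labels)
  if (is.na(id)) return(integer())
  sort(unique(as.vector(mesh$btris[mesh$blabel == id, , drop = FALSE])))
}

#' Total area of a labelled boundary surface
#'
#' @param mesh a `labeled_mesh`.
#' @param label boundary surface label (e.g. `"CONTACT_E1"`, `"GROUND_OUTER"`).
#' @return Area in m^2 (0 if the label is absent).
#' @export
boundary_area <- function(mesh, label) {
  id <- match(label, mesh$boundary_labels)
  if (is.na(id)) return(0)
  sum(tri_areas(mesh$nodes, mesh$btris[mesh$blabel == id, , drop = FALSE]))
}

#' Per-region mesh volumes
#'
#' @param mesh a `labeled_mesh`.
#' @return Named numeric vector of summed tetrahedron volumes (m^3) per
#'   region label.
#' @export
mesh_region_volumes <- function(mesh) {
  v <- abs(tet_signed_volumes(mesh$nodes, mesh$tets))
  out <- vapply(seq_along(mesh$region_labels),
                function(r) sum(v[mesh$region == r]), numeric(1))
  names(out) <- mesh$region_labels
  out
}

#' Mesh quality summary
#'
#' Reports the radius-ratio quality statistic (3 * inradius / circumradius;
#' 1 for the regular tetrahedron), element counts and volumes per region, and
#' boundary areas per label.  Elements with quality below `floor` are listed
#' as flagged.
#'
#' @param mesh a `labeled_mesh`.
#' @param floor quality floor below which elements are flagged.
#' @return A list with `quality` (min/median/mean), `n_flagged`, `flagged`
#'   (element indices), `regions` (tibble) and `boundaries` (tibble).
#' @export
mesh_quality_report <- function(mesh, floor = 0.02) {
  q <- tet_radius_ratio(mesh$nodes, mesh$tets)
  v <- abs(tet_signed_volumes(mesh$nodes, mesh$tets))
  regions <- tibble::tibble(
    region = mesh$region_labels,
    n_elements = vapply(seq_along(mesh$region_labels),
                        function(r) sum(mesh$region == r), integer(1)),
    volume_m3 = vapply(seq_along(mesh$region_labels),
                       function(r) sum(v[mesh$region == r]), numeric(1)),
    min_quality = vapply(seq_along(mesh$region_labels), function(r) {
      qq <- q[mesh$region == r]
      if (length(qq)) min(qq) else NA_real_
    }, numeric(1)))
  boundaries <- tibble::tibble(
    label = mesh$boundary_labels,
    n_tris = vapply(seq_along(mesh$boundary_labels),
                    function(b) sum(mesh$blabel == b), integer(1)),
    area_m2 = vapply(mesh$boundary_labels,
                     function(lb) boundary_area(mesh, lb), numeric(1)))
  flagged <- which(q < floor)
  list(quality = c(min = min(q), median = stats::median(q), mean = mean(q)),
       n_flagged = length(flagged), flagged = flagged,
       regions = regions, boundaries = boundaries)
}
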