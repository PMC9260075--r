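# Quasi-static potential problem on a labelled tetrahedral mesh:
#   div(sigma grad V) = 0
# with V = 0 on the ground surface, floating-equipotential contacts carrying
# a prescribed net current, natural (zero-flux) conditions on all other
# exterior surfaces, and a thin-layer contact-impedance condition across the
# stria interface (flux-continuous, potential jump (t/sigma_stria) * j_n).
#
# Contacts are realised by tying all nodes of a contact patch to a single
# master dof; the reduced system stays symmetric positive definite, so a
# current injection is just a unit load on the terminal dof and reciprocity
# of the transfer-impedance matrix holds to solver tolerance.

#' Source specification for a potential solve
#'
#' @param active_contacts character vector of boundary labels driven
#'   simultaneously (each carrying `injected_current_A`).
#' @param injected_current_A net current per active contact (A); the default
#'   is the 34 uA probe current commonly used for impedance measurements.
#' @param ground boundary label held at 0 V.
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(active_contacts,
                        injected_current_A = 34e-6,
                        ground = "GROUND_OUTER") {
  if (!length(active_contacts))
    stop("active_contacts must be non-empty", call. = FALSE)
  if (!is.finite(injected_current_A) || injected_current_A <= 0)
    stop("injected_current_A must be positive", call. = FALSE)
  structure(list(active_contacts = as.character(active_contacts),
                 injected_current_A = injected_current_A,
                 ground = ground),
            class = "source_spec")
}

#' Solver options
#'
#' @param method `"cholesky"` (sparse direct, default) or `"cg"`
#'   (Jacobi-preconditioned conjugate gradients).
#' @param tol relative-residual tolerance for the iterative solver and the
#'   post-hoc residual check.
#' @param max_iter iteration cap for `"cg"`.
#' @param contact_mode `"equipotential"` (floating terminal with prescribed
#'   net current; platinum contacts with zero interface impedance) or
#'   `"uniform_current"` (prescribed uniform current density over the patch;
#'   cross-check mode).
#' @param inactive_mode `"floating"` (inactive inserted contacts are tied
#'   equipotential surfaces carrying zero net current) or `"grounded"`.
#' @param ground_mode `"outer"` (whole outer boundary labelled
#'   `GROUND_OUTER`) or `"patch"` (only the basal portion of it, emulating an
#'   extracochlear return electrode).
#' @param ground_patch_length_m arc-length extent of the basal ground patch.
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(method = c("cholesky", "cg"),
                           tol = 1e-10, max_iter = 20000L,
                           contact_mode = c("equipotential", "uniform_current"),
                           inactive_mode = c("floating", "grounded"),
                           ground_mode = c("outer", "patch"),
                           ground_patch_length_m = 2e-3) {
  structure(list(method = match.arg(method),
                 tol = tol, max_iter = as.integer(max_iter),
                 contact_mode = match.arg(contact_mode),
                 inactive_mode = match.arg(inactive_mode),
                 ground_mode = match.arg(ground_mode),
                 ground_patch_length_m = ground_patch_length_m),
            class = "solver_options")
}

# ---------------------------------------------------------------------------
# assembly

# per-region P1 stiffness matrices (conductivity-independent) plus the
# unscaled thin-layer jump coupling; combine with combine_conductivity()
fem_assembly <- function(mesh) {
  n <- nrow(mesh$nodes)
  tets <- mesh$tets
  a <- mesh$nodes[tets[, 1], , drop = FALSE]
  e1 <- mesh$nodes[tets[, 2], , drop = FALSE] - a
  e2 <- mesh$nodes[tets[, 3], , drop = FALSE] - a
  e3 <- mesh$nodes[tets[, 4], , drop = FALSE] - a
  det <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
         e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
         e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  vol <- det / 6
  # rows of inv(J) * det  (adjugate), J = [e1; e2; e3]
  i11 <- e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]
  i12 <- e1[, 3] * e3[, 2] - e1[, 2] * e3[, 3]
  i13 <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  i21 <- e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3]
  i22 <- e1[, 1] * e3[, 3] - e1[, 3] * e3[, 1]
  i23 <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  i31 <- e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]
  i32 <- e1[, 2] * e3[, 1] - e1[, 1] * e3[, 2]
  i33 <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  # gradients of the barycentric functions 2..4 are the columns of inv(J)^T,
  # i.e. grad(lambda_k)_x = inv(J)[x, k-1]; grad(lambda_1) = -sum
  gx <- cbind(-(i11 + i12 + i13), i11, i12, i13) / det
  gy <- cbind(-(i21 + i22 + i23), i21, i22, i23) / det
  gz <- cbind(-(i31 + i32 + i33), i31, i32, i33) / det
  Ks <- vector("list", length(mesh$region_labels))
  names(Ks) <- mesh$region_labels
  for (r in seq_along(mesh$region_labels)) {
    sel <- mesh$region == r
    if (!any(sel)) next
    ii <- jj <- xx <- vector("list", 16L)
    idx <- 0L
    for (p in 1:4) for (q in 1:4) {
      idx <- idx + 1L
      ii[[idx]] <- tets[sel, p]
      jj[[idx]] <- tets[sel, q]
      xx[[idx]] <- vol[sel] * (gx[sel, p] * gx[sel, q] +
                               gy[sel, p] * gy[sel, q] +
                               gz[sel, p] * gz[sel, q])
    }
    Ks[[r]] <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                    x = unlist(xx), dims = c(n, n))
  }
  C <- NULL
  if (!is.null(mesh$interface)) {
    tris <- mesh$interface$tris
    plus_map <- seq_len(n)
    plus_map[mesh$interface$pairs[, 1]] <- mesh$interface$pairs[, 2]
    trip <- matrix(plus_map[tris], ncol = 3L)
    ar <- tri_areas(mesh$nodes, tris)
    Mloc <- matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3, 3) / 12
    ii <- jj <- xx <- list()
    for (p in 1:3) for (q in 1:3) {
      w <- ar * Mloc[p, q]
      ii <- c(ii, list(tris[, p], trip[, p], tris[, p], trip[, p]))
      jj <- c(jj, list(tris[, q], trip[, q], trip[, q], tris[, q]))
      xx <- c(xx, list(w, w, -w, -w))
    }
    C <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(n, n))
    C <- Matrix::drop0(C)
  }
  list(K_region = Ks, C_jump = C, n = n)
}

# total conductance matrix for a conductivity table
combine_conductivity <- function(asm, mesh, cond) {
  check_cond_covers(cond, mesh$region_labels)
  sigma <- cond$sigma_S_per_m
  K <- NULL
  for (r in names(asm$K_region)) {
    if (is.null(asm$K_region[[r]])) next
    term <- region_sigma(cond, r) * asm$K_region[[r]]
    K <- if (is.null(K)) term else K + term
  }
  if (!is.null(asm$C_jump)) {
    g <- sigma[["stria_vascularis"]] / cond$stria_thickness_m
    K <- K + g * asm$C_jump
  }
  K
}

# ---------------------------------------------------------------------------
# reduction: ground elimination + contact-node tying

ground_node_set <- function(mesh, src, opts) {
  gn <- boundary_nodes(mesh, src$ground)
  if (!length(gn))
    stop("ground surface '", src$ground, "' not found in mesh (singular system)",
         call. = FALSE)
  if (opts$ground_mode == "patch") {
    if (is.null(mesh$node_station))
      stop("ground_mode 'patch' needs a swept mesh with station data",
           call. = FALSE)
    s_node <- mesh$station_s[mesh$node_station[gn]]
    gn <- gn[s_node <= opts$ground_patch_length_m]
    if (!length(gn))
      stop("ground patch is empty; increase ground_patch_length_m",
           call. = FALSE)
  }
  gn
}

# build the reduction operator: interior nodes keep their own dof, terminal
# (tied contact) nodes share one dof per contact, ground nodes are dropped
build_reduction <- function(mesh, terminal_labels, ground_nodes) {
  n <- nrow(mesh$nodes)
  dof <- integer(n)
  dof[ground_nodes] <- -1L
  term_nodes <- lapply(terminal_labels, function(lb) {
    tn <- boundary_nodes(mesh, lb)
    if (!length(tn)) stop("contact '", lb, "' not found in mesh", call. = FALSE)
    setdiff(tn, ground_nodes)
  })
  for (tn in term_nodes) dof[tn] <- -2L
  free <- which(dof == 0L)
  dof[free] <- seq_along(free)
  n_red <- length(free) + length(terminal_labels)
  term_dof <- length(free) + seq_along(terminal_labels)
  names(term_dof) <- terminal_labels
  for (k in seq_along(terminal_labels)) dof[term_nodes[[k]]] <- term_dof[k]
  keep <- dof > 0L
  P <- Matrix::sparseMatrix(i = which(keep), j = dof[keep], x = 1,
                            dims = c(n, n_red))
  list(P = P, dof = dof, term_dof = term_dof, n_red = n_red)
}

# Jacobi-preconditioned conjugate gradients on a sparse SPD matrix
pcg_solve <- function(A, b, tol = 1e-10, max_iter = 20000L) {
  d <- Matrix::diag(A)
  x <- numeric(length(b))
  r <- b
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(list(x = x, iterations = 0L, residual = 0))
  z <- r / d
  p <- z
  rz <- sum(r * z)
  it <- 0L
  repeat {
    it <- it + 1L
    Ap <- as.vector(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / nb
    if (res <= tol || it >= max_iter) break
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  if (res > tol)
    stop(sprintf("conjugate gradients failed to converge: residual %.3g after %d iterations",
                 res, it), call. = FALSE)
  list(x = x, iterations = it, residual = res)
}

# internal reusable solver context (factor once, many right-hand sides)
fem_system <- function(mesh, cond, src, opts, asm = NULL) {
  if (is.null(asm)) asm <- fem_assembly(mesh)
  K <- combine_conductivity(asm, mesh, cond)
  gn <- ground_node_set(mesh, src, opts)
  inactive <- setdiff(mesh$contact_labels, src$active_contacts)
  if (opts$inactive_mode == "grounded" && length(inactive)) {
    for (lb in inactive) gn <- union(gn, boundary_nodes(mesh, lb))
    inactive <- character()
  }
  terminals <- if (opts$contact_mode == "equipotential") {
    c(src$active_contacts, inactive)
  } else {
    inactive
  }
  red <- build_reduction(mesh, terminals, gn)
  Kr <- Matrix::forceSymmetric(Matrix::crossprod(red$P, K %*% red$P))
  ch <- if (opts$method == "cholesky")
    Matrix::Cholesky(Kr, LDL = FALSE, perm = TRUE) else NULL
  list(asm = asm, K = K, Kr = Kr, ch = ch, red = red,
       ground_nodes = gn, mesh = mesh, cond = cond, opts = opts)
}

fem_solve_rhs <- function(sys, b) {
  if (!is.null(sys$ch)) {
    x <- as.vector(Matrix::solve(sys$ch, b))
    res <- sqrt(sum((as.vector(sys$Kr %*% x) - b)^2)) / sqrt(sum(b^2))
    list(x = x, iterations = 0L, residual = res)
  } else {
    pcg_solve(sys$Kr, b, sys$opts$tol, sys$opts$max_iter)
  }
}

# ---------------------------------------------------------------------------
# public solve

#' Solve the quasi-static potential problem
#'
#' Computes the weak solution of `div(sigma grad V) = 0` on the mesh with the
#' ground surface at 0 V, each active contact driven with net current
#' `injected_current_A` (as a floating equipotential terminal by default),
#' zero normal flux on all other exterior surfaces, and the stria thin-layer
#' jump condition where the mesh carries an interface.
#'
#' @param mesh a `labeled_mesh`.
#' @param cond a [conductivity_table()] covering every mesh region.
#' @param src a [source_spec()].
#' @param opts a [solver_options()].
#' @return An object of class `potential_field`: `values_V` (nodal potential,
#'   identically 0 on the ground surface), `contact_potentials_V` (named, one
#'   equipotential value per contact terminal), and `solve_stats`.
#' @export
solve_potential <- function(mesh, cond, src, opts = solver_options()) {
  stopifnot(inherits(mesh, "labeled_mesh"), inherits(cond, "conductivity_table"),
            inherits(src, "source_spec"), inherits(opts, "solver_options"))
  sys <- fem_system(mesh, cond, src, opts)
  b <- numeric(sys$red$n_red)
  if (opts$contact_mode == "equipotential") {
    b[sys$red$term_dof[src$active_contacts]] <- src$injected_current_A
  } else {
    # uniform current density over each active patch
    for (lb in src$active_contacts) {
      id <- match(lb, mesh$boundary_labels)
      if (is.na(id)) stop("contact '", lb, "' not found in mesh", call. = FALSE)
      tris <- mesh$btris[mesh$blabel == id, , drop = FALSE]
      ar <- tri_areas(mesh$nodes, tris)
      w <- src$injected_current_A * ar / sum(ar) / 3
      load <- numeric(nrow(mesh$nodes))
      for (p in 1:3) {
        tab <- tapply(w, tris[, p], sum)
        load[as.integer(names(tab))] <- load[as.integer(names(tab))] + tab
      }
      b <- b + as.vector(Matrix::crossprod(sys$red$P, load))
    }
  }
  sol <- fem_solve_rhs(sys, b)
  V <- as.vector(sys$red$P %*% sol$x)
  cp <- contact_potentials(mesh, V, sys, src, opts)
  structure(list(values_V = V,
                 contact_potentials_V = cp,
                 solve_stats = list(method = opts$method,
                                    iterations = sol$iterations,
                                    residual = sol$residual,
                                    n_dof = sys$red$n_red)),
            class = "potential_field")
}

contact_potentials <- function(mesh, V, sys, src, opts) {
  labs <- union(src$active_contacts, mesh$contact_labels)
  out <- vapply(labs, function(lb) {
    td <- sys$red$term_dof
    if (lb %in% names(td)) {
      nodes <- boundary_nodes(mesh, lb)
      V[nodes[1]]
    } else {
      id <- match(lb, mesh$boundary_labels)
      if (is.na(id)) return(NA_real_)
      tris <- mesh$btris[mesh$blabel == id, , drop = FALSE]
      ar <- tri_areas(mesh$nodes, tris)
      sum(ar * (V[tris[, 1]] + V[tris[, 2]] + V[tris[, 3]]) / 3) / sum(ar)
    }
  }, numeric(1))
  names(out) <- labs
  out
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("<potential_field> %d nodes, V in [%.4g, %.4g] V\n",
              length(x$values_V), min(x$values_V), max(x$values_V)))
  cat(sprintf("  solve: %s, residual %.2e%s\n", x$solve_stats$method,
              x$solve_stats$residual,
              if (x$solve_stats$iterations > 0)
                sprintf(", %d iterations", x$solve_stats$iterations) else ""))
  invisible(x)
}

#' Electrode-to-ground impedance of one contact
#'
#' `Z_el = V_el / I_el`: the contact equipotential value divided by the
#' injected current.
#'
#' @param field a [solve_potential()] result.
#' @param contact_id contact label (must be active in `src`).
#' @param src the [source_spec()] used for the solve.
#' @return An object of class `impedance_record` (a one-row tibble with
#'   `contact`, `I_A`, `V_V`, `Z_ohm`).
#' @export
compute_impedance <- function(field, contact_id, src) {
  stopifnot(inherits(field, "potential_field"), inherits(src, "source_spec"))
  if (!contact_id %in% src$active_contacts)
    stop("contact '", contact_id, "' is not active in this source", call. = FALSE)
  V_el <- field$contact_potentials_V[[contact_id]]
  if (is.null(V_el) || is.na(V_el))
    stop("contact '", contact_id, "' not present in the field", call. = FALSE)
  out <- tibble::tibble(contact = contact_id,
                        I_A = src$injected_current_A,
                        V_V = V_el,
                        Z_ohm = V_el / src$injected_current_A)
  class(out) <- c("impedance_record", class(out))
  out
}

#' Transfer-impedance matrix across contacts
#'
#' Activates each contact in turn with current `I` (all others floating) and
#' records the potential of every contact terminal: `Z[i, j]` is the voltage
#' at contact `i` per unit current injected at contact `j`.  The matrix is
#' symmetric up to solver tolerance (reciprocity of the self-adjoint
#' operator) and its diagonal dominates each column.
#'
#' @param mesh a `labeled_mesh` with contact labels.
#' @param cond a [conductivity_table()].
#' @param contacts contact labels to include (default: all in the mesh).
#' @param I injected current (A); cancels out of `Z`.
#' @param opts a [solver_options()].
#' @return A named `length(contacts)` square matrix (ohm).
#' @export
transfer_impedance_matrix <- function(mesh, cond,
                                      contacts = mesh$contact_labels,
                                      I = 34e-6, opts = solver_options()) {
  stopifnot(length(contacts) >= 1L)
  src <- source_spec(contacts[1], I)
  sys <- fem_system(mesh, cond, src, opts)
  td <- sys$red$term_dof
  missing <- setdiff(contacts, names(td))
  if (length(missing))
    stop("contacts not in mesh: ", paste(missing, collapse = ", "),
         call. = FALSE)
  Z <- matrix(NA_real_, length(contacts), length(contacts),
              dimnames = list(contacts, contacts))
  for (j in seq_along(contacts)) {
    b <- numeric(sys$red$n_red)
    b[td[contacts[j]]] <- I
    sol <- fem_solve_rhs(sys, b)
    Z[, j] <- sol$x[td[contacts]] / I
  }
  Z
}

#' Total current through the ground surface
#'
#' Integrated reaction flux over the ground nodes; for a converged solve it
#' equals the total injected current (current conservation).
#'
#' @param mesh a `labeled_mesh`.
#' @param cond a [conductivity_table()].
#' @param field a [solve_potential()] result on the same mesh.
#' @param src the [source_spec()] used.
#' @param opts the [solver_options()] used.
#' @return Current (A) leaving through the ground surface.
#' @export
ground_current <- function(mesh, cond, field, src, opts = solver_options()) {
  asm <- fem_assembly(mesh)
  K <- combine_conductivity(asm, mesh, cond)
  r <- as.vector(K %*% field$values_V)
  gn <- ground_node_set(mesh, src, opts)
  -sum(r[gn])
}
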