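# Configuration handling and result export.  Units are SI throughout (m,
# S/m, A, V, ohm); CSV columns carry unit suffixes.

#' Default run configuration
#'
#' A plain nested list of every tunable parameter with its default: geometry,
#' array, conductivities (the standard table values and the 34 uA probe
#' current), mesh and solver options, protocol selection and seed.
#'
#' @return An object of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    geometry = unclass(cochlea_params()),
    array = unclass(electrode_array_spec())[
      setdiff(names(electrode_array_spec()), "contact_ids")],
    conductivity = list(
      sigma_S_per_m = as.list(conductivity_table()$sigma_S_per_m),
      stria_thickness_m = conductivity_table()$stria_thickness_m),
    mesh = unclass(mesh_options()),
    solver = unclass(solver_options()),
    protocol = list(
      name = "sweep-insertion",
      injected_current_A = 34e-6,
      recorded_contacts = c("E1", "E6", "E11", "E16"),
      sensitivity_layer = "scala_tympani",
      sensitivity_factors = c(0.90, 0.95, 1.00, 1.05, 1.10),
      axis = "x",
      n_positions = 8L),
    output = list(dir = "results"),
    seed = 1L
  ), class = "run_config")
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key: ", full, call. = FALSE)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key ", full, " must be a mapping", call. = FALSE)
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Load (and validate) a run configuration
#'
#' Reads a YAML or JSON configuration file, fills every unset key with its
#' default, rejects unknown keys, and validates all sections by constructing
#' the corresponding parameter objects.  An empty file yields the pure
#' defaults (standard conductivity table, 34 uA).
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  cfg <- merge_config(unclass(default_config()), user)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  do.call(cochlea_params, cfg$geometry)
  do.call(electrode_array_spec, cfg$array)
  conductivity_table(unlist(cfg$conductivity$sigma_S_per_m),
                     cfg$conductivity$stria_thickness_m)
  do.call(mesh_options, cfg$mesh)
  do.call(solver_options, cfg$solver)
  if (!is.finite(cfg$protocol$injected_current_A) ||
      cfg$protocol$injected_current_A <= 0)
    stop("protocol.injected_current_A must be positive", call. = FALSE)
  invisible(TRUE)
}

# materialise parameter objects from a config
config_objects <- function(cfg) {
  list(params = do.call(cochlea_params, cfg$geometry),
       array = do.call(electrode_array_spec, cfg$array),
       cond = conductivity_table(unlist(cfg$conductivity$sigma_S_per_m),
                                 cfg$conductivity$stria_thickness_m),
       mesh_opts = do.call(mesh_options, cfg$mesh),
       solver_opts = do.call(solver_options, cfg$solver))
}

#' Write a run configuration to file
#'
#' @param cfg a `run_config`.
#' @param path destination (`.json` or `.yaml`).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(unclass(cfg), path, precision = 15L)
  }
  invisible(path)
}

#' Hash of a run configuration
#'
#' MD5 of the canonical JSON serialisation; used to key result sidecars.
#'
#' @param cfg a `run_config` (or any serialisable list).
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

# ---------------------------------------------------------------------------
# result export

#' Export results as CSV plus a JSON sidecar
#'
#' Writes a tidy CSV of the records and a JSON sidecar with provenance
#' (config hash if supplied, seed, package version, timestamp).  Re-export
#' over existing files is idempotent apart from the sidecar timestamp.
#'
#' @param x an `impedance_map`, `sensitivity_result` or `convergence_report`.
#' @param outdir output directory (created if needed).
#' @param prefix file-name prefix (defaults to the object's protocol/class).
#' @param cfg optional `run_config` hashed into the sidecar.
#' @param seed optional seed recorded in the sidecar.
#' @return Character vector of files written, invisibly.
#' @export
export_results <- function(x, outdir, prefix = NULL, cfg = NULL, seed = NULL) {
  UseMethod("export_results")
}

export_files <- function(records, extra, outdir, prefix, cfg, seed) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(outdir, paste0(prefix, ".csv"))
  utils::write.csv(records, csv, row.names = FALSE)
  sidecar <- c(list(
    written = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package_version = as.character(utils::packageVersion("cochleaVC")),
    config_hash = if (!is.null(cfg)) config_hash(cfg) else NULL,
    seed = seed), extra)
  js <- file.path(outdir, paste0(prefix, "_metadata.json"))
  jsonlite::write_json(sidecar[!vapply(sidecar, is.null, logical(1))], js,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, js))
}

#' @export
export_results.impedance_map <- function(x, outdir, prefix = NULL, cfg = NULL,
                                         seed = NULL) {
  md <- attr(x, "metadata")
  if (is.null(prefix)) prefix <- if (!is.null(md$protocol)) md$protocol
                                 else "impedance_map"
  extra <- md[setdiff(names(md), c("skipped", "mesh_opts", "solver_opts",
                                   "placement"))]
  extra$n_records <- nrow(x)
  export_files(as.data.frame(x), extra, outdir, prefix, cfg, seed)
}

#' @export
export_results.sensitivity_result <- function(x, outdir, prefix = "sensitivity",
                                              cfg = NULL, seed = NULL) {
  extra <- list(layer = x$layer, factors = x$factors,
                recorded_contact = x$recorded_contact, axis = x$axis,
                normalized_deviation = x$normalized_deviation,
                max_absolute_shift = x$max_absolute_shift)
  export_files(as.data.frame(x$profiles), extra, outdir, prefix, cfg, seed)
}

#' @export
export_results.convergence_report <- function(x, outdir, prefix = "convergence",
                                              cfg = NULL, seed = NULL) {
  extra <- list(Z_extrapolated = x$Z_extrapolated,
                observed_order = x$observed_order,
                oracle = x$oracle)
  export_files(as.data.frame(x$results), extra, outdir, prefix, cfg, seed)
}

# ---------------------------------------------------------------------------
# mesh / field file formats

#' Write a mesh (with optional fields) as ASCII VTU
#'
#' XML `UnstructuredGrid` with tetrahedral cells, region labels as cell data
#' and any nodal fields (e.g. a potential) as point data; readable by
#' ParaView and VTK.
#'
#' @param mesh a `labeled_mesh`.
#' @param path output `.vtu` file.
#' @param point_data named list of nodal vectors.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(format(mesh$nodes[, 1], digits = 12),
                   format(mesh$nodes[, 2], digits = 12),
                   format(mesh$nodes[, 3], digits = 12)), con)
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(paste(mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                   mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(as.character(seq_len(m) * 4L), con)
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(rep("10", m), con)
  w('</DataArray></Cells>')
  w('<CellData Scalars="region"><DataArray type="Int32" Name="region" format="ascii">')
  writeLines(as.character(mesh$region), con)
  w('</DataArray></CellData>')
  if (length(point_data)) {
    w('<PointData>')
    for (nm in names(point_data)) {
      w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
      writeLines(format(point_data[[nm]], digits = 12), con)
      w('</DataArray>')
    }
    w('</PointData>')
  }
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}

#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Tetrahedra carry their region index as the physical tag; boundary
#' triangles carry `100 + boundary index`.  Physical names are recorded for
#' both.  Thin-layer interface data has no MSH representation and is not
#' written.
#'
#' @param mesh a `labeled_mesh`.
#' @param path output `.msh` file.
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("$MeshFormat"); w("2.2 0 8"); w("$EndMeshFormat")
  w("$PhysicalNames")
  w(as.character(length(mesh$region_labels) + length(mesh$boundary_labels)))
  for (i in seq_along(mesh$boundary_labels))
    w(sprintf('2 %d "%s"', 100L + i, mesh$boundary_labels[i]))
  for (i in seq_along(mesh$region_labels))
    w(sprintf('3 %d "%s"', i, mesh$region_labels[i]))
  w("$EndPhysicalNames")
  w("$Nodes"); w(as.character(nrow(mesh$nodes)))
  writeLines(paste(seq_len(nrow(mesh$nodes)),
                   format(mesh$nodes[, 1], digits = 17),
                   format(mesh$nodes[, 2], digits = 17),
                   format(mesh$nodes[, 3], digits = 17)), con)
  w("$EndNodes")
  ntri <- nrow(mesh$btris); ntet <- nrow(mesh$tets)
  w("$Elements"); w(as.character(ntri + ntet))
  if (ntri)
    writeLines(paste(seq_len(ntri), 2L, 2L, 100L + mesh$blabel,
                     100L + mesh$blabel,
                     mesh$btris[, 1], mesh$btris[, 2], mesh$btris[, 3]), con)
  writeLines(paste(ntri + seq_len(ntet), 4L, 2L, mesh$region, mesh$region,
                   mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                   mesh$tets[, 4]), con)
  w("$EndElements")
  invisible(path)
}

#' Read a Gmsh MSH 2.2 ASCII mesh
#'
#' Inverse of [write_msh()] (regions, boundary surfaces and physical names;
#' no interface data).
#'
#' @param path `.msh` file.
#' @return A `labeled_mesh`.
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  sect <- function(name) {
    i0 <- which(lines == paste0("$", name)) + 1L
    i1 <- which(lines == paste0("$End", name)) - 1L
    if (!length(i0) || !length(i1)) stop("missing MSH section ", name,
                                         call. = FALSE)
    lines[i0:i1]
  }
  pn <- sect("PhysicalNames")[-1L]
  pn_dim <- as.integer(sub("^(\\d+) .*", "\\1", pn))
  pn_tag <- as.integer(sub("^\\d+ (\\d+) .*", "\\1", pn))
  pn_name <- sub('^\\d+ \\d+ "(.*)"$', "\\1", pn)
  nd <- sect("Nodes")[-1L]
  nodes <- matrix(as.numeric(unlist(strsplit(nd, " +"))), ncol = 4L,
                  byrow = TRUE)[, 2:4, drop = FALSE]
  el <- sect("Elements")[-1L]
  tok <- strsplit(el, " +")
  type <- vapply(tok, function(t) as.integer(t[2]), integer(1))
  tag <- vapply(tok, function(t) as.integer(t[4]), integer(1))
  tris <- do.call(rbind, lapply(tok[type == 2L], function(t)
    as.integer(t[6:8])))
  tri_tag <- tag[type == 2L]
  tets <- do.call(rbind, lapply(tok[type == 4L], function(t)
    as.integer(t[6:9])))
  tet_tag <- tag[type == 4L]
  region_labels <- pn_name[pn_dim == 3L][order(pn_tag[pn_dim == 3L])]
  boundary_labels <- pn_name[pn_dim == 2L][order(pn_tag[pn_dim == 2L])]
  new_labeled_mesh(nodes, tets, tet_tag, region_labels,
                   tris, tri_tag - 100L, boundary_labels,
                   contact_labels = grep("^CONTACT_", boundary_labels,
                                         value = TRUE),
                   provenance = list(kind = "msh_import", path = path))
}

#' Write boundary surfaces as ASCII STL
#'
#' @param mesh a `labeled_mesh`.
#' @param path output `.stl` file.
#' @param label optional boundary label to restrict to (default: all).
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, label = NULL) {
  tris <- mesh$btris
  if (!is.null(label)) {
    id <- match(label, mesh$boundary_labels)
    if (is.na(id)) stop("boundary label not found: ", label, call. = FALSE)
    tris <- tris[mesh$blabel == id, , drop = FALSE]
  }
  a <- mesh$nodes[tris[, 1], , drop = FALSE]
  b <- mesh$nodes[tris[, 2], , drop = FALSE]
  c <- mesh$nodes[tris[, 3], , drop = FALSE]
  u <- b - a; v <- c - a
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  nn <- sqrt(rowSums(nrm^2)); nn[nn == 0] <- 1
  nrm <- nrm / nn
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  fmt <- function(p) paste(format(p[, 1], digits = 9),
                           format(p[, 2], digits = 9),
                           format(p[, 3], digits = 9))
  block <- paste0("facet normal ", fmt(nrm), "\nouter loop\nvertex ",
                  fmt(a), "\nvertex ", fmt(b), "\nvertex ", fmt(c),
                  "\nendloop\nendfacet")
  writeLines(block, con)
  writeLines("endsolid mesh", con)
  invisible(path)
}
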