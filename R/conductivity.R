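#' Tissue conductivity table
#'
#' Isotropic conductivities (S/m) for every tissue and material region of the
#' cochlea volume conductor, following the values most commonly used in
#' computational models of the cochlea.  The scalae carry perilymph at
#' 1.43 S/m; the stria vascularis (0.0053 S/m) is never meshed as a solid but
#' enters through a thin-layer contact-impedance interface of thickness
#' `stria_thickness_m`.
#'
#' @param sigma_S_per_m named numeric vector of conductivities (S/m).  Values
#'   given here override the defaults; unknown names are added as extra
#'   regions.
#' @param stria_thickness_m thin-layer thickness used by the stria interface
#'   condition (m).
#'
#' @return An object of class `conductivity_table`: a list with elements
#'   `sigma_S_per_m` (named numeric) and `stria_thickness_m`.
#' @export
#' @examples
#' conductivity_table()$sigma_S_per_m[["scala_tympani"]]  # 1.43
conductivity_table <- function(sigma_S_per_m = NULL,
                               stria_thickness_m = 3.0e-5) {
  sigma <- c(
    scala_tympani   = 1.43,
    scala_vestibuli = 1.43,
    cochlea_wall    = 0.3,
    basilar_membrane = 0.0125,
    spiral_ligament = 1.67,
    stria_vascularis = 0.0053,
    spiral_ganglion = 0.33,
    artery          = 0.32,
    bone            = 0.0156,
    silicone        = 1e-7
  )
  if (!is.null(sigma_S_per_m)) {
    if (is.null(names(sigma_S_per_m)) || any(!nzchar(names(sigma_S_per_m))))
      stop("sigma_S_per_m must be a named vector", call. = FALSE)
    sigma[names(sigma_S_per_m)] <- as.numeric(sigma_S_per_m)
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("all conductivities must be positive and finite", call. = FALSE)
  if (!is.finite(stria_thickness_m) || stria_thickness_m <= 0)
    stop("stria_thickness_m must be positive", call. = FALSE)
  structure(list(sigma_S_per_m = sigma,
                 stria_thickness_m = stria_thickness_m),
            class = "conductivity_table")
}

#' Scale selected conductivities by a factor
#'
#' Used by the conductivity-sensitivity protocol: returns a copy of `cond`
#' with the conductivity of `layers` multiplied by `factor`.
#'
#' @param cond a [conductivity_table()].
#' @param layers character vector of region names, or `"all"` to scale every
#'   entry (including the stria interface conductivity).
#' @param factor positive scale factor.
#' @return A new `conductivity_table`.
#' @export
perturb_conductivity <- function(cond, layers = "scala_tympani", factor = 1) {
  stopifnot(inherits(cond, "conductivity_table"))
  if (!is.finite(factor) || factor <= 0)
    stop("factor must be positive", call. = FALSE)
  sigma <- cond$sigma_S_per_m
  if (identical(layers, "all")) {
    sigma <- sigma * factor
  } else {
    missing <- setdiff(layers, names(sigma))
    if (length(missing))
      stop("unknown tissue layer(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    sigma[layers] <- sigma[layers] * factor
  }
  structure(list(sigma_S_per_m = sigma,
                 stria_thickness_m = cond$stria_thickness_m),
            class = "conductivity_table")
}

#' @export
print.conductivity_table <- function(x, ...) {
  cat("<conductivity_table> (S/m)\n")
  s <- x$sigma_S_per_m
  for (nm in names(s)) cat(sprintf("  %-17s %g\n", nm, s[[nm]]))
  cat(sprintf("  stria thin-layer thickness: %g um\n",
              x$stria_thickness_m * 1e6))
  invisible(x)
}

# the electrode carrier region is silicone
REGION_ALIASES <- c(carrier = "silicone")

# conductivity of a mesh region (resolving material aliases)
region_sigma <- function(cond, label) {
  key <- if (label %in% names(REGION_ALIASES)) REGION_ALIASES[[label]] else label
  cond$sigma_S_per_m[[key]]
}

# internal: check a conductivity table covers all mesh regions
check_cond_covers <- function(cond, region_labels) {
  keys <- ifelse(region_labels %in% names(REGION_ALIASES),
                 REGION_ALIASES[region_labels], region_labels)
  missing <- setdiff(keys, names(cond$sigma_S_per_m))
  if (length(missing))
    stop("conductivity table lacks entries for region(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
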