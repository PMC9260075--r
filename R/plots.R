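# Quick-look figures; impedances are plotted in kilo-ohm to match the usual
# presentation of cochlear-implant impedance data.

#' Plot a full-insertion depth profile
#'
#' @param profile an `impedance_map` from [run_insertion_depth_profile()] (or
#'   the k = n slice of a sequential run with columns `contact`, `Z_ohm`).
#' @return A ggplot object.
#' @export
plot_depth_profile <- function(profile) {
  df <- as.data.frame(profile)
  df$contact <- factor(df$contact,
                       levels = df$contact[order(-seq_len(nrow(df)))])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contact, y = .data$Z_ohm / 1e3,
                                   group = 1)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "contact (basal to apical)",
                  y = "impedance to ground (kΩ)") +
    ggplot2::theme_minimal()
}

#' Plot proximity-sweep profiles
#'
#' Impedance versus in-plane offset, one line per recorded contact.
#'
#' @param map an `impedance_map` from [run_proximity_sweep()].
#' @param axis which offset column to use (`"x"` or `"y"`).
#' @return A ggplot object.
#' @export
plot_proximity_profiles <- function(map, axis = c("x", "y")) {
  axis <- match.arg(axis)
  df <- as.data.frame(map)
  df$offset_mm <- (if (axis == "x") df$x_offset_m else df$y_offset_m) * 1e3
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset_mm, y = .data$Z_ohm / 1e3,
                                   colour = .data$contact)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("%s offset (mm)", axis),
                  y = "impedance to ground (kΩ)", colour = "contact") +
    ggplot2::theme_minimal()
}

#' Plot conductivity-sensitivity profiles
#'
#' Mid-scala-normalised impedance profiles, one line per conductivity scale
#' factor.
#'
#' @param sens a `sensitivity_result`.
#' @return A ggplot object.
#' @export
plot_sensitivity_profiles <- function(sens) {
  df <- as.data.frame(sens$profiles)
  df$factor <- factor(df$factor)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset_m * 1e3,
                                   y = .data$Z_normalized,
                                   colour = .data$factor)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "offset (mm)", y = "Z / Z(mid-scala)",
                  colour = "σ factor") +
    ggplot2::theme_minimal()
}
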