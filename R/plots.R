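# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a voltage matrix
#'
#' @param object A `voltage_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.voltage_matrix <- function(object, ...) {
  df <- tidy.voltage_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$stimulating, .data$recording,
                                   fill = .data$mV)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "stimulating contact", y = "recording contact",
                  fill = "mV") +
    ggplot2::coord_fixed()
}

#' Column profiles of a voltage matrix
#'
#' Mean-subtracted recording profiles for selected stimulating contacts,
#' matching how telemetry profiles are usually displayed.
#'
#' @param x A `voltage_matrix`.
#' @param stimulating Stimulating contacts to show.
#' @param center Subtract each column's off-diagonal mean.
#' @return A ggplot.
#' @export
plot_contact_profiles <- function(x, stimulating = c(4, 11, 18),
                                  center = TRUE) {
  df <- tidy.voltage_matrix(x)
  df <- df[df$stimulating %in% stimulating, ]
  if (center) {
    df <- dplyr::mutate(dplyr::group_by(df, .data$stimulating),
                        mV = .data$mV - mean(.data$mV))
    df <- dplyr::ungroup(df)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$recording, .data$mV,
                                   colour = factor(.data$stimulating))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "recording contact",
                  y = if (center) "mV (mean subtracted)" else "mV",
                  colour = "stimulating")
}

#' Error curve of a conductivity-ratio optimization
#'
#' @param object An `r_opt`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.r_opt <- function(object, ...) {
  df <- tidy.r_opt(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$R, .data$rms_mV)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[df$minimum, ], colour = "red", size = 2) +
    ggplot2::labs(x = expression(R == sigma[ST] / sigma[bone]),
                  y = "RMS error (mV)")
}

#' Excitation profile along the cochlea
#'
#' @param object An `excitation_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.excitation_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$arc_mm, .data$probability)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(data = object[object$fired, ],
                        ggplot2::aes(colour = .data$site_class), size = 0.6) +
    ggplot2::scale_colour_manual(values = c(peripheral = "grey40",
                                            central = "black")) +
    ggplot2::labs(x = "position along basilar membrane (mm)",
                  y = "firing probability", colour = "site")
}

#' Mid-modiolar slice of a labelled volume
#'
#' @param vol A `labeled_volume`.
#' @param axis Slice normal (`"y"` shows the classic mid-modiolar view).
#' @param at Coordinate (mm) of the slice; defaults to the domain center.
#' @return A ggplot.
#' @export
plot_volume_slice <- function(vol, axis = "y", at = NULL) {
  ai <- match(axis, c("x", "y", "z"))
  coord <- list(vol$x, vol$y, vol$z)[[ai]]
  at <- at %||% vol$center[ai]
  k <- which.min(abs(coord - at))
  sl <- switch(axis, x = vol$labels[k, , ], y = vol$labels[, k, ],
               z = vol$labels[, , k])
  other <- setdiff(c("x", "y", "z"), axis)
  c1 <- list(vol$x, vol$y, vol$z)[[match(other[1], c("x", "y", "z"))]]
  c2 <- list(vol$x, vol$y, vol$z)[[match(other[2], c("x", "y", "z"))]]
  df <- tibble::tibble(a = rep(c1, times = length(c2)),
                       b = rep(c2, each = length(c1)),
                       label = vol$label_levels[as.vector(sl)])
  ggplot2::ggplot(df[df$label != "exterior", ],
                  ggplot2::aes(.data$a, .data$b, fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = paste0(other[1], " (mm)"), y = paste0(other[2], " (mm)"))
}
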