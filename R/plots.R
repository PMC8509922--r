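#' Plot prevalence fractions of a screen
#'
#' @param object A `"bmp_screen"`.
#' @param ... Unused.
#' @return A ggplot: most-abundant share per tetramer class.
#' @method autoplot bmp_screen
#' @export
autoplot.bmp_screen <- function(object, ...) {
  prev <- prevalence_summary(object)
  ggplot2::ggplot(prev, ggplot2::aes(
    x = stats::reorder(.data$class, -.data$percent), y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "most abundant (% of parameter space)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a ligand response or scenario sweep
#'
#' @param object A `"bmp_response_curve"`.
#' @param classes Classes to show (`NULL` = all).
#' @param ... Unused.
#' @return A ggplot: concentration vs ligand, log-log, one line per class.
#' @method autoplot bmp_response_curve
#' @export
autoplot.bmp_response_curve <- function(object, classes = NULL, ...) {
  df <- if (is.null(classes)) object else object[object$class %in% classes, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ligand, y = .data$concentration,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "ligand (nM)", y = "tetramer (nM)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a receptor titration
#'
#' @param object A `"bmp_titration_curve"`.
#' @param classes Classes to show (`NULL` = all).
#' @param ... Unused.
#' @return A ggplot: concentration vs the titrated receptor total.
#' @method autoplot bmp_titration_curve
#' @export
autoplot.bmp_titration_curve <- function(object, classes = NULL, ...) {
  df <- if (is.null(classes)) object else object[object$class %in% classes, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$concentration,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste0(df$receptor[1], " (nM)"), y = "tetramer (nM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot dynamic ranges as detection-to-saturation segments
#'
#' Reproduces the sensor view: one horizontal segment per tetramer class
#' from its detection floor to its saturation concentration; classes that
#' cannot form a single complex appear as a point at the scan floor.
#'
#' @param dr A `"bmp_dynamic_range"` from [dynamic_range()].
#' @return A ggplot.
#' @export
plot_dynamic_range <- function(dr) {
  stopifnot(inherits(dr, "bmp_dynamic_range"))
  df <- dr
  df$class <- stats::reorder(df$class, df$fold)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      data = df[df$formable, ],
      ggplot2::aes(x = .data$lower, xend = .data$upper,
                   y = .data$class, yend = .data$class)) +
    ggplot2::geom_point(
      data = df[df$formable, ],
      ggplot2::aes(x = .data$lower, y = .data$class), colour = "red") +
    ggplot2::geom_point(
      data = df[df$formable, ],
      ggplot2::aes(x = .data$upper, y = .data$class), colour = "black") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ligand (nM)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot winner fractions of a dynamic-range screen
#'
#' @param object A `"bmp_dr_screen"`.
#' @param ... Unused.
#' @return A ggplot: fraction of receptor space where each class has the
#'   largest dynamic range.
#' @method autoplot bmp_dr_screen
#' @export
autoplot.bmp_dr_screen <- function(object, ...) {
  ws <- dr_winner_summary(object)
  ggplot2::ggplot(ws, ggplot2::aes(
    x = stats::reorder(.data$class, -.data$percent), y = .data$percent)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "largest dynamic range (% of receptor space)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Slice view of a screen along two receptor axes
#'
#' A generic two-receptor slice of the prevalence screen at fixed ligand,
#' gamma and the remaining receptor: tiles coloured by the most abundant
#' tetramer class.
#'
#' @param screen A `"bmp_screen"`.
#' @param x,y Receptor axes (`"BmpR1"`, `"Acvr1"`, `"TypeII"`).
#' @param ligand,gamma Fixed levels (defaults: medians present in the
#'   screen).
#' @param fixed Named value for the remaining receptor (default: its
#'   median level).
#' @return A ggplot.
#' @export
plot_screen_slice <- function(screen, x = "BmpR1", y = "Acvr1",
                              ligand = NULL, gamma = NULL, fixed = NULL) {
  stopifnot(inherits(screen, "bmp_screen"))
  other <- setdiff(c("BmpR1", "Acvr1", "TypeII"), c(x, y))
  pick_mid <- function(v) sort(unique(v))[ceiling(length(unique(v)) / 2)]
  ligand <- ligand %||% pick_mid(screen$ligand)
  gamma <- gamma %||% pick_mid(screen$gamma)
  fixed_val <- if (is.null(fixed)) pick_mid(screen[[other]]) else fixed
  df <- screen[screen$ligand == ligand & screen$gamma == gamma &
                 screen[[other]] == fixed_val, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                   fill = .data$most_abundant)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = paste0(x, " (nM)"), y = paste0(y, " (nM)"), fill = NULL,
                  title = sprintf("ligand %.3g nM, %s %.3g nM, gamma %g",
                                  ligand, other, fixed_val, gamma)) +
    ggplot2::theme_minimal()
}
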