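#' Plot methods
#'
#' `autoplot()` methods give the standard views of each result type: the
#' log-compressed B-mode image, the ROI mask overlay, the
#' impedance-vs-thickness curve with error bars, per-line backscatter values,
#' and the per-condition TER drop summary.
#'
#' @param object The object to plot.
#' @param dynamic_range Display dynamic range in dB for B-mode images.
#' @param ... Unused.
#' @return A ggplot object.
#' @name qusim-plots
NULL

bmode_df <- function(scan) {
  env <- compute_envelope(scan)
  db <- env$db
  depths <- sample_depth_mm(seq_len(ncol(db)), env$sampling_rate,
                            env$sound_speed_assumed, env$depth_origin)
  lat <- (seq_len(nrow(db)) - 1) * env$line_pitch
  tidyr::expand_grid(line = seq_len(nrow(db)), sample = seq_len(ncol(db))) |>
    dplyr::mutate(
      lateral_mm = lat[.data$line],
      depth_mm = depths[.data$sample],
      db = as.vector(t(db))[(.data$line - 1) * ncol(db) + .data$sample]
    )
}

#' @rdname qusim-plots
#' @method autoplot bscan
#' @export
autoplot.bscan <- function(object, dynamic_range = 40, ...) {
  df <- bmode_df(object)
  df$db <- pmax(df$db, -dynamic_range)
  ggplot2::ggplot(df, ggplot2::aes(.data$lateral_mm, .data$depth_mm,
                                   fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "dB") +
    ggplot2::labs(x = "Lateral position (mm)", y = "Depth (mm)",
                  title = "B-mode envelope image") +
    ggplot2::theme_minimal()
}

#' @rdname qusim-plots
#' @method autoplot roi_mask
#' @export
autoplot.roi_mask <- function(object, ...) {
  m <- object$mask
  depths <- sample_depth_mm(seq_len(ncol(m)), object$sampling_rate,
                            object$sound_speed_assumed, object$depth_origin)
  lat <- (seq_len(nrow(m)) - 1) * (object$line_pitch %||% 1)
  idx <- which(m, arr.ind = TRUE)
  df <- tibble(lateral_mm = lat[idx[, 1]], depth_mm = depths[idx[, 2]])
  ggplot2::ggplot(df, ggplot2::aes(.data$lateral_mm, .data$depth_mm)) +
    ggplot2::geom_raster(fill = "steelblue") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Lateral position (mm)", y = "Depth (mm)",
                  title = sprintf("ROI mask (d1 = %.2f, d2 = %.2f mm)",
                                  object$d1, object$d2)) +
    ggplot2::theme_minimal()
}

#' @rdname qusim-plots
#' @method autoplot qus_impedance_sweep
#' @export
autoplot.qus_impedance_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$thickness_mm, .data$mean_mrayl)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_mrayl - .data$sd_mrayl,
      ymax = .data$mean_mrayl + .data$sd_mrayl
    )) +
    ggplot2::labs(x = "Segmented tissue thickness (mm)",
                  y = "Acoustic impedance (MRayl)",
                  title = "Impedance vs segmentation thickness",
                  subtitle = "Error bars: standard deviation across lines") +
    ggplot2::theme_minimal()
}

#' @rdname qusim-plots
#' @method autoplot qus_bsc
#' @export
autoplot.qus_bsc <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$line, .data$mu_b)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = object$mean, linetype = 2) +
    ggplot2::labs(x = "A-line", y = expression(mu[B]),
                  title = "Per-line backscatter coefficient") +
    ggplot2::theme_minimal()
}

#' @rdname qusim-plots
#' @method autoplot ter_summary
#' @export
autoplot.ter_summary <- function(object, ...) {
  df <- dplyr::mutate(object, condition = factor(
    .data$condition, levels = c("MB_only", "US_only", "US_plus_MB")
  ))
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$mean_percent_drop)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_percent_drop - .data$sem_percent_drop,
      ymax = .data$mean_percent_drop + .data$sem_percent_drop
    ), width = 0.2) +
    ggplot2::labs(x = NULL, y = "TER drop from baseline (%)",
                  title = "Barrier-function response to insonation") +
    ggplot2::theme_minimal()
}
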