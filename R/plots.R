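#' Target plot of coronal screw errors
#'
#' Scatter of per-screw (ML, SI) errors at a chosen analysis plane (tail,
#' mid-pedicle or tip), centred on the planned position, with grey reference
#' rings (default 2 and 4 mm), a star at the signed mean error and an
#' axis-aligned ellipse whose semi-axes are two standard deviations of the
#' signed per-axis errors. Right-sided screws are already mirrored into the
#' medial-positive convention by the metrics layer, so both sides pool
#' directly. The mean and ellipse parameters are taken verbatim from
#' [summarize_accuracy()] -- the plot never recomputes statistics.
#'
#' @param records Accuracy record tibble.
#' @param plane `"tail"`, `"mid"` or `"tip"`.
#' @param ring_radii Reference ring radii, mm (positive, ascending).
#' @param show_mean,show_ellipse Toggle the mean marker / 2 SD ellipse.
#' @param covariance If `TRUE`, draw the covariance (tilted) 2 SD ellipse
#'   instead of the axis-aligned per-axis one.
#' @return A ggplot object; the summary used is attached as
#'   `attr(, "summary")`.
#' @export
plot_target <- function(records, plane = c("mid", "tail", "tip"),
                        ring_radii = c(2, 4), show_mean = TRUE,
                        show_ellipse = TRUE, covariance = FALSE) {
  plane <- match.arg(plane)
  stopifnot(nrow(records) >= 1, all(ring_radii > 0),
            !is.unsorted(ring_radii))
  ml_col <- paste0(plane, "_ML")
  si_col <- paste0(plane, "_SI")
  df <- tibble::tibble(ML = records[[ml_col]], SI = records[[si_col]])
  summ <- summarize_accuracy(records, "all")
  s_ml <- summ[summ$metric == ml_col, ]
  s_si <- summ[summ$metric == si_col, ]
  rings <- dplyr::bind_rows(lapply(ring_radii, function(r) {
    th <- seq(0, 2 * pi, length.out = 181)
    tibble::tibble(x = r * cos(th), y = r * sin(th), r = r)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ML, y = .data$SI)) +
    ggplot2::geom_path(data = rings,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$r),
                       colour = "grey60", linewidth = 0.4,
                       inherit.aes = FALSE) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80", linewidth = 0.3) +
    ggplot2::geom_point(colour = "steelblue", alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "ML error (mm, medial +)", y = "SI error (mm, superior +)",
                  title = paste0(plane, " plane")) +
    ggplot2::theme_minimal()
  if (show_ellipse && nrow(df) >= 2) {
    th <- seq(0, 2 * pi, length.out = 181)
    if (covariance) {
      S <- stats::cov(cbind(df$ML, df$SI))
      e <- eigen(S, symmetric = TRUE)
      ax <- 2 * sqrt(pmax(e$values, 0))
      pts <- cbind(ax[1] * cos(th), ax[2] * sin(th)) %*% t(e$vectors)
      ell <- tibble::tibble(x = pts[, 1] + s_ml$sme, y = pts[, 2] + s_si$sme)
    } else {
      ell <- tibble::tibble(x = s_ml$sme + s_ml$precision_2sd * cos(th),
                            y = s_si$sme + s_si$precision_2sd * sin(th))
    }
    p <- p + ggplot2::geom_polygon(data = ell,
                                   ggplot2::aes(x = .data$x, y = .data$y),
                                   fill = "mediumpurple", alpha = 0.2,
                                   inherit.aes = FALSE)
  } else if (show_ellipse && nrow(df) == 1) {
    warning("single record: plotting without a precision ellipse")
  }
  if (show_mean) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(x = s_ml$sme, y = s_si$sme),
      ggplot2::aes(x = .data$x, y = .data$y),
      shape = 8, size = 3, colour = "purple4", inherit.aes = FALSE)
  }
  attr(p, "summary") <- summ
  p
}

#' Render a target plot to an image file
#'
#' @inheritParams plot_target
#' @param out Output image path (`.png` or `.svg`).
#' @param width,height Figure size in inches.
#' @return `out`, invisibly; the plotted data table (records and summary)
#'   is written alongside as `<out>.csv`.
#' @export
render_target_plot <- function(records, out, plane = "mid",
                               ring_radii = c(2, 4), width = 4, height = 4) {
  p <- plot_target(records, plane, ring_radii)
  ggplot2::ggsave(out, p, width = width, height = height, dpi = 150)
  readr::write_csv(attr(p, "summary"), paste0(out, ".csv"))
  invisible(out)
}

#' @export
autoplot.accuracy_records <- function(object, plane = "mid", ...) {
  plot_target(tibble::as_tibble(object), plane = plane, ...)
}
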