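#' Plot time-resolved curves with ribbons
#'
#' One line per well or replicate group over time. For an
#' [aggregate_replicates()] result the replicate SD is drawn as a shaded
#' ribbon around each curve; for a [windowed_slope()] result the ribbon is
#' the local-fit residual standard error. Colors, line types and legend
#' labels come from the layout when one is given.
#'
#' @param table An `assay_table`, `aggregated_table` or `slope_table`.
#' @param layout Optional [plate_layout()] supplying styles.
#' @param ribbon Draw the SD/residual ribbon when available.
#' @return A ggplot object.
#' @export
plot_curves <- function(table, layout = NULL, ribbon = TRUE) {
  if (inherits(table, "slope_table")) {
    long <- tidy.slope_table(table)
    names(long)[names(long) == "series"] <- "group"
    long$lo <- long$slope - long$residual
    long$hi <- long$slope + long$residual
    long$y <- long$slope
  } else if (inherits(table, "aggregated_table")) {
    long <- tidy.aggregated_table(table)
    long$lo <- long$mean - long$sd
    long$hi <- long$mean + long$sd
    long$y <- long$mean
  } else {
    long <- tidyr::pivot_longer(tibble::as_tibble(table), -"time",
                                names_to = "group", values_to = "y")
    ribbon <- FALSE
  }
  long$group <- factor(long$group, levels = unique(long$group))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$y,
                                          color = .data$group))
  if (ribbon)
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi, group = .data$group),
      fill = "grey70", alpha = 0.5, color = NA)
  p <- p + ggplot2::geom_line() +
    ggplot2::labs(x = paste0("time (", time_unit(table), ")"),
                  y = value_unit(table), color = NULL) +
    ggplot2::theme_minimal()
  p + layout_scales(layout, long$group)
}

layout_scales <- function(layout, groups) {
  if (is.null(layout)) return(NULL)
  sty <- unique(layout[layout$role != "excluded",
                       c("group", "color", "legend")])
  sty <- sty[!is.na(sty$color) & sty$group %in% levels(groups), ]
  if (!nrow(sty)) return(NULL)
  ggplot2::scale_color_manual(values = setNames(sty$color, sty$group),
                              labels = setNames(sty$legend, sty$group),
                              na.value = "grey40")
}

#' @export
autoplot.aggregated_table <- function(object, ...) plot_curves(object, ...)

#' @export
autoplot.slope_table <- function(object, ...) plot_curves(object, ...)

#' Plot dose-response fits at selected time points
#'
#' Overlays the observed dose-response points and fitted log-logistic curves
#' of the fits nearest the requested snapshot times (six evenly spaced
#' snapshots by default), the classic companion panel to an IC50 trajectory.
#'
#' @param trajectory An [fit_ic50_over_time()] result.
#' @param times Snapshot times; defaults to 6 evenly spaced converged fits.
#' @return A ggplot object (dose on a log axis; zero doses are drawn at half
#'   the smallest nonzero dose).
#' @export
plot_fit_snapshots <- function(trajectory, times = NULL) {
  fits <- attr(trajectory, "fits")
  ok <- which(trajectory$converged)
  if (!length(ok)) stop("no converged fits to plot", call. = FALSE)
  if (is.null(times))
    times <- trajectory$time[ok[unique(round(seq(1, length(ok),
                                                 length.out = 6)))]]
  idx <- ok[vapply(times, function(ti)
    which.min(abs(trajectory$time[ok] - ti)), integer(1))]
  idx <- unique(idx)
  pts <- purrr::map_dfr(idx, function(i)
    tibble::tibble(time = fits[[i]]$time, dose = fits[[i]]$doses,
                   response = fits[[i]]$responses))
  xmin <- min(pts$dose[pts$dose > 0]) / 2
  grid <- exp(seq(log(xmin), log(max(pts$dose)), length.out = 120))
  curves <- purrr::map_dfr(idx, function(i) {
    p <- fits[[i]]$estimates
    tibble::tibble(time = fits[[i]]$time, dose = grid,
                   response = loglogistic(grid, b = p[["b"]], c = p[["c"]],
                                          d = p[["d"]], e = p[["e"]],
                                          g = if ("g" %in% names(p))
                                            p[["g"]] else 1))
  })
  pts$dose[pts$dose == 0] <- xmin
  lab <- function(t) sprintf("t = %.3g", t)
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$dose, .data$response,
                               color = lab(.data$time))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pts) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste0("dose (", attr(trajectory, "dose_unit"), ")"),
                  y = "response", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an IC50 trajectory
#'
#' The fitted inflection parameter over time, with its standard error as a
#' shaded ribbon; non-converged time points are gaps.
#'
#' @inheritParams plot_fit_snapshots
#' @param ribbon Draw the +/- 1 SE ribbon.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(trajectory, ribbon = TRUE) {
  dat <- trajectory[trajectory$converged, ]
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$ic50))
  if (ribbon)
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ic50 - .data$se,
                   ymax = .data$ic50 + .data$se),
      fill = "grey70", alpha = 0.6)
  p + ggplot2::geom_line() +
    ggplot2::labs(x = paste0("time (", attr(trajectory, "time_unit"), ")"),
                  y = paste0("IC50 (", attr(trajectory, "dose_unit"), ")")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ic50_trajectory <- function(object, ...) plot_trajectory(object, ...)

#' Export a plot to a static image file
#'
#' @param plot A ggplot object.
#' @param path Output path ending in `.png` or `.pdf`.
#' @param width,height,dpi Device size in inches and resolution.
#' @return `path`, invisibly.
#' @export
export_plot <- function(plot, path, width = 8, height = 5, dpi = 150) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "pdf"))
    stop("unknown plot format '", ext, "' (use png or pdf)", call. = FALSE)
  dev <- if (ext == "png") grDevices::png else NULL
  ggplot2::ggsave(path, plot, width = width, height = height, dpi = dpi,
                  device = if (ext == "png") dev else ext)
  invisible(path)
}
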