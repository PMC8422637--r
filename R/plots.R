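#' Plot a schedule trace as a Gantt chart
#'
#' One horizontal bar per stage occurrence, instructions on the y axis,
#' cycles on the x axis; the double-buffered overlap of consecutive
#' instructions (and the EX stage masking CF/LD/WB) is directly visible.
#'
#' @param object a `schedule_trace`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.schedule_trace <- function(object, ...) {
  d <- tidy(object)
  d$stage <- factor(d$stage, levels = c("CF", "LD", "EX", "WB"))
  ggplot2::ggplot(d, ggplot2::aes(y = factor(.data$instr))) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   yend = factor(.data$instr), colour = .data$stage),
      linewidth = 3) +
    ggplot2::labs(x = "cycle", y = "instruction",
                  title = sprintf("%s schedule, makespan %s cycles",
                                  if (object$double_buffered) "Double-buffered"
                                  else "Serial",
                                  format(object$makespan))) +
    ggplot2::theme_minimal()
}

#' Plot a float-vs-int8 comparison report
#'
#' @param object a `quant_comparison` from [compare_float_int8()].
#' @param ... unused.
#' @return A ggplot of per-volume Dice for both paths.
#' @export
autoplot.quant_comparison <- function(object, ...) {
  d <- tidyr_longer_dice(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$volume), y = .data$dsc,
                                  fill = .data$path)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "evaluation volume", y = "Dice",
                  title = "Float vs int8 segmentation quality") +
    ggplot2::theme_minimal()
}

tidyr_longer_dice <- function(x) {
  dplyr::bind_rows(
    tibble::tibble(volume = x$volume, path = "float", dsc = x$dsc_float),
    tibble::tibble(volume = x$volume, path = "int8", dsc = x$dsc_int8))
}

#' Plot the middle axial slice of a phantom
#'
#' @param phantom result of [make_phantom()].
#' @param channel modality index to show.
#' @return A ggplot raster of the slice with the label contour overlaid.
#' @export
plot_phantom_slice <- function(phantom, channel = 1L) {
  x <- vol_chw(phantom$volume)
  lab <- vol_chw(phantom$labels)
  z <- ceiling(dim(x)[2] / 2)
  d <- expand.grid(y = seq_len(dim(x)[3]), x = seq_len(dim(x)[4]))
  d$intensity <- as.vector(x[channel, z, , ])
  d$tumor <- as.vector(lab[1L, z, , ]) > 0
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_point(data = d[d$tumor, ], shape = ".", colour = "red") +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Phantom, channel %d, slice z=%d", channel, z)) +
    ggplot2::theme_void()
}
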