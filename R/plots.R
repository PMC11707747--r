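#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_errorbar labs theme_minimal facet_wrap scale_fill_viridis_c
#'   coord_equal geom_hline
#' @export
ggplot2::autoplot

#' Plot a phantom's ground truth
#' @param object a `tissue_phantom`
#' @param ... unused
#' @return a ggplot: nuclei colored by class over the tumor-region outline
#' @export
autoplot.tissue_phantom <- function(object, ...) {
  nuc <- tidy(object)
  tum <- which(object$tumor_mask, arr.ind = TRUE)
  p <- ggplot()
  if (nrow(tum)) {
    p <- p + geom_tile(data = tibble::tibble(x = tum[, 2], y = tum[, 1]),
                       aes(x = .data$x, y = .data$y), fill = "grey85")
  }
  p + geom_point(data = nuc,
                 aes(x = .data$x, y = .data$y, colour = .data$cell_class,
                     size = .data$radius_px)) +
    coord_equal() +
    labs(title = "Tissue phantom ground truth", x = "x (px)", y = "y (px)",
         colour = "class", size = "radius (px)") +
    theme_minimal()
}

#' Plot training curves
#' @param object a `virtustain_train`
#' @param ... unused
#' @return a ggplot of the training loss and validation L1 over steps
#' @export
autoplot.virtustain_train <- function(object, ...) {
  h <- tidyr::pivot_longer(
    dplyr::select(object$history, "step", "loss", "val_l1", "val_fd"),
    -"step", names_to = "metric", values_to = "value")
  h <- dplyr::filter(h, is.finite(.data$value))
  ggplot(h, aes(x = .data$step, y = .data$value)) +
    geom_line() + geom_point(size = 0.6) +
    facet_wrap(~metric, scales = "free_y") +
    labs(title = "Stainer training", x = "step", y = NULL) +
    theme_minimal()
}

#' Plot a concordance report
#' @param object a `concordance_report`
#' @param ... unused
#' @return a ggplot of Pearson r with CIs per measurement and ROI
#' @export
autoplot.concordance_report <- function(object, ...) {
  d <- dplyr::mutate(object,
                     label = paste(.data$measure, .data$marker, sep = " / "))
  ggplot(d, aes(x = .data$r, y = .data$label)) +
    geom_point() +
    geom_errorbar(aes(xmin = .data$ci_low, xmax = .data$ci_high), width = 0.2) +
    geom_hline(xintercept = 0, linetype = 3) +
    facet_wrap(~roi) +
    labs(title = "Real vs virtual concordance", x = "Pearson r (95% CI)",
         y = NULL) +
    theme_minimal()
}

#' Display one channel of an image bundle
#' @param bundle an [image_bundle()]
#' @param channel channel name or index
#' @return a ggplot raster
#' @export
plot_channel <- function(bundle, channel = 1L) {
  m <- get_channel(bundle, channel)
  d <- tibble::tibble(x = rep(seq_len(ncol(m)), each = nrow(m)),
                      y = rep(seq_len(nrow(m)), ncol(m)),
                      value = as.vector(m))
  ggplot(d, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_tile() + scale_fill_viridis_c() + coord_equal() +
    labs(title = if (is.character(channel)) channel else bundle$channels[channel],
         x = NULL, y = NULL) +
    theme_minimal()
}
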