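# ggplot2 visualisation helpers.

#' Plot ROC curves from an evaluation table or model report
#'
#' @param report A `model_report` (single curve) or a list of them, named by
#'   model.
#' @return A ggplot object.
#' @export
plot_roc <- function(report) {
  if (inherits(report, "model_report")) report <- list(model = report)
  df <- dplyr::bind_rows(lapply(names(report), function(n) {
    dplyr::mutate(report[[n]]$roc, model = n)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot
#'
#' @param km A `km_fit` from [km_estimate()].
#' @param conf Shade Greenwood confidence bands (default TRUE).
#' @return A ggplot object.
#' @export
plot_km <- function(km, conf = TRUE) {
  df <- dplyr::bind_rows(lapply(split(km$curve, km$curve$group), function(g) {
    dplyr::bind_rows(tibble::tibble(group = g$group[1], time = 0, surv = 1,
                                    lower = 1, upper = 1), g)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                        colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability") +
    ggplot2::theme_minimal()
  if (conf) {
    p <- p + ggplot2::geom_step(ggplot2::aes(y = .data$lower), linetype = 3,
                                alpha = 0.6) +
      ggplot2::geom_step(ggplot2::aes(y = .data$upper), linetype = 3,
                         alpha = 0.6)
  }
  p
}

#' Habitat overlay for one slice
#'
#' Shows a grey-scale background sequence with the habitat labels of the
#' chosen axial slice overlaid in colour.
#'
#' @param stack A [volume_stack].
#' @param hmap A `habitat_map`.
#' @param slice Axial slice index (default: slice with most region voxels).
#' @param sequence Background sequence name, default `"AP"`.
#' @return A ggplot object.
#' @export
plot_habitats <- function(stack, hmap, slice = NULL, sequence = "AP") {
  lab <- hmap$labels
  if (is.null(slice)) {
    slice <- which.max(apply(lab > 0, 3, sum))
  }
  bg <- stack$volumes[[sequence]][, , slice]
  sl <- lab[, , slice]
  d <- dim(bg)
  df <- tibble::tibble(
    x = rep(seq_len(d[1]), times = d[2]),
    y = rep(seq_len(d[2]), each = d[1]),
    intensity = as.vector(bg),
    habitat = ifelse(as.vector(sl) > 0, as.vector(sl), NA))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_raster(data = df[!is.na(df$habitat), ],
                         ggplot2::aes(alpha = 0.6, fill = NULL),
                         fill = NA) +
    ggplot2::geom_tile(data = df[!is.na(df$habitat), ],
                       ggplot2::aes(colour = factor(.data$habitat %% 8)),
                       fill = NA, linewidth = 0.1, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Autoplot methods
#'
#' `autoplot()` for `model_report` draws its ROC curve; for `km_fit` the
#' Kaplan-Meier curves.
#'
#' @param object Object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.model_report <- function(object, ...) plot_roc(object)

#' @rdname autoplot.model_report
#' @export
autoplot.km_fit <- function(object, ...) plot_km(object)
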