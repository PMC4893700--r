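## Scores plots with 95% Hotelling ellipses (ggplot2, Suggests).

#' Scores plot with Hotelling ellipses
#'
#' Plots the first two component scores of a [PcaModel-class] or
#' [PlsModel-class], colored by class, with the global 95% Hotelling
#' ellipse and, for PLS-DA models, per-class ellipses. External samples
#' can be projected on top.
#'
#' @param model a fitted [PcaModel-class] or [PlsModel-class].
#' @param classes class labels for PCA scores (taken from the model for
#'   PLS-DA).
#' @param newdata optional matrix of external (log-scale) samples to
#'   project (PLS-DA only).
#' @param alpha significance level of the ellipses.
#' @return a ggplot object.
#' @export
plotScores <- function(model, classes = NULL, newdata = NULL, alpha = 0.05) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotScores needs the ggplot2 package")
  sc <- if (is(model, "PlsModel")) model@scores else model@scores
  if (ncol(sc) < 2L) stop("need at least two components to plot")
  if (is(model, "PlsModel") && is.null(classes)) classes <- model@labels
  df <- data.frame(t1 = sc[, 1], t2 = sc[, 2],
                   class = if (is.null(classes)) "sample" else classes,
                   role = "training")
  gl <- hotellingEllipse(sc[, 1:2], alpha = alpha)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data[["t1"]], y = .data[["t2"]],
                                         color = .data[["class"]])) +
    ggplot2::geom_path(data = gl, ggplot2::aes(x = .data[["x"]], y = .data[["y"]]),
                       inherit.aes = FALSE, linetype = 2, color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = colnames(sc)[1], y = colnames(sc)[2]) +
    ggplot2::theme_minimal()
  if (is(model, "PlsModel")) {
    for (cl in unique(model@labels)) {
      tc <- sc[model@labels == cl, 1:2, drop = FALSE]
      if (nrow(tc) < 4L) next
      el <- hotellingEllipse(tc, alpha = alpha, center = TRUE)
      el$class <- cl
      gg <- gg + ggplot2::geom_path(
        data = el, ggplot2::aes(x = .data[["x"]], y = .data[["y"]],
                                color = .data[["class"]]),
        inherit.aes = FALSE, linetype = 3)
    }
    if (!is.null(newdata)) {
      pr <- predict(model, newdata, alpha = alpha)
      nd <- data.frame(t1 = pr$scores[, 1], t2 = pr$scores[, 2],
                       class = pr$class)
      gg <- gg + ggplot2::geom_point(data = nd, size = 4, shape = 1, stroke = 1.2)
    }
  }
  gg
}
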