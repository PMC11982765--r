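# Violin-plot data extraction and optional ggplot2 rendering. Figures are
# backed by exported data (densities, box statistics, weight tables) so the
# plotting layer stays a thin, untested skin over a tested data contract.

#' Violin-plot data for a Monte Carlo dropout distribution
#'
#' Per class, a Gaussian kernel density estimate of the sampled class
#' probabilities over a fixed grid on \[0, 1\] (Silverman's rule-of-thumb
#' bandwidth), normalized to integrate to 1 over the grid by the
#' trapezoidal rule, plus box statistics (median, quartiles, whiskers at
#' the 2.5 and 97.5 percentiles). A zero-variance sample degenerates to a
#' unit point mass on the nearest grid cell.
#'
#' @param dist An `hs_mcd` distribution.
#' @param grid_size Number of grid points (default 512).
#' @return List of class `hs_violin`: `density` (long data.frame class/x/y)
#'   and `box` (per-class stats data.frame).
#' @export
violin_data <- function(dist, grid_size = 512) {
  stopifnot(inherits(dist, "hs_mcd"))
  if (dist$n_samples < 1)
    hs_error("hierscore_empty_distribution", "empty MCD distribution")
  grid <- seq(0, 1, length.out = grid_size)
  dx <- grid[[2]] - grid[[1]]
  dens <- list(); box <- list()
  for (cl in colnames(dist$samples)) {
    v <- dist$samples[, cl]
    if (stats::sd(v) < 1e-12) {
      y <- numeric(grid_size)
      y[[which.min(abs(grid - v[[1]]))]] <- 1 / dx  # unit point mass
    } else {
      d <- stats::density(v, bw = "nrd0", kernel = "gaussian",
                          from = 0, to = 1, n = grid_size)
      y <- d$y
      area <- sum((y[-1] + y[-grid_size]) / 2) * dx
      y <- y / area
    }
    dens[[cl]] <- data.frame(class = cl, x = grid, y = y)
    q <- stats::quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975),
                         names = FALSE, type = 7)
    box[[cl]] <- data.frame(class = cl, lower_whisker = q[[1]],
                            q1 = q[[2]], median = q[[3]], q3 = q[[4]],
                            upper_whisker = q[[5]],
                            iqr = q[[4]] - q[[2]])
  }
  structure(list(density = do.call(rbind, dens),
                 box = do.call(rbind, box),
                 grid_size = grid_size),
            class = "hs_violin")
}

#' Render a violin plot of an MCD distribution
#'
#' Thin ggplot2 layer over [violin_data()]; requires ggplot2 at run time.
#'
#' @param dist An `hs_mcd` distribution.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_mcd <- function(dist, title = "MCD class probability distribution") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- as.data.frame(dist$samples)
  long <- data.frame(class = rep(colnames(dist$samples),
                                 each = nrow(dist$samples)),
                     probability = as.numeric(as.matrix(df)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$probability, y = .data$class,
                                     fill = .data$class)) +
    ggplot2::geom_violin(scale = "width", alpha = 0.7) +
    ggplot2::geom_boxplot(width = 0.12, outlier.shape = NA, fill = "white") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(title = title, x = "class probability", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Render a signed weight bar chart for one class
#'
#' @param model A trained `hs_model`.
#' @param class Class name.
#' @param k Top-k positive and negative weights (default 6).
#' @return A ggplot object.
#' @export
plot_class_weights <- function(model, class, k = 6) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  gw <- global_class_weights(model, class, k)
  d <- rbind(gw$positive, gw$negative)
  d$feature <- factor(d$feature, levels = d$feature[order(d$weight)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$weight, y = .data$feature,
                                  fill = .data$weight > 0)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = paste0("Output-layer weights: ", class),
                  x = "weight", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
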