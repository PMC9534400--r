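# broom-style tidiers and ggplot2 methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an optimization result
#'
#' One row per class with its sensitivity under the selected constants; with
#' `trace = TRUE` passed to [optimize_constants()], `tidy(x, "trace")`
#' returns the full per-combination mean-sensitivity trace instead.
#'
#' @param x A `tch_optimization`.
#' @param what `"tpr"` (default) or `"trace"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tch_optimization <- function(x, what = c("tpr", "trace"), ...) {
  what <- match.arg(what)
  if (what == "trace") {
    if (is.null(x$trace)) stop("optimization was run without `trace = TRUE`", call. = FALSE)
    return(x$trace)
  }
  tibble::tibble(class = names(x$tpr), tpr = as.numeric(x$tpr))
}

#' @rdname tidy.tch_optimization
#' @export
glance.tch_optimization <- function(x, ...) {
  tibble::tibble(
    c_g = x$constants$c_g, c_r = x$constants$c_r,
    c_y = x$constants$c_y, c_d = x$constants$c_d, t = x$constants$t,
    mean_tpr = x$mean_tpr, min_tpr = min(x$tpr), retained = x$retained,
    n_combinations = x$n_combinations, n_points = x$n_points
  )
}

#' Tidy an evaluation report
#'
#' `tidy()` returns the confusion matrix in long form (one row per truth x
#' prediction cell); `glance()` returns the one-row metric summary.
#'
#' @param x A `tch_evaluation`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tch_evaluation <- function(x, ...) {
  cm <- x$confusion
  tibble::tibble(
    truth = rep(rownames(cm), times = ncol(cm)),
    predicted = rep(colnames(cm), each = nrow(cm)),
    n = as.integer(cm)
  )
}

#' @rdname tidy.tch_evaluation
#' @export
glance.tch_evaluation <- function(x, ...) {
  tibble::tibble(
    stratum = x$stratum, eligible = x$eligible, n_points = x$n_points,
    accuracy = x$accuracy, kappa = x$kappa,
    tpr_green = x$tpr[["green"]], tpr_red = x$tpr[["red"]],
    tpr_gray = x$tpr[["gray"]], tpr_shadow = x$tpr[["shadow"]]
  )
}

#' Plot a raster
#'
#' Classified rasters draw with the fixed class colors (orange red crowns,
#' light-gray gray crowns, dark-green healthy crowns, black shadow, white
#' unclassified); RGB rasters draw in true color.
#'
#' @param object A `tch_raster`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tch_raster <- function(object, ...) {
  tab <- as_tibble.tch_raster(object)
  if (!is.null(tab$value)) {
    codes <- class_codes()
    if (all(stats::na.omit(unique(tab$value)) %in% codes)) {
      lab <- names(codes)[match(tab$value, codes)]
      tab$class <- factor(lab, levels = names(codes))
      p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$x, y = .data$y,
                                             fill = .data$class)) +
        ggplot2::geom_raster() +
        ggplot2::scale_fill_manual(values = class_colors(), drop = FALSE)
    } else {
      p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$x, y = .data$y,
                                             fill = .data$value)) +
        ggplot2::geom_raster()
    }
  } else {
    maxv <- max(tab$r, tab$g, tab$b, 1)
    tab$hex <- grDevices::rgb(tab$r, tab$g, tab$b, maxColorValue = maxv)
    p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$hex)) +
      ggplot2::scale_fill_identity()
  }
  p + ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Confusion-matrix heatmap for an evaluation
#'
#' @param object A `tch_evaluation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tch_evaluation <- function(object, ...) {
  tab <- tidy.tch_evaluation(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                    fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2C7FB8") +
    ggplot2::theme_minimal()
}

#' Map the class partition of HSV space
#'
#' Classifies a dense hue x saturation grid at fixed value levels under a set
#' of constants, visualizing how the model carves HSV color space into the
#' four classes (white where no score exceeds the threshold).
#'
#' @param constants A [tch_constants()].
#' @param v Value levels (panel per level).
#' @param n Grid resolution per axis.
#' @return A ggplot.
#' @export
plot_class_space <- function(constants = tch_constants(),
                             v = c(0.12, 0.35, 0.75), n = 120) {
  grid <- tidyr::expand_grid(
    h = seq(0, 1 - 1e-9, length.out = n),
    s = seq(0, 1, length.out = n),
    v = v
  )
  sc <- assign_scores(grid$h, grid$s, grid$v, constants)
  grid$class <- sc$class
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$h, y = .data$s,
                                     fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~v, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_manual(values = class_colors(), drop = FALSE) +
    ggplot2::labs(x = "hue", y = "saturation") +
    ggplot2::theme_minimal()
}
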