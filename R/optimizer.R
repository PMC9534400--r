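# Exhaustive grid search over model-constant combinations, selecting the set
# that maximizes mean per-class sensitivity on training points.

#' Candidate grid of model constants
#'
#' The default calibration grid: 13 candidate values for each of the hue
#' constants `c_g` and `c_r` and 10 for each of the decay constants `c_y` and
#' `c_d`, giving 13 x 13 x 10 x 10 = 16900 combinations when fully crossed.
#'
#' @param c_g,c_r,c_y,c_d Numeric vectors of candidate values, all >= 2.
#' @return A `tch_grid` list of the four candidate vectors.
#' @examples
#' g <- tch_grid()
#' prod(lengths(g))
#' @export
tch_grid <- function(c_g = c(2, 5, 10, 20, 30, 40, 50, 60, 100,
                             1000, 10000, 100000, 1000000),
                     c_r = c_g,
                     c_y = c(2, 5, 10, 100, 1000, 10000, 100000,
                             1000000, 10000000, 100000000),
                     c_d = c_y) {
  for (nm in c("c_g", "c_r", "c_y", "c_d")) {
    v <- get(nm)
    if (any(v < 2)) stop("grid values for `", nm, "` must be >= 2", call. = FALSE)
  }
  structure(list(c_g = c_g, c_r = c_r, c_y = c_y, c_d = c_d),
            class = "tch_grid")
}

#' Confusion matrix with an explicit unclassified column
#'
#' Tallies predictions against truth over the four crown classes. Predictions
#' of `unclassified` (maximum score at or below the threshold) are kept as a
#' fifth prediction column so they count against sensitivity and accuracy.
#'
#' @param truth Factor or character vector of true classes (green, red, gray,
#'   shadow).
#' @param predicted Factor or character vector of predicted classes,
#'   possibly including `unclassified`.
#' @return An integer matrix with truth rows (4) and prediction columns (5).
#' @examples
#' confusion_matrix(c("green", "red"), c("green", "gray"))
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have the same length", call. = FALSE)
  }
  truth <- factor(as.character(truth), levels = point_classes())
  predicted <- factor(as.character(predicted), levels = tch_class_levels())
  if (anyNA(truth)) stop("`truth` contains labels outside the four classes", call. = FALSE)
  cm <- table(truth = truth, predicted = predicted)
  matrix(as.integer(cm), nrow = 4, dimnames = dimnames(cm))
}

#' Per-class sensitivity (true positive rate)
#'
#' `TPR_k = cm[k, k] / sum(cm[k, ])` for each truth class. Classes with no
#' truth points are reported as `NA` with a warning.
#'
#' @param cm A confusion matrix from [confusion_matrix()] (truth rows named
#'   by class; prediction columns include the same class names).
#' @return Named numeric vector of four sensitivities.
#' @examples
#' cm <- confusion_matrix(rep(point_classes(), 10), rep(point_classes(), 10))
#' per_class_tpr(cm)
#' @export
per_class_tpr <- function(cm) {
  classes <- rownames(cm)
  n <- rowSums(cm)
  tpr <- cm[cbind(classes, classes)] / n
  if (any(n == 0)) {
    warning("class(es) with no truth points: ",
            paste(classes[n == 0], collapse = ", "),
            "; sensitivity undefined", call. = FALSE)
    tpr[n == 0] <- NA_real_
  }
  stats::setNames(as.numeric(tpr), classes)
}

# Precompute the constant-independent pixel geometry once: normalized +
# blue-adjusted HSV and rescaled hues for each training pixel.
pixel_geometry <- function(points, bits = 8, blue_adjustment = TRUE) {
  rn <- normalize_channel(points$r, bits)
  gn <- normalize_channel(points$g, bits)
  bn <- normalize_channel(points$b, bits)
  if (blue_adjustment) bn <- apply_blue_adjustment(rn, gn, bn, bits)
  hsv <- rgb_to_hsv(rn, gn, bn)
  list(
    hg = rescale_hue_green(hsv$h),
    hr = rescale_hue_red(hsv$h),
    s = hsv$s, v = hsv$v,
    achrom = hsv$s == 0
  )
}

#' Optimize model constants by exhaustive grid search
#'
#' Classifies every training pixel under every combination of candidate
#' constants, computes the confusion matrix and per-class sensitivities for
#' each, and returns the combination with the highest mean sensitivity
#' (ties broken by the first combination in ascending lexicographic order of
#' `(c_g, c_r, c_y, c_d)`). The result also carries the retention flag used
#' to screen imagery of marginal quality: a calibration is retained only when
#' the minimum class sensitivity is at least `min_tpr`.
#'
#' Scores are cached across combinations (hue rescaling and HSV are
#' constant-independent; each score curve depends on one constant only), which
#' is exactly equivalent to naive re-evaluation.
#'
#' @param train Training point tibble (see [read_points()]); must contain all
#'   four classes.
#' @param grid A [tch_grid()].
#' @param t Classification threshold used during optimization (default 0.1).
#' @param min_tpr Retention threshold on the minimum class sensitivity
#'   (default 0.7).
#' @param bits Bit depth of the channel values.
#' @param trace Keep the full per-combination mean-sensitivity trace
#'   (a tibble with one row per combination) in the result.
#' @return A `tch_optimization` object: `constants` ([tch_constants()]),
#'   `mean_tpr`, `tpr` (per class), `confusion` matrix, `retained`,
#'   `n_combinations`, and optionally `trace`.
#' @export
optimize_constants <- function(train, grid = tch_grid(), t = 0.1,
                               min_tpr = 0.7, bits = 8, trace = FALSE) {
  train <- validate_points(train, bits = bits)
  present <- table(train$class)
  if (any(present == 0)) {
    stop("training set must contain all four classes; missing: ",
         paste(names(present)[present == 0], collapse = ", "), call. = FALSE)
  }
  stopifnot(inherits(grid, "tch_grid"))
  geo <- pixel_geometry(train, bits = bits)
  n <- nrow(train)
  truth <- as.integer(train$class) # 1..4 in precedence order

  # One score matrix per constant, rows = candidate values.
  G <- vapply(grid$c_g, function(c) score_green(geo$hg, c), numeric(n))
  R <- vapply(grid$c_r, function(c) score_red(geo$hr, c), numeric(n))
  Y <- vapply(grid$c_y, function(c) score_gray(geo$s, c), numeric(n))
  D <- vapply(grid$c_d, function(c) score_shadow(geo$v, c), numeric(n))
  if (any(geo$achrom)) {
    G[geo$achrom, ] <- 0
    R[geo$achrom, ] <- 0
  }

  combos <- expand.grid(
    i_d = seq_along(grid$c_d), i_y = seq_along(grid$c_y),
    i_r = seq_along(grid$c_r), i_g = seq_along(grid$c_g)
  )
  # ascending lexicographic order of (c_g, c_r, c_y, c_d) for tie-breaking
  ord_g <- order(grid$c_g); ord_r <- order(grid$c_r)
  ord_y <- order(grid$c_y); ord_d <- order(grid$c_d)
  combos <- combos[order(match(combos$i_g, ord_g), match(combos$i_r, ord_r),
                         match(combos$i_y, ord_y), match(combos$i_d, ord_d)), ]

  best <- list(mean_tpr = -Inf, row = NA_integer_)
  trace_tpr <- if (trace) numeric(nrow(combos)) else NULL
  m <- matrix(0, n, 4)
  for (k in seq_len(nrow(combos))) {
    m[, 1] <- G[, combos$i_g[k]]
    m[, 2] <- R[, combos$i_r[k]]
    m[, 3] <- Y[, combos$i_y[k]]
    m[, 4] <- D[, combos$i_d[k]]
    if (any(geo$achrom)) {
      m[geo$achrom, 3] <- m[geo$achrom, 3] - m[geo$achrom, 4]
    }
    pred <- max.col(m, ties.method = "first")
    x <- m[cbind(seq_len(n), pred)]
    pred[x <= t] <- 5L
    mean_tpr <- mean(vapply(1:4, function(cl) {
      mean(pred[truth == cl] == cl)
    }, numeric(1)))
    if (trace) trace_tpr[k] <- mean_tpr
    if (mean_tpr > best$mean_tpr) best <- list(mean_tpr = mean_tpr, row = k)
  }

  sel <- combos[best$row, ]
  constants <- tch_constants(
    c_g = grid$c_g[sel$i_g], c_r = grid$c_r[sel$i_r],
    c_y = grid$c_y[sel$i_y], c_d = grid$c_d[sel$i_d], t = t
  )
  scored <- classify_pixels(train, constants, bits = bits)
  cm <- confusion_matrix(train$class, scored$class)
  tpr <- per_class_tpr(cm)
  out <- structure(
    list(
      constants = constants,
      mean_tpr = mean(tpr),
      tpr = tpr,
      confusion = cm,
      retained = all(tpr >= min_tpr),
      min_tpr_rule = min_tpr,
      n_combinations = nrow(combos),
      n_points = n
    ),
    class = "tch_optimization"
  )
  if (trace) {
    out$trace <- tibble::tibble(
      c_g = grid$c_g[combos$i_g], c_r = grid$c_r[combos$i_r],
      c_y = grid$c_y[combos$i_y], c_d = grid$c_d[combos$i_d],
      mean_tpr = trace_tpr
    )
  }
  out
}

#' @export
print.tch_optimization <- function(x, ...) {
  cat("<tch_optimization> ", x$n_combinations, "combinations on",
      x$n_points, "points\n")
  print(x$constants)
  cat("mean TPR =", format(x$mean_tpr, digits = 4),
      " retained =", x$retained, "\n")
  cat("per-class TPR:",
      paste(names(x$tpr), format(x$tpr, digits = 3), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Median optimal constants across strata
#'
#' Given optimization results for several imagery strata (e.g., state x year
#' combinations), reports the per-parameter median of the selected constants —
#' the construction of a single transferable "global" calibration.
#'
#' @param results A list of `tch_optimization` objects, or a data frame with
#'   columns `c_g`, `c_r`, `c_y`, `c_d`.
#' @param retained_only Use only results whose `retained` flag is TRUE
#'   (ignored for data-frame input).
#' @param t Threshold stored in the returned constants.
#' @return A [tch_constants()] object of per-parameter medians.
#' @export
median_constants <- function(results, retained_only = TRUE, t = 0.1) {
  if (is.data.frame(results)) {
    tab <- results
  } else {
    if (retained_only) results <- purrr::keep(results, "retained")
    if (length(results) == 0) stop("no retained results", call. = FALSE)
    tab <- purrr::map_dfr(results, function(r) {
      tibble::as_tibble(r$constants[c("c_g", "c_r", "c_y", "c_d")])
    })
  }
  tch_constants(
    c_g = stats::median(tab$c_g), c_r = stats::median(tab$c_r),
    c_y = stats::median(tab$c_y), c_d = stats::median(tab$c_d), t = t
  )
}

#' Constants table across strata
#'
#' Flattens a named list of `tch_optimization` results into the one-row-per-
#' stratum constants table (stratum, constants, mean and per-class TPR,
#' retention flag).
#'
#' @param results Named list of `tch_optimization` objects (names identify
#'   the stratum, e.g. `"CO_2019"`).
#' @return A tibble.
#' @export
constants_table <- function(results) {
  purrr::imap_dfr(results, function(r, nm) {
    tibble::tibble(
      stratum = nm,
      c_g = r$constants$c_g, c_r = r$constants$c_r,
      c_y = r$constants$c_y, c_d = r$constants$c_d,
      mean_tpr = r$mean_tpr,
      tpr_green = r$tpr[["green"]], tpr_red = r$tpr[["red"]],
      tpr_gray = r$tpr[["gray"]], tpr_shadow = r$tpr[["shadow"]],
      retained = r$retained
    )
  })
}
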