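# Accuracy assessment on withheld testing points: overall accuracy, Cohen's
# kappa, per-class sensitivity, eligibility screening, and confusion-pattern
# summaries.

#' Overall accuracy of a confusion matrix
#'
#' Proportion of correctly classified points: the sum of the diagonal cells
#' (matching truth row and prediction column names) over the total count.
#' Unclassified predictions have no matching truth row and so count as errors.
#'
#' @param cm Confusion matrix with named truth rows and prediction columns
#'   (see [confusion_matrix()]); any square named matrix also works.
#' @return Proportion in `[0, 1]`.
#' @examples
#' overall_accuracy(matrix(c(45, 10, 5, 40), 2, 2,
#'   dimnames = list(c("a", "b"), c("a", "b"))))
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  shared <- intersect(rownames(cm), colnames(cm))
  sum(cm[cbind(shared, shared)]) / total
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with expected
#' agreement `p_e` computed from the row and column marginals. Non-square
#' matrices (e.g., with an extra `unclassified` prediction column) are first
#' extended with zero rows/columns to the union of row and column categories,
#' so unclassified predictions enter the marginals but never the agreement.
#'
#' @param cm Confusion matrix with named rows (truth) and columns (predicted).
#' @return The kappa statistic, or `NA` with a warning when `p_e = 1`
#'   (degenerate marginals).
#' @examples
#' cohens_kappa(matrix(c(45, 10, 5, 40), 2, 2,
#'   dimnames = list(c("a", "b"), c("a", "b"))))
#' @export
cohens_kappa <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  cats <- union(rownames(cm), colnames(cm))
  sq <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  sq[rownames(cm), colnames(cm)] <- cm
  p_o <- sum(diag(sq)) / total
  p_e <- sum(rowSums(sq) * colSums(sq)) / total^2
  if (isTRUE(all.equal(p_e, 1))) {
    warning("degenerate marginals (expected agreement = 1); kappa undefined",
            call. = FALSE)
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Evaluate a calibrated model on withheld testing points
#'
#' Classifies every testing point under the supplied constants, builds the
#' confusion matrix and computes overall accuracy, Cohen's kappa and
#' per-class sensitivity. A report is *eligible* only when every one of the
#' four classes has at least `min_test_n` testing points; otherwise the
#' summary metrics are withheld (`NA`) while the confusion matrix is still
#' returned for inspection.
#'
#' @param test Testing point tibble (see [split_train_test()]).
#' @param constants A [tch_constants()] object.
#' @param min_test_n Minimum testing points per class for metric reporting
#'   (default 5).
#' @param bits Bit depth of the channel values.
#' @param kappa_unclassified Include unclassified predictions in the kappa
#'   marginals (default TRUE); when FALSE, kappa is computed on the 4x4
#'   classified-only submatrix.
#' @param stratum Optional stratum label carried into the report.
#' @return A `tch_evaluation` object: `accuracy`, `kappa`, `tpr`,
#'   `confusion`, `eligible`, `n_points`, `constants`, `stratum`.
#' @export
evaluate_model <- function(test, constants = tch_constants(), min_test_n = 5,
                           bits = 8, kappa_unclassified = TRUE,
                           stratum = NA_character_) {
  test <- validate_points(test, bits = bits)
  scored <- classify_pixels(test, constants, bits = bits)
  cm <- confusion_matrix(test$class, scored$class)
  eligible <- all(rowSums(cm) >= min_test_n)
  if (eligible) {
    accuracy <- overall_accuracy(cm)
    kappa <- if (kappa_unclassified) {
      cohens_kappa(cm)
    } else {
      cohens_kappa(cm[, rownames(cm), drop = FALSE])
    }
    tpr <- per_class_tpr(cm)
  } else {
    accuracy <- NA_real_
    kappa <- NA_real_
    tpr <- stats::setNames(rep(NA_real_, 4), rownames(cm))
  }
  structure(
    list(
      accuracy = accuracy, kappa = kappa, tpr = tpr, confusion = cm,
      eligible = eligible, min_test_n = min_test_n,
      n_points = nrow(test), constants = constants, stratum = stratum
    ),
    class = "tch_evaluation"
  )
}

#' @export
print.tch_evaluation <- function(x, ...) {
  cat("<tch_evaluation> ", x$n_points, "testing points",
      if (!is.na(x$stratum)) paste0("(", x$stratum, ")"), "\n")
  if (!x$eligible) {
    cat("ineligible: fewer than", x$min_test_n,
        "testing points in at least one class; metrics withheld\n")
  } else {
    cat("overall accuracy =", format(x$accuracy, digits = 4),
        " kappa =", format(x$kappa, digits = 4), "\n")
    cat("per-class TPR:",
        paste(names(x$tpr), format(x$tpr, digits = 3), sep = "=",
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Dominant confusion pattern of an evaluation
#'
#' Reports, for the truth class with the lowest sensitivity, where its errors
#' went — the prediction class absorbing most of its misclassified points
#' (e.g., shadow mistaken for gray, or gray and red confused with each
#' other).
#'
#' @param x A `tch_evaluation` or a confusion matrix.
#' @return A one-row tibble: `lowest_tpr_class`, `tpr`, `dominant_confusion`
#'   (NA when the class has no errors), `confused_n`, `error_n`.
#' @export
confusion_pattern <- function(x) {
  cm <- if (inherits(x, "tch_evaluation")) x$confusion else x
  tpr <- suppressWarnings(per_class_tpr(cm))
  lo <- names(which.min(tpr))
  row <- cm[lo, ]
  row[lo] <- 0L
  dominant <- if (sum(row) == 0) NA_character_ else names(which.max(row))
  tibble::tibble(
    lowest_tpr_class = lo,
    tpr = tpr[[lo]],
    dominant_confusion = dominant,
    confused_n = if (is.na(dominant)) 0L else as.integer(row[[dominant]]),
    error_n = as.integer(sum(row))
  )
}

#' Aggregate evaluation reports across strata
#'
#' Summarizes a collection of per-stratum evaluations with the median and
#' chosen percentiles of overall accuracy and kappa among eligible reports.
#'
#' @param reports List of `tch_evaluation` objects.
#' @param probs Percentiles to report (default 5th and 95th).
#' @return A one-row tibble of medians, percentiles and counts.
#' @export
summarize_evaluations <- function(reports, probs = c(0.05, 0.95)) {
  tab <- purrr::map_dfr(reports, function(r) {
    tibble::tibble(accuracy = r$accuracy, kappa = r$kappa,
                   eligible = r$eligible)
  })
  ok <- dplyr::filter(tab, .data$eligible)
  qa <- stats::quantile(ok$accuracy, probs, na.rm = TRUE)
  qk <- stats::quantile(ok$kappa, probs, na.rm = TRUE)
  out <- tibble::tibble(
    n_models = nrow(tab),
    n_eligible = nrow(ok),
    median_accuracy = stats::median(ok$accuracy),
    median_kappa = stats::median(ok$kappa)
  )
  for (i in seq_along(probs)) {
    out[[paste0("accuracy_p", round(100 * probs[i]))]] <- qa[[i]]
    out[[paste0("kappa_p", round(100 * probs[i]))]] <- qk[[i]]
  }
  out
}

#' Serialize an evaluation report to JSON
#'
#' @param x A `tch_evaluation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(x, path) {
  stopifnot(inherits(x, "tch_evaluation"))
  jsonlite::write_json(
    list(
      stratum = x$stratum,
      eligible = x$eligible,
      n_points = x$n_points,
      accuracy = x$accuracy,
      kappa = x$kappa,
      tpr = as.list(x$tpr),
      confusion = list(
        truth = rownames(x$confusion),
        predicted = colnames(x$confusion),
        counts = x$confusion
      ),
      constants = unclass(x$constants)
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
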