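# Labeled crown-color point tables: reading, validation, writing, and the
# stratified 90/10 train/test partition.

point_classes <- function() c("green", "red", "gray", "shadow")

optional_point_columns <- function() {
  c("nir", "state", "year", "ecocode", "digitizer", "lon", "lat")
}

#' Read a labeled crown-color point table
#'
#' Reads training/testing points from a delimited text file (CSV) or a
#' GeoJSON point file. Required columns/properties: `class` (one of green,
#' red, gray, shadow), `r`, `g`, `b` (raw channel values for the declared bit
#' depth). Optional columns `nir`, `state`, `year`, `ecocode`, `digitizer`,
#' `lon`, `lat` are carried through when present. Records are validated:
#' unknown class labels or out-of-range channels are rejected with the
#' offending row named.
#'
#' @param path Path to a `.csv` or `.geojson`/`.json` file.
#' @param bits Bit depth the channel values must respect.
#' @return A tibble of validated points with `class` as a factor.
#' @export
read_points <- function(path, bits = 8) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    pts <- read_points_geojson(path)
  } else {
    pts <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  validate_points(pts, bits = bits)
}

read_points_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  rows <- purrr::map(gj$features, function(f) {
    props <- purrr::map(f$properties, ~.x)
    coords <- f$geometry$coordinates
    if (!is.null(coords) && is.null(props$lon)) {
      props$lon <- coords[[1]]
      props$lat <- coords[[2]]
    }
    tibble::as_tibble(props)
  })
  dplyr::bind_rows(rows)
}

#' Validate a point table
#'
#' @param points A data frame with at least `class`, `r`, `g`, `b`.
#' @param bits Bit depth for channel range checks.
#' @return The validated tibble (class coerced to factor).
#' @export
validate_points <- function(points, bits = 8) {
  points <- tibble::as_tibble(points)
  missing <- setdiff(c("class", "r", "g", "b"), names(points))
  if (length(missing) > 0) {
    stop("point table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(points) == 0) stop("point table is empty", call. = FALSE)
  cls <- tolower(as.character(points$class))
  bad <- which(!cls %in% point_classes())
  if (length(bad) > 0) {
    stop("invalid class label ", dQuote(as.character(points$class)[bad[1]]),
         " in row ", bad[1], call. = FALSE)
  }
  maxv <- 2^bits - 1
  for (ch in c("r", "g", "b")) {
    x <- points[[ch]]
    bad <- which(!is.finite(x) | x < 0 | x > maxv | x != round(x))
    if (length(bad) > 0) {
      stop("channel ", ch, " out of range for ", bits, "-bit imagery in row ",
           bad[1], call. = FALSE)
    }
  }
  points$class <- factor(cls, levels = point_classes())
  points
}

#' Write a point table to CSV
#'
#' @param points A validated point tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path) {
  readr::write_csv(points, path, progress = FALSE)
  invisible(path)
}

#' Split points into training and testing sets
#'
#' Performs the stratified random split used to calibrate and evaluate the
#' model: within each stratum (by default the `state` x `year` imagery
#' combination) and class, classes with at least `min_class_n` points
#' contribute `round((1 - fraction) * n)` randomly chosen testing points
#' (at least 1), the rest going to training; classes with fewer than
#' `min_class_n` points contribute all points to training and none to
#' testing. The split is reproducible under `seed`.
#'
#' @param points A validated point tibble (see [read_points()]).
#' @param fraction Training fraction (default 0.9 for a 90/10 split).
#' @param min_class_n Minimum class size within a stratum for a testing
#'   subset to be withheld (default 50).
#' @param seed Integer seed controlling the random draw.
#' @param stratum_vars Character vector of stratum columns; columns absent
#'   from `points` are ignored (a single stratum when none are present).
#' @return A `tch_partition` list with tibbles `train` and `test` and a
#'   `manifest` (per stratum x class counts, fraction, seed).
#' @export
split_train_test <- function(points, fraction = 0.9, min_class_n = 50,
                             seed = 1L, stratum_vars = c("state", "year")) {
  points <- validate_points(points)
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  }
  stratum_vars <- intersect(stratum_vars, names(points))
  idx <- seq_len(nrow(points))
  key <- if (length(stratum_vars) > 0) {
    interaction(points[stratum_vars], drop = TRUE, lex.order = TRUE)
  } else {
    factor(rep("all", nrow(points)))
  }
  groups <- split(idx, list(stratum = key, class = points$class), drop = TRUE)

  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  test_idx <- integer(0)
  for (nm in sort(names(groups))) {
    ids <- groups[[nm]]
    n <- length(ids)
    if (n >= min_class_n) {
      n_test <- max(1L, round((1 - fraction) * n))
      test_idx <- c(test_idx, ids[sample.int(n, n_test)])
    }
  }
  in_test <- idx %in% test_idx
  train <- points[!in_test, , drop = FALSE]
  test <- points[in_test, , drop = FALSE]

  counts <- dplyr::count(
    dplyr::mutate(points, .set = ifelse(in_test, "test", "train")),
    dplyr::across(dplyr::all_of(c(stratum_vars, "class"))), .data$.set
  )
  counts <- tidyr::pivot_wider(counts, names_from = ".set",
                               values_from = "n", values_fill = 0L)
  if (!"test" %in% names(counts)) counts$test <- 0L
  structure(
    list(
      train = train, test = test,
      manifest = list(
        counts = counts, fraction = fraction,
        min_class_n = min_class_n, seed = seed,
        stratum_vars = stratum_vars
      )
    ),
    class = "tch_partition"
  )
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.tch_partition <- function(x, ...) {
  cat("<tch_partition> ", nrow(x$train), "training points,",
      nrow(x$test), "testing points (fraction =", x$manifest$fraction,
      ", seed =", x$manifest$seed, ")\n")
  print(x$manifest$counts)
  invisible(x)
}

#' Write a partition to disk
#'
#' Writes `train.csv`, `test.csv` and a `manifest.json` (counts, fraction,
#' minimum class size, seed) into `dir`.
#'
#' @param partition A `tch_partition` from [split_train_test()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_partition <- function(partition, dir) {
  stopifnot(inherits(partition, "tch_partition"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(partition$train, file.path(dir, "train.csv"), progress = FALSE)
  readr::write_csv(partition$test, file.path(dir, "test.csv"), progress = FALSE)
  jsonlite::write_json(
    list(
      fraction = partition$manifest$fraction,
      min_class_n = partition$manifest$min_class_n,
      seed = partition$manifest$seed,
      stratum_vars = partition$manifest$stratum_vars,
      counts = partition$manifest$counts
    ),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
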