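# Synthetic fixtures: class-typical color sampling in HSV, scene rendering
# with known truth, and labeled training-point tables — every stage of the
# pipeline is testable without external imagery.

#' Default HSV sampling boxes for the four crown classes
#'
#' Uniform HSV boxes whose supports align with the supports of the score
#' curves: green hues straddle the green anchor (H = 1/3) at moderate-to-high
#' saturation; red hues straddle the red anchor (H = 0/1) with the allowance
#' towards orange/brown; gray is near-achromatic (very low saturation) at
#' blue-ish hues where the hue scores vanish; shadow is very dark. Hue ranges
#' may be negative (wrapped modulo 1). These are testing defaults, not a
#' model of any particular sensor.
#'
#' @return Named list of per-class lists with `h`, `s`, `v` ranges.
#' @export
class_color_defaults <- function() {
  list(
    green = list(h = c(0.26, 0.41), s = c(0.40, 0.90), v = c(0.30, 0.80)),
    red = list(h = c(-0.07, 0.10), s = c(0.45, 0.90), v = c(0.30, 0.85)),
    gray = list(h = c(0.50, 0.83), s = c(0.00, 0.08), v = c(0.35, 0.80)),
    shadow = list(h = c(0.50, 0.83), s = c(0.10, 0.50), v = c(0.00, 0.05))
  )
}

# Standard HSV -> RGB (h in [0,1), s, v in [0,1]); returns normalized channels.
hsv_to_rgb <- function(h, s, v) {
  h <- h %% 1
  k <- floor(h * 6)
  f <- h * 6 - k
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t_ <- v * (1 - (1 - f) * s)
  r <- g <- b <- numeric(length(h))
  for (kk in 0:5) {
    sel <- k == kk
    if (!any(sel)) next
    ch <- switch(as.character(kk),
      "0" = list(v, t_, p), "1" = list(q, v, p), "2" = list(p, v, t_),
      "3" = list(p, q, v), "4" = list(t_, p, v), "5" = list(v, p, q)
    )
    r[sel] <- ch[[1]][sel]; g[sel] <- ch[[2]][sel]; b[sel] <- ch[[3]][sel]
  }
  list(r = r, g = g, b = b)
}

#' Sample class-typical RGB colors
#'
#' Draws `n` colors for a crown class: HSV uniform in the class box (see
#' [class_color_defaults()]), converted to RGB and quantized to the raw bit
#' depth. Under the default boxes and the default (median) constants, at
#' least 99% of draws classify back to their generating class.
#'
#' @param class One of `"green"`, `"red"`, `"gray"`, `"shadow"`.
#' @param n Number of draws.
#' @param params Per-class HSV box (default from [class_color_defaults()]).
#' @param seed Optional integer seed (draws are deterministic when set).
#' @param bits Bit depth for quantization.
#' @return A tibble with integer columns `r`, `g`, `b`.
#' @export
sample_class_colors <- function(class, n, params = NULL, seed = NULL, bits = 8) {
  stopifnot(n > 0)
  class <- match.arg(class, point_classes())
  if (is.null(params)) params <- class_color_defaults()[[class]]
  if (any(params$s < 0 | params$s > 1) || any(params$v < 0 | params$v > 1)) {
    stop("saturation and value ranges must lie within [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- .Random.seed_exists()
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  h <- stats::runif(n, params$h[1], params$h[2])
  s <- stats::runif(n, params$s[1], params$s[2])
  v <- stats::runif(n, params$v[1], params$v[2])
  rgb <- hsv_to_rgb(h, s, v)
  maxv <- 2^bits - 1
  tibble::tibble(
    r = as.integer(round(rgb$r * maxv)),
    g = as.integer(round(rgb$g * maxv)),
    b = as.integer(round(rgb$b * maxv))
  )
}

#' Specify a synthetic scene
#'
#' A scene is a background (by default a non-class "water" color that the
#' model leaves unclassified) with rectangular patches of crown classes.
#' Patches are given in pixel coordinates (row/col of the upper-left corner
#' plus height and width) and must not overlap with conflicting classes.
#'
#' @param width,height Scene size in pixels.
#' @param px Pixel size in meters.
#' @param patches A data frame with columns `class`, `row`, `col`, `height`,
#'   `width` (pixel units, 1-based upper-left corner).
#' @param background `"water"` (unclassified background) or a class name.
#' @param seed Integer seed fixing all color draws.
#' @param bits Bit depth.
#' @return A `tch_scene_spec` list.
#' @export
scene_spec <- function(width = 64, height = 64, px = 1,
                       patches = NULL, background = "water",
                       seed = 1L, bits = 8) {
  if (is.null(patches)) {
    patches <- tibble::tibble(class = character(), row = integer(),
                              col = integer(), height = integer(),
                              width = integer())
  }
  patches <- tibble::as_tibble(patches)
  if (nrow(patches) > 0) {
    bad <- patches$row < 1 | patches$col < 1 |
      patches$row + patches$height - 1 > height |
      patches$col + patches$width - 1 > width
    if (any(bad)) stop("patch outside scene bounds", call. = FALSE)
  }
  structure(
    list(width = width, height = height, px = px, patches = patches,
         background = background, seed = seed, bits = bits),
    class = "tch_scene_spec"
  )
}

water_color_box <- function() list(h = c(0.55, 0.62), s = c(0.35, 0.55), v = c(0.40, 0.60))

#' Render a synthetic scene
#'
#' Produces an RGB raster and the matching truth raster (class codes of
#' [class_codes()]; background pixels are coded `unclassified`). Patch and
#' background colors are drawn per pixel from the class color boxes; all
#' randomness is fixed by the spec's seed. Overlapping patches of different
#' classes are an error.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (3-band `tch_raster`) and `truth` (single-band
#'   `tch_raster` of class codes).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "tch_scene_spec"))
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(spec$seed)

  h <- spec$height; w <- spec$width
  codes <- class_codes()
  truth <- matrix(NA_integer_, h, w)
  # background
  if (spec$background == "water") {
    bg_box <- water_color_box()
    bg_code <- codes[["unclassified"]]
  } else {
    bg_class <- match.arg(spec$background, point_classes())
    bg_box <- class_color_defaults()[[bg_class]]
    bg_code <- codes[[bg_class]]
  }
  n <- h * w
  hh <- stats::runif(n, bg_box$h[1], bg_box$h[2])
  ss <- stats::runif(n, bg_box$s[1], bg_box$s[2])
  vv <- stats::runif(n, bg_box$v[1], bg_box$v[2])
  truth[] <- bg_code

  if (nrow(spec$patches) > 0) {
    boxes <- class_color_defaults()
    for (p in seq_len(nrow(spec$patches))) {
      cl <- match.arg(spec$patches$class[p], point_classes())
      rows <- spec$patches$row[p]:(spec$patches$row[p] + spec$patches$height[p] - 1L)
      cols <- spec$patches$col[p]:(spec$patches$col[p] + spec$patches$width[p] - 1L)
      cells <- as.vector(outer(rows, (cols - 1L) * h, `+`))
      clash <- truth[cells] != bg_code & truth[cells] != codes[[cl]]
      if (any(clash)) stop("overlapping patches of different classes", call. = FALSE)
      box <- boxes[[cl]]
      m <- length(cells)
      hh[cells] <- stats::runif(m, box$h[1], box$h[2])
      ss[cells] <- stats::runif(m, box$s[1], box$s[2])
      vv[cells] <- stats::runif(m, box$v[1], box$v[2])
      truth[cells] <- codes[[cl]]
    }
  }
  rgb <- hsv_to_rgb(hh, ss, vv)
  maxv <- 2^spec$bits - 1
  img <- array(0L, dim = c(h, w, 3))
  img[, , 1] <- as.integer(round(rgb$r * maxv))
  img[, , 2] <- as.integer(round(rgb$g * maxv))
  img[, , 3] <- as.integer(round(rgb$b * maxv))
  list(
    image = tch_raster(img, px = spec$px),
    truth = tch_raster(truth, px = spec$px)
  )
}

#' Generate a labeled training-point table
#'
#' Emulates photo-interpreted crown-color points: `n_per_class` labeled
#' points per class per stratum with class-typical RGB draws and stratum
#' metadata (state, year, ecoregion code, digitizer, coordinates). With
#' `cluster_size > 1`, points are drawn in crown clusters sharing a color
#' center with a small jitter, mimicking several pixels digitized on one
#' crown.
#'
#' @param n_per_class Points per class within each stratum.
#' @param strata A data frame with columns `state` and `year` (one row per
#'   stratum), or NULL for a single unnamed stratum.
#' @param params Named list of per-class HSV boxes (default
#'   [class_color_defaults()]).
#' @param cluster_size Points per simulated crown (1 = independent draws).
#' @param seed Integer seed.
#' @param bits Bit depth.
#' @return A validated point tibble (see [read_points()]).
#' @export
make_training_set <- function(n_per_class = 100, strata = NULL,
                              params = NULL, cluster_size = 1L,
                              seed = 1L, bits = 8) {
  stopifnot(n_per_class >= 1)
  if (is.null(params)) params <- class_color_defaults()
  if (is.null(strata)) strata <- tibble::tibble(state = "XX", year = 2019L)
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  maxv <- 2^bits - 1

  out <- list()
  for (srow in seq_len(nrow(strata))) {
    for (cl in point_classes()) {
      box <- params[[cl]]
      n_crowns <- ceiling(n_per_class / cluster_size)
      hc <- stats::runif(n_crowns, box$h[1], box$h[2])
      sc <- stats::runif(n_crowns, box$s[1], box$s[2])
      vc <- stats::runif(n_crowns, box$v[1], box$v[2])
      idx <- rep(seq_len(n_crowns), each = cluster_size)[seq_len(n_per_class)]
      jitter_sd <- if (cluster_size > 1L) 0.01 else 0
      h <- hc[idx] + stats::rnorm(n_per_class, 0, jitter_sd)
      s <- clamp(sc[idx] + stats::rnorm(n_per_class, 0, jitter_sd), box$s[1], box$s[2])
      v <- clamp(vc[idx] + stats::rnorm(n_per_class, 0, jitter_sd), box$v[1], box$v[2])
      rgb <- hsv_to_rgb(h, s, v)
      out[[length(out) + 1L]] <- tibble::tibble(
        class = cl,
        r = as.integer(round(rgb$r * maxv)),
        g = as.integer(round(rgb$g * maxv)),
        b = as.integer(round(rgb$b * maxv)),
        nir = as.integer(round(stats::runif(n_per_class, 0, maxv))),
        state = strata$state[srow],
        year = strata$year[srow],
        ecocode = paste0("S", srow),
        digitizer = "synthetic",
        lon = stats::runif(n_per_class, -120, -70),
        lat = stats::runif(n_per_class, 30, 48)
      )
    }
  }
  validate_points(dplyr::bind_rows(out), bits = bits)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
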