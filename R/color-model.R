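# Core pixel model: RGB normalization, the blue-channel adjustment, HSV
# conversion, hue rescaling, the four class score curves, and final assignment.

#' Model constants for the crown-health classifier
#'
#' Bundles the four calibration constants of the score curves and the minimum
#' classification threshold. `c_g` and `c_r` steepen the green and red hue
#' scores, `c_y` and `c_d` control how fast the gray and shadow scores decay
#' with saturation and value. All four constants must be >= 2 (the score
#' curves are defined only there). The defaults are the median optimal
#' constants found across a large national calibration of NAIP state x year
#' imagery (c_g = 5, c_r = 5, c_y = 1e7, c_d = 1e4) with threshold t = 0.1.
#'
#' @param c_g,c_r,c_y,c_d Positive reals >= 2.
#' @param t Classification threshold in `[0, 1)`. A pixel is left
#'   unclassified when the maximum class score does not strictly exceed `t`.
#' @return A `tch_constants` object (named list).
#' @examples
#' tch_constants()
#' tch_constants(c_g = 10, c_r = 5, c_y = 1e6, c_d = 1e4, t = 0.2)
#' @export
tch_constants <- function(c_g = 5, c_r = 5, c_y = 1e7, c_d = 1e4, t = 0.1) {
  for (nm in c("c_g", "c_r", "c_y", "c_d")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 2) {
      stop("`", nm, "` must be a single number >= 2", call. = FALSE)
    }
  }
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t >= 1) {
    stop("`t` must be a single number in [0, 1)", call. = FALSE)
  }
  structure(
    list(c_g = c_g, c_r = c_r, c_y = c_y, c_d = c_d, t = t),
    class = "tch_constants"
  )
}

#' @export
print.tch_constants <- function(x, ...) {
  cat("<tch_constants>  c_g =", format(x$c_g), " c_r =", format(x$c_r),
      " c_y =", format(x$c_y), " c_d =", format(x$c_d), " t =", format(x$t), "\n")
  invisible(x)
}

# Class labels in fixed precedence order (argmax tie-break) plus the
# no-decision outcome. Raster codes live in raster.R.
tch_class_levels <- function() c("green", "red", "gray", "shadow", "unclassified")

#' Max-normalize raw channel values
#'
#' Divides raw unsigned integer channel values by `2^bits - 1` so the model
#' equations can be applied to imagery of any unsigned bit depth.
#'
#' @param x Numeric vector of raw channel values (whole numbers).
#' @param bits Unsigned integer bit depth of the imagery (8 for NAIP).
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' normalize_channel(c(0, 51, 255), bits = 8)
#' @export
normalize_channel <- function(x, bits = 8) {
  maxv <- 2^bits - 1
  if (any(!is.finite(x)) || any(x < 0 | x > maxv) || any(x != round(x))) {
    stop("raw channel values must be whole numbers in [0, ", maxv, "]",
         call. = FALSE)
  }
  x / maxv
}

#' Apply the blue-channel adjustment
#'
#' When blue equals red (with green >= red) or blue equals green (with
#' red >= green), the pixel sits exactly on the green or red hue anchor
#' (H = 1/3 or H = 0) regardless of its saturation and value, so the hue-based
#' scores would act independently of the other two channels. The model removes
#' this pathology by lowering the blue channel by one quantization step
#' (`1 / 2^bits` in normalized units) for exactly these pixels, flooring at 0.
#' All other pixels pass through unchanged.
#'
#' @param r,g,b Normalized channel vectors in `[0, 1]` (equal length).
#' @param bits Bit depth used to size the adjustment step.
#' @return Numeric vector: the adjusted blue channel.
#' @examples
#' apply_blue_adjustment(100 / 255, 101 / 255, 100 / 255)
#' @export
apply_blue_adjustment <- function(r, g, b, bits = 8) {
  step <- 1 / 2^bits
  hit <- (b == r & g >= r) | (b == g & r >= g)
  b[hit] <- pmax(b[hit] - step, 0)
  b
}

#' Convert normalized RGB to HSV
#'
#' Standard hexcone conversion with hue in `[0, 1)` (red at 0, green at 1/3,
#' blue at 2/3), `S = (max - min) / max` (0 when max = 0) and `V = max`.
#' Achromatic pixels take H = 0. Ties on the maximum channel resolve in the
#' order red, green, blue.
#'
#' @param r,g,b Numeric vectors in `[0, 1]` (equal length).
#' @return A tibble with columns `h`, `s`, `v`.
#' @examples
#' rgb_to_hsv(0, 1, 0)
#' @export
rgb_to_hsv <- function(r, g, b) {
  if (any(r < 0 | r > 1 | g < 0 | g > 1 | b < 0 | b > 1)) {
    stop("normalized channels must lie in [0, 1]", call. = FALSE)
  }
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 1)
  # rgb2hsv returns h in [0, 1] with h = 1 possible only by rounding; the
  # model's hue domain is the half-open circle.
  h <- hsv["h", ]
  h[h >= 1] <- 0
  tibble::tibble(h = unname(h), s = unname(hsv["s", ]), v = unname(hsv["v", ]))
}

#' Rescaled hues for the green and red score curves
#'
#' `rescale_hue_green()` maps hue so the green anchor (H = 1/3) scores 1 and
#' support falls off linearly to 0 at H = 1/6 and H = 1/2.
#' `rescale_hue_red()` does the same for the red anchor (H = 0 or 1) with
#' support on `[0, 1/6)` and `(5/6, 1)`; the red class thereby also covers
#' hues tending towards brown, orange, and yellow. Values may be negative
#' (outside the class support).
#'
#' @param h Hue vector in `[0, 1)`.
#' @return Numeric vector, at most 1.
#' @examples
#' rescale_hue_green(c(1 / 3, 0.25, 0))
#' rescale_hue_red(c(0, 1 / 12, 1 / 3))
#' @export
rescale_hue_green <- function(h) 1 - abs(h - 1 / 3) / (1 / 6)

#' @rdname rescale_hue_green
#' @export
rescale_hue_red <- function(h) abs(1 / 2 - h) / (1 / 6) - 2

check_constant <- function(c, nm) {
  if (any(c < 2)) stop("model constant `", nm, "` must be >= 2", call. = FALSE)
  invisible(c)
}

# Shared exponential rescaling (c^x - 1) / (c - 1): 0 at x = 0, 1 at x = 1,
# curvature set by c.
score_curve <- function(x, c) (c^x - 1) / (c - 1)

#' Class score curves
#'
#' The four score equations of the model. `score_green()`/`score_red()` map a
#' rescaled hue through `(c^h - 1) / (c - 1)`, clamped to 0 for negative
#' rescaled hues (outside the class support). `score_gray()` decays from 1 at
#' zero saturation, `score_shadow()` from 1 at zero value; their constants set
#' the decay rate.
#'
#' @param hg,hr Rescaled hues from [rescale_hue_green()] / [rescale_hue_red()].
#' @param s,v Saturation / value in `[0, 1]`.
#' @param c_g,c_r,c_y,c_d Model constants, each >= 2.
#' @return Numeric vector of scores in `[0, 1]`.
#' @examples
#' score_green(1, 5)
#' score_gray(0.3, 1e7)
#' @export
score_green <- function(hg, c_g = 5) {
  check_constant(c_g, "c_g")
  ifelse(hg < 0, 0, score_curve(hg, c_g))
}

#' @rdname score_green
#' @export
score_red <- function(hr, c_r = 5) {
  check_constant(c_r, "c_r")
  ifelse(hr < 0, 0, score_curve(hr, c_r))
}

#' @rdname score_green
#' @export
score_gray <- function(s, c_y = 1e7) {
  check_constant(c_y, "c_y")
  score_curve(1 - s, c_y)
}

#' @rdname score_green
#' @export
score_shadow <- function(v, c_d = 1e4) {
  check_constant(c_d, "c_d")
  score_curve(1 - v, c_d)
}

#' Classify pixels into crown condition classes
#'
#' Runs the full per-pixel pipeline on a table of raw RGB values:
#' max-normalization, the blue-channel adjustment, HSV conversion, hue
#' rescaling, the four score curves, the zero-saturation recalculation
#' (`Y' = Y - D`, with the hue-based scores vacated since hue is undefined at
#' zero chroma), and final assignment of the maximum score `X` to its class
#' when `X > t` (strictly), otherwise `unclassified`. Score ties resolve by
#' the fixed precedence green > red > gray > shadow.
#'
#' @param data A data frame with columns `r`, `g`, `b` holding raw channel
#'   values for the declared bit depth.
#' @param constants A [tch_constants()] object.
#' @param bits Unsigned bit depth of the imagery.
#' @param blue_adjustment Apply the blue-channel adjustment (default TRUE;
#'   disabling it exposes the hue-anchor pathology the adjustment corrects).
#' @return The input tibble with appended columns `h`, `s`, `v`, `score_green`,
#'   `score_red`, `score_gray`, `score_shadow`, `score_max`, and `class`
#'   (factor with levels green, red, gray, shadow, unclassified). An input
#'   `class` column (truth labels) is preserved under the name `truth`; any
#'   other input column sharing an output name is replaced.
#' @examples
#' classify_pixels(data.frame(r = c(76, 180), g = c(175, 60), b = c(80, 50)))
#' @export
classify_pixels <- function(data, constants = tch_constants(), bits = 8,
                            blue_adjustment = TRUE) {
  stopifnot(is.data.frame(data))
  if (!all(c("r", "g", "b") %in% names(data))) {
    stop("`data` must have columns r, g, b", call. = FALSE)
  }
  if (!inherits(constants, "tch_constants")) {
    constants <- do.call(tch_constants, as.list(constants))
  }
  sc <- pixel_scores(data$r, data$g, data$b, constants, bits = bits,
                     blue_adjustment = blue_adjustment)
  data <- tibble::as_tibble(data)
  if ("class" %in% names(data)) data <- dplyr::rename(data, truth = "class")
  data <- data[setdiff(names(data), names(sc))]
  dplyr::bind_cols(data, sc)
}

#' @rdname classify_pixels
#' @param r,g,b Scalar raw channel values.
#' @export
classify_pixel <- function(r, g, b, constants = tch_constants(), bits = 8,
                           blue_adjustment = TRUE) {
  classify_pixels(tibble::tibble(r = r, g = g, b = b), constants,
                  bits = bits, blue_adjustment = blue_adjustment)
}

# Vectorized score/assignment core shared by the table, raster, and optimizer
# paths. Returns a tibble of h, s, v, the four scores, score_max and class.
pixel_scores <- function(r, g, b, constants, bits = 8, blue_adjustment = TRUE) {
  rn <- normalize_channel(r, bits)
  gn <- normalize_channel(g, bits)
  bn <- normalize_channel(b, bits)
  if (blue_adjustment) bn <- apply_blue_adjustment(rn, gn, bn, bits)
  hsv <- rgb_to_hsv(rn, gn, bn)
  assign_scores(hsv$h, hsv$s, hsv$v, constants)
}

# Scores + class from HSV; the zero-saturation branch lives here.
assign_scores <- function(h, s, v, constants) {
  G <- score_green(rescale_hue_green(h), constants$c_g)
  R <- score_red(rescale_hue_red(h), constants$c_r)
  Y <- score_gray(s, constants$c_y)
  D <- score_shadow(v, constants$c_d)
  achrom <- s == 0
  if (any(achrom)) {
    # Zero chroma: hue is undefined, so the hue-based scores carry no
    # information; gray competes with shadow through Y' = Y - D.
    G[achrom] <- 0
    R[achrom] <- 0
    Y[achrom] <- Y[achrom] - D[achrom]
  }
  m <- cbind(G, R, Y, D)
  X <- pmax(G, R, Y, D)
  cls <- max.col(m, ties.method = "first")
  cls[X <= constants$t] <- 5L
  tibble::tibble(
    h = h, s = s, v = v,
    score_green = G, score_red = R, score_gray = Y, score_shadow = D,
    score_max = X,
    class = factor(tch_class_levels()[cls], levels = tch_class_levels())
  )
}
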