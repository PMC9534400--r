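# Unit tests for the per-pixel color model: normalization, the blue
# adjustment, HSV conversion, hue rescaling, the score curves, and class
# assignment.

test_that("max normalization maps raw channels onto [0, 1]", {
  expect_equal(normalize_channel(c(255, 0, 51, 102, 204), bits = 8),
               c(1, 0, 0.2, 0.4, 0.8))
  expect_equal(normalize_channel(4095, bits = 12), 1)
  expect_error(normalize_channel(256, bits = 8), "\\[0, 255\\]")
  expect_error(normalize_channel(-1, bits = 8), "\\[0, 255\\]")
  expect_error(normalize_channel(10.5, bits = 8), "whole numbers")
})

test_that("blue adjustment triggers only on the hue-anchor configurations", {
  # b == r with g >= r: green anchor
  expect_equal(apply_blue_adjustment(100 / 255, 101 / 255, 100 / 255),
               100 / 255 - 1 / 256)
  # b == g with r >= g: red anchor
  expect_equal(apply_blue_adjustment(150 / 255, 90 / 255, 90 / 255),
               90 / 255 - 1 / 256)
  # no channel equality: untouched
  expect_equal(apply_blue_adjustment(0.2, 0.4, 0.8), 0.8)
  # b == r but g < r (blue is the max): untouched
  expect_equal(apply_blue_adjustment(0.5, 0.2, 0.5), 0.5)
  # floor at zero
  expect_equal(apply_blue_adjustment(0, 200 / 255, 0), 0)
  # adjustment step scales with bit depth
  expect_equal(apply_blue_adjustment(0.5, 0.6, 0.5, bits = 12),
               0.5 - 1 / 4096)
})

test_that("HSV conversion follows the hexcone with H in [0, 1)", {
  expect_equal(rgb_to_hsv(0, 1, 0), tibble::tibble(h = 1 / 3, s = 1, v = 1))
  expect_equal(rgb_to_hsv(0.5, 0.5, 0.5),
               tibble::tibble(h = 0, s = 0, v = 0.5))
  got <- rgb_to_hsv(180 / 255, 60 / 255, 50 / 255)
  expect_equal(got$h, 0.012821, tolerance = 1e-4)
  expect_equal(got$s, 0.722222, tolerance = 1e-5)
  expect_equal(got$v, 0.705882, tolerance = 1e-5)
  expect_error(rgb_to_hsv(1.2, 0, 0), "\\[0, 1\\]")
})

test_that("hue rescaling anchors green at 1/3 and red at 0/1", {
  expect_equal(rescale_hue_green(1 / 3), 1)
  expect_equal(rescale_hue_green(0.25), 0.5)
  expect_equal(rescale_hue_green(0), -1)
  expect_equal(rescale_hue_red(0), 1)
  expect_equal(rescale_hue_red(1 / 12), 0.5)
  expect_equal(rescale_hue_red(1 / 3), -1)
  # symmetry: G(H) = G(2/3 - H), R(H) = R(1 - H)
  hs <- seq(0, 0.99, by = 0.01)
  expect_equal(rescale_hue_green(hs), rescale_hue_green(2 / 3 - hs))
  expect_equal(rescale_hue_red(hs), rescale_hue_red(1 - hs))
})

test_that("score curves hit their anchors and stated values", {
  expect_equal(score_green(1, 5), 1)
  expect_equal(score_green(0.5, 5), (sqrt(5) - 1) / 4)
  expect_equal(score_red(-1, 5), 0)
  expect_equal(score_red(1, 2), 1)
  expect_equal(score_gray(0, 1e7), 1)
  expect_equal(score_gray(1, 1e7), 0)
  expect_equal(score_gray(0.3, 1e7), (1e7^0.7 - 1) / (1e7 - 1))
  expect_equal(score_gray(0.3, 1e7), 0.0079432, tolerance = 1e-4)
  expect_equal(score_shadow(0, 1e4), 1)
  expect_equal(score_shadow(0.5, 1e4), 99 / 9999)
  expect_equal(score_shadow(20 / 255, 1e4), 0.48561, tolerance = 1e-3)
  expect_error(score_green(0.5, 1.5), ">= 2")
  expect_error(score_gray(0.5, 1), ">= 2")
})

# access the shared curve through the public surface
score_curve_probe <- function(x, c_) score_green(x, c_)

test_that("score curves stay in range and are monotone on their supports", {
  h <- seq(0, 1 - 1e-9, length.out = 501)
  for (c_ in c(2, 5, 100, 1e6)) {
    G <- score_green(rescale_hue_green(h), c_)
    R <- score_red(rescale_hue_red(h), c_)
    expect_true(all(G >= 0 & G <= 1))
    expect_true(all(R >= 0 & R <= 1))
    # support: G > 0 exactly on (1/6, 1/2); R > 0 on [0,1/6) U (5/6, 1)
    expect_equal(G > 0, h > 1 / 6 & h < 1 / 2)
    expect_equal(R > 0, h < 1 / 6 | h > 5 / 6)
    # strictly decreasing in distance from the anchor (on the open support)
    on_g <- h > 1 / 6 & h <= 1 / 3
    expect_true(all(diff(G[on_g]) > 0))
    on_r <- h < 1 / 6
    expect_true(all(diff(R[on_r]) < 0))
  }
  s <- seq(0, 1, length.out = 101)
  for (c_ in c(2, 1e4, 1e8)) {
    Y <- score_gray(s, c_)
    expect_true(all(Y >= 0 & Y <= 1))
    expect_true(all(diff(Y) < 0))
  }
  # c = 2 curve is 2^x - 1; large c concentrates mass at the anchor
  x <- seq(0, 1, by = 0.05)
  expect_equal(score_curve_probe(x, 2), 2^x - 1)
  expect_lt(max(score_curve_probe(x[x <= 0.75], 1e8)), 0.02)
})

test_that("classification reproduces the worked pixels", {
  cc <- tch_constants(c_g = 5, c_r = 5, c_y = 1e7, c_d = 1e4, t = 0.1)
  px <- classify_pixels(
    data.frame(r = c(76, 128, 10, 180), g = c(175, 128, 10, 60),
               b = c(80, 128, 10, 50)), cc)
  expect_equal(as.character(px$class), c("green", "gray", "shadow", "red"))
  expect_equal(px$score_green[1], 0.921, tolerance = 1e-3)
  expect_equal(px$score_red[4], 0.8544, tolerance = 1e-3)
  # near-black gray: shadow beats gray
  expect_gt(px$score_shadow[3], px$score_gray[3])
})

test_that("the blue adjustment rescues the green-anchor pathology", {
  cc <- tch_constants()
  with_adj <- classify_pixel(100, 101, 100, cc)
  without <- classify_pixel(100, 101, 100, cc, blue_adjustment = FALSE)
  expect_equal(as.character(with_adj$class), "gray")
  expect_equal(as.character(without$class), "green")
  expect_equal(without$score_green, 1) # H = 1/3 exactly without adjustment
})

test_that("achromatic dark pixels always classify shadow, never gray", {
  cc <- tch_constants()
  v <- 0:12 # V <= 0.05 at 8 bits
  got <- classify_pixels(data.frame(r = v, g = v, b = v), cc)
  expect_true(all(got$class == "shadow"))
})

test_that("every pixel receives exactly one of the five outcomes", {
  cc <- tch_constants(t = 0.3)
  set.seed(7)
  n <- 5000
  got <- classify_pixels(
    data.frame(r = sample(0:255, n, TRUE), g = sample(0:255, n, TRUE),
               b = sample(0:255, n, TRUE)), cc)
  expect_false(anyNA(got$class))
  expect_true(all(levels(got$class) ==
                    c("green", "red", "gray", "shadow", "unclassified")))
  # threshold is strict: X <= t is unclassified, X > t never is
  expect_true(all((got$score_max <= cc$t) == (got$class == "unclassified")))
})

test_that("vectorized classification matches the scalar oracle", {
  cc <- tch_constants()
  set.seed(42)
  n <- 20000
  r <- sample(0:255, n, TRUE); g <- sample(0:255, n, TRUE)
  b <- sample(0:255, n, TRUE)
  got <- classify_pixels(data.frame(r = r, g = g, b = b), cc)
  want <- oracle_classify_many(r, g, b, cc)
  expect_identical(as.character(got$class), want)
  # and under a different threshold / constants set
  cc2 <- tch_constants(c_g = 1000, c_r = 2, c_y = 100, c_d = 1e8, t = 0.25)
  got2 <- classify_pixels(data.frame(r = r, g = g, b = b), cc2)
  want2 <- oracle_classify_many(r, g, b, cc2)
  expect_identical(as.character(got2$class), want2)
})

test_that("constants are validated", {
  expect_error(tch_constants(c_g = 1), ">= 2")
  expect_error(tch_constants(t = 1), "\\[0, 1\\)")
  expect_error(tch_constants(t = -0.1), "\\[0, 1\\)")
})
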