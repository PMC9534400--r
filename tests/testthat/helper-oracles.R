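# Independent reference implementations used to check the package: a scalar
# per-pixel classifier written directly from the model equations (hand-coded
# hexcone conversion, explicit branches), and a label-propagation connected
# components oracle. These deliberately share no code with the package.

# Scalar hexcone RGB -> HSV; ties on the max channel resolve r, then g.
oracle_rgb_to_hsv <- function(r, g, b) {
  mx <- max(r, g, b)
  mn <- min(r, g, b)
  d <- mx - mn
  v <- mx
  s <- if (mx == 0) 0 else d / mx
  if (d == 0) {
    h <- 0
  } else if (mx == r) {
    h <- ((g - b) / d) %% 6 / 6
  } else if (mx == g) {
    h <- ((b - r) / d + 2) / 6
  } else {
    h <- ((r - g) / d + 4) / 6
  }
  if (h >= 1) h <- 0
  c(h = h, s = s, v = v)
}

# Full scalar pipeline for one raw pixel. Returns the class label.
oracle_classify <- function(r, g, b, constants, bits = 8,
                            blue_adjustment = TRUE) {
  maxv <- 2^bits - 1
  rn <- r / maxv; gn <- g / maxv; bn <- b / maxv
  if (blue_adjustment &&
      ((bn == rn && gn >= rn) || (bn == gn && rn >= gn))) {
    bn <- max(bn - 1 / 2^bits, 0)
  }
  hsv <- oracle_rgb_to_hsv(rn, gn, bn)
  h <- hsv[["h"]]; s <- hsv[["s"]]; v <- hsv[["v"]]
  hg <- 1 - abs(h - 1 / 3) / (1 / 6)
  hr <- abs(1 / 2 - h) / (1 / 6) - 2
  G <- if (hg < 0) 0 else (constants$c_g^hg - 1) / (constants$c_g - 1)
  R <- if (hr < 0) 0 else (constants$c_r^hr - 1) / (constants$c_r - 1)
  Y <- (constants$c_y^(1 - s) - 1) / (constants$c_y - 1)
  D <- (constants$c_d^(1 - v) - 1) / (constants$c_d - 1)
  if (s == 0) {
    G <- 0
    R <- 0
    Y <- Y - D
  }
  scores <- c(green = G, red = R, gray = Y, shadow = D)
  X <- max(scores)
  if (X <= constants$t) return("unclassified")
  names(scores)[which(scores == X)[1]] # first = precedence green>red>gray>shadow
}

oracle_classify_many <- function(r, g, b, constants, bits = 8,
                                 blue_adjustment = TRUE) {
  vapply(seq_along(r), function(k) {
    oracle_classify(r[k], g[k], b[k], constants, bits, blue_adjustment)
  }, character(1))
}

# Connected components by iterative label propagation (each cell takes the
# minimum label among itself and its rook neighbors until stable), then
# labels are renumbered in first-appearance scan order.
oracle_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    new <- lab
    up <- rbind(Inf, lab[-nr, , drop = FALSE]); up[up == 0] <- Inf
    dn <- rbind(lab[-1, , drop = FALSE], Inf); dn[dn == 0] <- Inf
    lf <- cbind(Inf, lab[, -nc, drop = FALSE]); lf[lf == 0] <- Inf
    rt <- cbind(lab[, -1, drop = FALSE], Inf); rt[rt == 0] <- Inf
    cand <- pmin(lab, up, dn, lf, rt)
    new[mask] <- cand[mask]
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- unique(lab[lab > 0])
  lab[lab > 0] <- match(lab[lab > 0], ids)
  matrix(as.integer(lab), nr, nc)
}
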