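# Minimal georeferenced raster container and the raster-level workflow:
# model projection, forest/non-forest masking, and plain-text / TIFF I/O.

#' Integer codes of the classified raster
#'
#' Fixed artifact convention for single-band class rasters:
#' 0 = unclassified/background, 1 = red, 2 = gray, 3 = green, 4 = shadow,
#' 255 = nodata/masked.
#'
#' @return Named integer vector.
#' @export
class_codes <- function() {
  c(unclassified = 0L, red = 1L, gray = 2L, green = 3L, shadow = 4L,
    nodata = 255L)
}

#' Display colors for the classified raster
#'
#' Orange for the red class, light gray for gray, dark green for green,
#' black for shadow, white for unclassified background.
#'
#' @return Named character vector of colors keyed by class name.
#' @export
class_colors <- function() {
  c(unclassified = "#FFFFFF", red = "#E66101", gray = "#C8C8C8",
    green = "#1B5E20", shadow = "#000000", nodata = "#9ECAE1")
}

#' Create a georeferenced raster
#'
#' A lightweight in-memory raster: a matrix (single band) or a
#' rows x cols x 3 array (RGB), an affine georeference given by the upper-left
#' corner and square pixel size, a CRS label, and a nodata value. Row 1 is the
#' top of the image.
#'
#' @param data Numeric matrix or 3-band array.
#' @param xmin,ymax World coordinates of the upper-left corner.
#' @param px Pixel size in CRS units (meters for projected CRS).
#' @param crs CRS label, e.g. `"EPSG:5070"`. Geographic CRS (degrees) are
#'   recognized from `"EPSG:4326"` / `"longlat"` labels.
#' @param nodata Nodata value (default `NA`).
#' @return A `tch_raster` object.
#' @examples
#' tch_raster(matrix(0L, 4, 4), px = 1)
#' @export
tch_raster <- function(data, xmin = 0, ymax = NULL, px = 1,
                       crs = "EPSG:5070", nodata = NA_real_) {
  stopifnot(is.array(data), length(dim(data)) %in% c(2L, 3L), px > 0)
  if (length(dim(data)) == 3L && dim(data)[3] != 3L) {
    stop("3-D raster data must have exactly 3 bands", call. = FALSE)
  }
  if (is.null(ymax)) ymax <- nrow(data) * px
  structure(
    list(data = data, xmin = xmin, ymax = ymax, px = px, crs = crs,
         nodata = nodata, provenance = list()),
    class = "tch_raster"
  )
}

#' @export
print.tch_raster <- function(x, ...) {
  d <- dim(x$data)
  cat("<tch_raster> ", d[1], "x", d[2],
      if (length(d) == 3L) paste0("x", d[3], " (RGB)") else "(single band)",
      " px =", x$px, " ul = (", x$xmin, ",", x$ymax, ") crs =", x$crs, "\n")
  invisible(x)
}

#' @export
dim.tch_raster <- function(x) dim(x$data)

crs_is_geographic <- function(crs) {
  grepl("4326|longlat|CRS84|WGS\\s*84$", crs, ignore.case = TRUE)
}

# World coordinates of pixel centers.
pixel_centers <- function(raster, rows, cols) {
  list(
    x = raster$xmin + (cols - 0.5) * raster$px,
    y = raster$ymax - (rows - 0.5) * raster$px
  )
}

#' Classify an RGB raster
#'
#' Applies the per-pixel crown-health model across a 3-band raster, producing
#' a single-band coded class raster (see [class_codes()]). Pixels where any
#' band equals the raster's nodata value (or is `NA`) receive the nodata code.
#' The whole grid is classified in one vectorized pass; results are identical
#' to per-pixel evaluation.
#'
#' @param raster A 3-band `tch_raster` (bands ordered R, G, B, raw unsigned
#'   integers).
#' @param constants A [tch_constants()] object (carries the threshold `t`).
#' @param bits Bit depth of the imagery.
#' @param blue_adjustment Apply the blue-channel adjustment (default TRUE).
#' @return A single-band `tch_raster` of class codes with provenance
#'   (constants, threshold, bits) recorded.
#' @export
classify_raster <- function(raster, constants = tch_constants(), bits = 8,
                            blue_adjustment = TRUE) {
  stopifnot(inherits(raster, "tch_raster"))
  d <- dim(raster$data)
  if (length(d) != 3L || d[3] != 3L) {
    stop("`raster` must have exactly 3 bands ordered R, G, B", call. = FALSE)
  }
  r <- as.vector(raster$data[, , 1])
  g <- as.vector(raster$data[, , 2])
  b <- as.vector(raster$data[, , 3])
  bad <- is.na(r) | is.na(g) | is.na(b)
  if (!is.na(raster$nodata)) {
    bad <- bad | r == raster$nodata | g == raster$nodata | b == raster$nodata
  }
  codes <- rep(class_codes()[["nodata"]], length(r))
  if (any(!bad)) {
    sc <- pixel_scores(r[!bad], g[!bad], b[!bad], constants, bits = bits,
                       blue_adjustment = blue_adjustment)
    codes[!bad] <- class_codes()[as.character(sc$class)]
  }
  out <- tch_raster(matrix(as.integer(codes), d[1], d[2]),
                    xmin = raster$xmin, ymax = raster$ymax, px = raster$px,
                    crs = raster$crs, nodata = class_codes()[["nodata"]])
  out$provenance <- list(constants = unclass(constants), bits = bits,
                         blue_adjustment = blue_adjustment)
  out
}

#' Build a forest/non-forest mask from a categorical land-cover raster
#'
#' Reclassifies a single-band categorical raster (e.g., 30 m NLCD) to a
#' binary mask: 1 (forest) where the cell value is one of `forest_values`
#' — by default the NLCD forest classes 41 (deciduous), 42 (evergreen),
#' 43 (mixed) and 90 (woody wetlands) — and 0 (non-forest) everywhere else.
#'
#' @param landcover A single-band `tch_raster` of land-cover codes.
#' @param forest_values Integer vector of land-cover values treated as forest.
#' @return A binary `tch_raster` at the land-cover resolution.
#' @export
build_forest_mask <- function(landcover, forest_values = c(41, 42, 43, 90)) {
  stopifnot(inherits(landcover, "tch_raster"), length(dim(landcover$data)) == 2L)
  m <- matrix(as.integer(landcover$data %in% forest_values),
              nrow(landcover$data), ncol(landcover$data))
  tch_raster(m, xmin = landcover$xmin, ymax = landcover$ymax,
             px = landcover$px, crs = landcover$crs, nodata = NA_real_)
}

#' Mask a classified raster with a coarse forest mask
#'
#' Sets every fine pixel whose *center* falls inside a non-forest coarse cell
#' to the nodata/masked code (255); pixels in forest cells, and pixels whose
#' centers fall outside the mask's extent, are left unchanged. The mask may be
#' at a coarser resolution (nearest-neighbor lookup by pixel center). Masking
#' is idempotent.
#'
#' @param classified A single-band classified `tch_raster`.
#' @param mask A binary `tch_raster` from [build_forest_mask()].
#' @return The masked `tch_raster`.
#' @export
apply_mask <- function(classified, mask) {
  stopifnot(inherits(classified, "tch_raster"), inherits(mask, "tch_raster"))
  if (!identical(classified$crs, mask$crs)) {
    stop("CRS mismatch between classified raster and mask", call. = FALSE)
  }
  d <- dim(classified$data)
  cx_min <- classified$xmin
  cx_max <- classified$xmin + d[2] * classified$px
  cy_max <- classified$ymax
  cy_min <- classified$ymax - d[1] * classified$px
  md <- dim(mask$data)
  mx_min <- mask$xmin
  mx_max <- mask$xmin + md[2] * mask$px
  my_max <- mask$ymax
  my_min <- mask$ymax - md[1] * mask$px
  if (cx_min >= mx_max || cx_max <= mx_min || cy_min >= my_max || cy_max <= my_min) {
    stop("classified raster and mask extents are disjoint", call. = FALSE)
  }
  rows <- rep(seq_len(d[1]), times = d[2])
  cols <- rep(seq_len(d[2]), each = d[1])
  ctr <- pixel_centers(classified, rows, cols)
  mcol <- floor((ctr$x - mx_min) / mask$px) + 1L
  mrow <- floor((my_max - ctr$y) / mask$px) + 1L
  inside <- mcol >= 1L & mcol <= md[2] & mrow >= 1L & mrow <= md[1]
  nonforest <- inside
  nonforest[inside] <- mask$data[cbind(mrow[inside], mcol[inside])] == 0L
  out <- classified
  out$data[cbind(rows[nonforest], cols[nonforest])] <- class_codes()[["nodata"]]
  out
}

#' Convert a raster to a tidy tibble
#'
#' One row per pixel with world coordinates of the pixel center; single-band
#' rasters get a `value` column, RGB rasters get `r`, `g`, `b`.
#'
#' @param x A `tch_raster`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y` and the value column(s).
#' @export
as_tibble.tch_raster <- function(x, ...) {
  d <- dim(x$data)
  rows <- rep(seq_len(d[1]), times = d[2])
  cols <- rep(seq_len(d[2]), each = d[1])
  ctr <- pixel_centers(x, rows, cols)
  out <- tibble::tibble(row = rows, col = cols, x = ctr$x, y = ctr$y)
  if (length(d) == 2L) {
    out$value <- as.vector(x$data)
  } else {
    out$r <- as.vector(x$data[, , 1])
    out$g <- as.vector(x$data[, , 2])
    out$b <- as.vector(x$data[, , 3])
  }
  out
}

#' Write / read a single-band raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange (`.asc`): a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values
#' from the top of the grid down. The CRS label is stored in a `.prj.json`
#' sidecar.
#'
#' @param raster A single-band `tch_raster`.
#' @param path Output `.asc` path.
#' @return `path` (write) or a `tch_raster` (read).
#' @export
write_raster_ascii <- function(raster, path) {
  stopifnot(inherits(raster, "tch_raster"), length(dim(raster$data)) == 2L)
  d <- dim(raster$data)
  nodata <- if (is.na(raster$nodata)) -9999 else raster$nodata
  m <- raster$data
  m[is.na(m)] <- nodata
  header <- c(
    paste("ncols", d[2]), paste("nrows", d[1]),
    paste("xllcorner", format(raster$xmin, scientific = FALSE)),
    paste("yllcorner", format(raster$ymax - d[1] * raster$px, scientific = FALSE)),
    paste("cellsize", format(raster$px, scientific = FALSE)),
    paste("NODATA_value", format(nodata, scientific = FALSE))
  )
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  jsonlite::write_json(list(crs = raster$crs), paste0(path, ".prj.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_raster_ascii
#' @export
read_raster_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  keys <- vapply(hdr, `[[`, "", 1)
  vals <- as.numeric(vapply(hdr, `[[`, "", 2))
  names(vals) <- keys
  ncols <- as.integer(vals[["ncols"]]); nrows <- as.integer(vals[["nrows"]])
  body <- lines[-(1:6)]
  m <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  stopifnot(nrow(m) == nrows, ncol(m) == ncols)
  nodata <- vals[["nodata_value"]]
  m[m == nodata] <- NA
  crs <- "EPSG:5070"
  sidecar <- paste0(path, ".prj.json")
  if (file.exists(sidecar)) crs <- jsonlite::read_json(sidecar)$crs
  px <- vals[["cellsize"]]
  tch_raster(m, xmin = vals[["xllcorner"]], ymax = vals[["yllcorner"]] + nrows * px,
             px = px, crs = crs, nodata = NA_real_)
}

#' Write / read a raster as TIFF with a georeference sidecar
#'
#' Uses the `tiff` package; the affine transform, CRS, nodata value and bit
#' depth are carried in a `.aux.json` sidecar so round-trips preserve
#' georeferencing.
#'
#' @param raster A `tch_raster` (single band or RGB).
#' @param path Output `.tif` path.
#' @param bits Bit depth for integer encoding.
#' @return `path` (write) or a `tch_raster` (read).
#' @export
write_raster_tiff <- function(raster, path, bits = 8) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the `tiff` package is required for TIFF I/O", call. = FALSE)
  }
  stopifnot(inherits(raster, "tch_raster"))
  maxv <- 2^bits - 1
  img <- raster$data / maxv
  img[is.na(img)] <- 0
  tiff::writeTIFF(img, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(xmin = raster$xmin, ymax = raster$ymax, px = raster$px,
         crs = raster$crs, nodata = raster$nodata, bits = bits),
    paste0(path, ".aux.json"), auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname write_raster_tiff
#' @export
read_raster_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the `tiff` package is required for TIFF I/O", call. = FALSE)
  }
  img <- tiff::readTIFF(path)
  aux <- list(xmin = 0, ymax = NULL, px = 1, crs = "EPSG:5070",
              nodata = NA, bits = 8)
  sidecar <- paste0(path, ".aux.json")
  if (file.exists(sidecar)) {
    got <- jsonlite::read_json(sidecar)
    for (nm in names(got)) if (!is.null(got[[nm]])) aux[[nm]] <- got[[nm]]
  }
  data <- round(img * (2^aux$bits - 1))
  if (length(dim(data)) == 3L) data <- data[, , 1:3, drop = FALSE]
  tch_raster(data, xmin = aux$xmin,
             ymax = if (is.null(aux$ymax)) nrow(data) * aux$px else aux$ymax,
             px = aux$px, crs = aux$crs,
             nodata = if (is.null(aux$nodata) || is.na(aux$nodata)) NA_real_ else aux$nodata)
}
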