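# Damaged-tree object extraction: rook-adjacency connected components of red
# and gray pixels, pixel-boundary polygonization with holes, the area filter,
# and inside-constrained interior points.

#' Label rook-adjacency connected components
#'
#' Labels 4-connected (edge-sharing, "rook move") components of TRUE cells in
#' a logical matrix. Diagonal-only contacts do *not* join components.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same shape: 0 for background, 1..k for the
#'   components (labelled in scan order).
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  stack <- integer(nr * nc)
  for (start in which(mask & labels == 0L)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    top <- 1L
    stack[1L] <- start
    labels[start] <- lab
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      i <- ((cur - 1L) %% nr) + 1L
      j <- ((cur - 1L) %/% nr) + 1L
      if (i > 1L) {
        nb <- cur - 1L
        if (mask[nb] && labels[nb] == 0L) { labels[nb] <- lab; top <- top + 1L; stack[top] <- nb }
      }
      if (i < nr) {
        nb <- cur + 1L
        if (mask[nb] && labels[nb] == 0L) { labels[nb] <- lab; top <- top + 1L; stack[top] <- nb }
      }
      if (j > 1L) {
        nb <- cur - nr
        if (mask[nb] && labels[nb] == 0L) { labels[nb] <- lab; top <- top + 1L; stack[top] <- nb }
      }
      if (j < nc) {
        nb <- cur + nr
        if (mask[nb] && labels[nb] == 0L) { labels[nb] <- lab; top <- top + 1L; stack[top] <- nb }
      }
    }
  }
  labels
}

# Trace the boundary rings of one component (logical matrix) as polygons on
# pixel edges. Returns a list of rings; each ring is a 2-column matrix of
# world (x, y) vertices, counterclockwise for the exterior, clockwise for
# holes (interior always on the left). Vertices are traced on the integer
# pixel-corner grid and converted to world coordinates at the end.
trace_rings <- function(comp, xmin, ymax, px) {
  nr <- nrow(comp); nc <- ncol(comp)
  cells <- which(comp, arr.ind = TRUE)
  in_comp <- function(i, j) {
    ok <- i >= 1L & i <= nr & j >= 1L & j <= nc
    ok[ok] <- comp[cbind(i[ok], j[ok])]
    ok
  }
  i <- cells[, 1]; j <- cells[, 2]
  # Directed boundary edges with the component interior on the left (world
  # orientation, y up). Vertex key = vr * (nc + 1) + vc with vr in 0..nr,
  # vc in 0..nc (vr 0 = top edge of row 1).
  edges <- list()
  add_edges <- function(exposed, from_r, from_c, to_r, to_c) {
    if (!any(exposed)) return(NULL)
    cbind(from_r[exposed], from_c[exposed], to_r[exposed], to_c[exposed])
  }
  e <- rbind(
    add_edges(!in_comp(i + 1L, j), i, j - 1L, i, j),         # bottom: BL -> BR
    add_edges(!in_comp(i, j + 1L), i, j, i - 1L, j),         # right:  BR -> TR
    add_edges(!in_comp(i - 1L, j), i - 1L, j, i - 1L, j - 1L), # top:   TR -> TL
    add_edges(!in_comp(i, j - 1L), i - 1L, j - 1L, i, j - 1L) # left:  TL -> BL
  )
  n_e <- nrow(e)
  from_key <- e[, 1] * (nc + 1L) + e[, 2]
  to_key <- e[, 3] * (nc + 1L) + e[, 4]
  # outgoing edges indexed by start vertex
  ord <- order(from_key)
  starts <- from_key[ord]
  first <- match(unique(starts), starts)
  lookup <- stats::setNames(first, unique(starts))
  used <- logical(n_e)

  # direction codes in row-space deltas (dr, dc)
  dirs <- cbind(dr = e[, 3] - e[, 1], dc = e[, 4] - e[, 2])
  # world-left turn from an incoming direction (y up): rotate (dx, dy) left;
  # in row space (r down) this is (dr, dc) -> (-dc, -dr)? Derive via world:
  # world dir (dx, dy) = (dc, -dr); left turn -> (-dy, dx) = (dr, dc)_new with
  # dc_new = -dy = dr_old? Keep a small table instead.
  # Row-space dirs: E=(0,1), N=(-1,0), W=(0,-1), S=(1,0).
  # World equivalents: E->+x, N->+y, W->-x, S->-y. Left turn cycle in world:
  # +x -> +y -> -x -> -y, i.e. row-space E -> N -> W -> S -> E.
  dir_code <- function(dr, dc) (dr == 0 & dc == 1) * 1 + (dr == -1) * 2 +
    (dr == 0 & dc == -1) * 3 + (dr == 1) * 4
  codes <- dir_code(dirs[, 1], dirs[, 2])
  left_of <- c(2L, 3L, 4L, 1L)     # E->N, N->W, W->S, S->E
  right_of <- c(4L, 1L, 2L, 3L)

  outgoing <- function(vkey) {
    pos <- lookup[as.character(vkey)]
    if (is.na(pos)) return(integer(0))
    idx <- integer(0)
    p <- pos
    while (p <= n_e && starts[p] == vkey) {
      idx <- c(idx, ord[p])
      p <- p + 1L
    }
    idx[!used[idx]]
  }

  rings <- list()
  for (e0 in seq_len(n_e)) {
    if (used[e0]) next
    ring_r <- e[e0, 1]; ring_c <- e[e0, 2]
    cur <- e0
    repeat {
      used[cur] <- TRUE
      ring_r <- c(ring_r, e[cur, 3]); ring_c <- c(ring_c, e[cur, 4])
      nxt_key <- to_key[cur]
      cand <- outgoing(nxt_key)
      if (length(cand) == 0L) break
      if (length(cand) > 1L) {
        # pinch vertex: prefer the world-left turn to keep rings simple
        pref <- c(left_of[codes[cur]], codes[cur], right_of[codes[cur]])
        cand <- cand[order(match(codes[cand], pref))]
      }
      cur <- cand[1L]
    }
    # drop collinear intermediate vertices
    keep <- rep(TRUE, length(ring_r))
    if (length(ring_r) > 3L) {
      for (k in 2:(length(ring_r) - 1L)) {
        if ((ring_r[k] - ring_r[k - 1L]) == (ring_r[k + 1L] - ring_r[k]) &&
            (ring_c[k] - ring_c[k - 1L]) == (ring_c[k + 1L] - ring_c[k])) {
          keep[k] <- FALSE
        }
      }
    }
    ring_r <- ring_r[keep]; ring_c <- ring_c[keep]
    rings[[length(rings) + 1L]] <- cbind(
      x = xmin + ring_c * px,
      y = ymax - ring_r * px
    )
  }
  rings
}

ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Extract crown objects from a classified raster
#'
#' Converts contiguous (rook-adjacency) groupings of red and gray pixels into
#' polygons traced on pixel boundaries (holes preserved), with pixel counts,
#' areas in square meters, and inside-constrained interior points. Red and
#' gray components are extracted independently and never merged.
#'
#' @param classified A single-band classified `tch_raster` in a projected
#'   CRS (pixel size in meters); geographic CRS is an error since areas in
#'   m^2 are undefined there.
#' @param classes Which classes to extract (default red and gray).
#' @return A `tch_objects` tibble: `id`, `class`, `pixel_count`, `area_m2`,
#'   `point_x`, `point_y` and a `rings` list-column (each element a list of
#'   2-column vertex matrices; first ring exterior, others holes).
#' @export
extract_components <- function(classified, classes = c("red", "gray")) {
  stopifnot(inherits(classified, "tch_raster"), length(dim(classified$data)) == 2L)
  if (crs_is_geographic(classified$crs)) {
    stop("classified raster is in a geographic CRS; area in m^2 is undefined",
         call. = FALSE)
  }
  codes <- class_codes()
  px <- classified$px
  out <- list()
  for (cl in classes) {
    mask <- classified$data == codes[[cl]]
    mask[is.na(mask)] <- FALSE
    labels <- label_components(mask)
    k <- max(labels)
    if (k == 0L) next
    for (comp_id in seq_len(k)) {
      comp <- labels == comp_id
      cells <- which(comp, arr.ind = TRUE)
      n_px <- nrow(cells)
      rings <- trace_rings(comp, classified$xmin, classified$ymax, px)
      areas <- vapply(rings, ring_signed_area, numeric(1))
      ring_order <- order(areas <= 0) # exterior (positive) first
      rings <- rings[ring_order]
      pt <- interior_point_of(comp, rings, classified)
      out[[length(out) + 1L]] <- tibble::tibble(
        class = cl,
        pixel_count = n_px,
        area_m2 = n_px * px^2,
        point_x = pt[1], point_y = pt[2],
        rings = list(rings)
      )
    }
  }
  objs <- if (length(out) == 0) {
    tibble::tibble(class = character(), pixel_count = integer(),
                   area_m2 = numeric(), point_x = numeric(),
                   point_y = numeric(), rings = list())
  } else {
    dplyr::bind_rows(out)
  }
  objs <- dplyr::mutate(objs, id = dplyr::row_number(), .before = 1)
  class(objs) <- c("tch_objects", class(objs))
  objs
}

# Inside-constrained representative point: the polygon centroid when it falls
# strictly inside; otherwise the center of the component pixel nearest the
# centroid within the centroid's row (guaranteed interior for pixel polygons).
interior_point_of <- function(comp, rings, raster) {
  cells <- which(comp, arr.ind = TRUE)
  ctr <- pixel_centers(raster, cells[, 1], cells[, 2])
  centroid <- c(mean(ctr$x), mean(ctr$y))
  if (point_in_rings(centroid[1], centroid[2], rings)) return(centroid)
  # fall back to a pixel center in the row whose center y is nearest
  row_best <- cells[which.min(abs(ctr$y - centroid[2])), 1]
  cols <- sort(cells[cells[, 1] == row_best, 2])
  runs <- split(cols, cumsum(c(1L, diff(cols) != 1L)))
  run <- runs[[which.max(lengths(runs))]]
  j <- run[ceiling(length(run) / 2)]
  p <- pixel_centers(raster, row_best, j)
  c(p$x, p$y)
}

#' Point-in-polygon test (even-odd rule)
#'
#' Tests whether a point lies inside a polygon given as a list of rings
#' (exterior plus holes); crossing a hole boundary flips containment.
#'
#' @param x,y Point coordinates.
#' @param rings List of 2-column vertex matrices (closed or open rings).
#' @return Logical.
#' @export
point_in_rings <- function(x, y, rings) {
  inside <- FALSE
  for (ring in rings) {
    xs <- ring[, 1]; ys <- ring[, 2]
    n <- nrow(ring)
    if (xs[1] == xs[n] && ys[1] == ys[n]) n <- n - 1L
    jj <- n
    for (ii in seq_len(n)) {
      if ((ys[ii] > y) != (ys[jj] > y)) {
        xint <- xs[ii] + (y - ys[ii]) / (ys[jj] - ys[ii]) * (xs[jj] - xs[ii])
        if (x < xint) inside <- !inside
      }
      jj <- ii
    }
  }
  inside
}

#' Filter crown objects by area
#'
#' Retains objects whose area satisfies `min_area <= area_m2 <= max_area`
#' (both bounds inclusive). The defaults, 4 and 50 m^2, correspond to crown
#' radii of roughly 1 to 4 m and screen out single-pixel noise and large
#' non-crown patches.
#'
#' @param objects A `tch_objects` tibble from [extract_components()].
#' @param min_area,max_area Inclusive area bounds in m^2.
#' @return The filtered `tch_objects` tibble.
#' @export
filter_by_area <- function(objects, min_area = 4, max_area = 50) {
  if (min_area > max_area) stop("`min_area` must be <= `max_area`", call. = FALSE)
  dplyr::filter(objects, .data$area_m2 >= min_area, .data$area_m2 <= max_area)
}

#' Interior points of crown objects
#'
#' Returns the inside-constrained representative point of each object as a
#' point table (one point per polygon, guaranteed strictly inside even for
#' non-convex shapes whose centroid falls outside).
#'
#' @param objects A `tch_objects` tibble.
#' @return A tibble: `id`, `class`, `area_m2`, `pixel_count`, `x`, `y`.
#' @export
interior_points <- function(objects) {
  if (nrow(objects) == 0) {
    return(tibble::tibble(id = integer(), class = character(),
                          area_m2 = numeric(), pixel_count = integer(),
                          x = numeric(), y = numeric()))
  }
  if (any(vapply(objects$rings, length, integer(1)) == 0)) {
    stop("object with empty geometry", call. = FALSE)
  }
  tibble::tibble(
    id = objects$id, class = objects$class,
    area_m2 = objects$area_m2, pixel_count = objects$pixel_count,
    x = objects$point_x, y = objects$point_y
  )
}

#' Write crown objects to GeoJSON
#'
#' Writes polygon features (with `class`, `area_m2`, `pixel_count`
#' properties) or their interior points as a GeoJSON FeatureCollection.
#' Coordinates are written in the raster's projected CRS, recorded in a
#' top-level `crs_label` member.
#'
#' @param objects A `tch_objects` tibble.
#' @param path Output path.
#' @param geometry `"polygons"` or `"points"`.
#' @param crs CRS label recorded in the file.
#' @return `path`, invisibly.
#' @export
write_objects_geojson <- function(objects, path, geometry = c("polygons", "points"),
                                  crs = "EPSG:5070") {
  geometry <- match.arg(geometry)
  features <- purrr::pmap(
    list(objects$id, objects$class, objects$area_m2, objects$pixel_count,
         objects$rings, objects$point_x, objects$point_y),
    function(id, cl, area, n_px, rings, px_, py_) {
      geom <- if (geometry == "polygons") {
        coords <- purrr::map(rings, function(rg) {
          if (!all(rg[1, ] == rg[nrow(rg), ])) rg <- rbind(rg, rg[1, ])
          unname(apply(rg, 1, as.list, simplify = FALSE))
        })
        list(type = "Polygon", coordinates = coords)
      } else {
        list(type = "Point", coordinates = c(px_, py_))
      }
      list(
        type = "Feature",
        properties = list(id = id, class = cl, area_m2 = area,
                          pixel_count = n_px),
        geometry = geom
      )
    }
  )
  jsonlite::write_json(
    list(type = "FeatureCollection", crs_label = crs, features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
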