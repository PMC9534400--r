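# Rook components, pixel-boundary polygons with holes, the area filter, and
# inside-constrained interior points.

code_raster <- function(m, px = 1) tch_raster(m, px = px)

red_code <- function() crownhealth::class_codes()[["red"]]

grid_from_cells <- function(nr, nc, cells, code = red_code()) {
  m <- matrix(0L, nr, nc)
  m[cells] <- code
  m
}

test_that("diagonal-touching pixels form separate rook components", {
  m <- grid_from_cells(4, 4, cbind(c(2, 3), c(2, 3)))
  objs <- extract_components(code_raster(m), classes = "red")
  expect_equal(nrow(objs), 2L)
  expect_equal(objs$pixel_count, c(1L, 1L))
})

test_that("solid blocks and crosses dissolve into single polygons", {
  m <- grid_from_cells(5, 5, as.matrix(expand.grid(2:4, 2:4)))
  objs <- extract_components(code_raster(m), classes = "red")
  expect_equal(nrow(objs), 1L)
  expect_equal(objs$pixel_count, 9L)
  expect_equal(objs$area_m2, 9)

  plus <- grid_from_cells(5, 5, cbind(c(2, 3, 3, 3, 4), c(3, 2, 3, 4, 3)))
  pobj <- extract_components(code_raster(plus), classes = "red")
  expect_equal(nrow(pobj), 1L)
  expect_equal(pobj$area_m2, 5)
  # shoelace area of the traced rings agrees with the pixel count
  area <- sum(vapply(pobj$rings[[1]], function(rg) {
    x <- rg[, 1]; y <- rg[, 2]; n <- nrow(rg)
    sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  }, numeric(1)))
  expect_equal(area, 5)
})

test_that("component labelling matches an independent flood-fill oracle", {
  set.seed(99)
  for (rep_ in 1:8) {
    m <- matrix(stats::runif(30 * 25) < 0.45, 30, 25)
    expect_identical(label_components(m), oracle_components(m))
  }
})

test_that("total polygon area equals class pixel count times pixel area", {
  set.seed(123)
  px <- 0.6
  m <- matrix(ifelse(stats::runif(400) < 0.3, red_code(), 0L), 20, 20)
  objs <- extract_components(code_raster(m, px = px), classes = "red")
  expect_equal(sum(objs$area_m2), sum(m == red_code()) * px^2)
  shoelace_total <- sum(vapply(objs$rings, function(rings) {
    sum(vapply(rings, function(rg) {
      x <- rg[, 1]; y <- rg[, 2]
      sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(shoelace_total, sum(objs$area_m2))
})

test_that("holes are preserved and excluded from containment", {
  # 5x5 ring of red with a hollow 3x3 center
  m <- matrix(red_code(), 5, 5)
  m[2:4, 2:4] <- 0L
  m[3, 3] <- red_code() # island inside the hole: separate component
  objs <- extract_components(code_raster(m), classes = "red")
  expect_equal(nrow(objs), 2L)
  ring_obj <- objs[which.max(objs$pixel_count), ]
  expect_equal(ring_obj$pixel_count, 16L)
  expect_equal(length(ring_obj$rings[[1]]), 2L) # exterior + hole
  # a point at the center of the hole is not inside the ring polygon
  expect_false(point_in_rings(2.5, 2.5, ring_obj$rings[[1]]))
  expect_true(point_in_rings(0.5, 0.5, ring_obj$rings[[1]]))
})

test_that("the area filter is inclusive at both bounds and idempotent", {
  px <- 1
  m <- matrix(0L, 20, 40)
  m[2:4, 2:4] <- red_code()            # 9 m2: kept
  m[10, 10:12] <- red_code()           # 3 m2: dropped
  m[8:13, 20:29] <- red_code()         # 60 m2: dropped
  m[16:19, 35:39] <- red_code()        # 20 m2: kept
  m[18, 2:5] <- red_code()             # 4 m2: kept (inclusive minimum)
  objs <- extract_components(code_raster(m, px = px), classes = "red")
  expect_equal(nrow(objs), 5L)
  kept <- filter_by_area(objs, 4, 50)
  expect_setequal(kept$area_m2, c(9, 20, 4))
  expect_identical(filter_by_area(kept, 4, 50), kept)
  expect_error(filter_by_area(objs, 50, 4), "min_area")
})

test_that("interior points are the centroid for convex shapes", {
  m <- grid_from_cells(6, 6, as.matrix(expand.grid(2:5, 3:4)))
  objs <- extract_components(code_raster(m), classes = "red")
  pts <- interior_points(objs)
  # 4 rows x 2 cols block: rows 2..5 (y centers 4.5..1.5), cols 3..4
  expect_equal(pts$x, 3)
  expect_equal(pts$y, 3)
})

test_that("a C-shaped polygon with exterior centroid still gets an inside point", {
  # C open to the right: centroid of pixels falls in the mouth
  m <- matrix(0L, 7, 7)
  m[2, 2:6] <- red_code()
  m[6, 2:6] <- red_code()
  m[3:5, 2] <- red_code()
  objs <- extract_components(code_raster(m), classes = "red")
  expect_equal(nrow(objs), 1L)
  rings <- objs$rings[[1]]
  centroid <- c(mean(which(m > 0, arr.ind = TRUE)[, 2] - 0.5),
                mean(7 - which(m > 0, arr.ind = TRUE)[, 1] + 0.5))
  expect_false(point_in_rings(centroid[1], centroid[2], rings))
  pts <- interior_points(objs)
  expect_true(point_in_rings(pts$x, pts$y, rings))
})

test_that("every emitted point lies inside its polygon on random grids", {
  set.seed(7)
  for (rep_ in 1:5) {
    m <- matrix(ifelse(stats::runif(600) < 0.35, red_code(), 0L), 24, 25)
    objs <- extract_components(code_raster(m), classes = "red")
    expect_equal(nrow(interior_points(objs)), nrow(objs))
    ok <- vapply(seq_len(nrow(objs)), function(i) {
      point_in_rings(objs$point_x[i], objs$point_y[i], objs$rings[[i]])
    }, logical(1))
    expect_true(all(ok))
  }
})

test_that("red and gray are extracted independently, never merged", {
  m <- matrix(0L, 5, 5)
  m[2, 2:3] <- class_codes()[["red"]]
  m[2, 4] <- class_codes()[["gray"]] # edge-adjacent to the red run
  objs <- extract_components(code_raster(m))
  expect_equal(sort(objs$class), c("gray", "red"))
  expect_equal(objs$pixel_count[objs$class == "red"], 2L)
  expect_equal(objs$pixel_count[objs$class == "gray"], 1L)
})

test_that("geographic CRS is rejected for area-based extraction", {
  ras <- tch_raster(matrix(0L, 3, 3), px = 1, crs = "EPSG:4326")
  expect_error(extract_components(ras), "geographic")
})

test_that("objects serialize to GeoJSON polygons and points", {
  tf_poly <- withr::local_tempfile(fileext = ".geojson")
  tf_pts <- withr::local_tempfile(fileext = ".geojson")
  m <- grid_from_cells(6, 6, as.matrix(expand.grid(2:4, 2:4)))
  objs <- extract_components(code_raster(m), classes = "red")
  write_objects_geojson(objs, tf_poly, "polygons")
  write_objects_geojson(objs, tf_pts, "points")
  poly <- jsonlite::read_json(tf_poly)
  expect_equal(poly$type, "FeatureCollection")
  expect_equal(length(poly$features), 1L)
  expect_equal(poly$features[[1]]$geometry$type, "Polygon")
  expect_equal(poly$features[[1]]$properties$area_m2, 9)
  pts <- jsonlite::read_json(tf_pts)
  expect_equal(pts$features[[1]]$geometry$type, "Point")
})
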