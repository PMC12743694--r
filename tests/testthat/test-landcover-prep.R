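test_that("reclassification groups raw classes per the default table", {
  tab <- reclass_table()
  raw_codes <- function(nm) tab$raw[match(nm, tab$name)]
  raw <- grid_raster(matrix(raw_codes(c("other wooded land", "riverbed",
                                        "cropland", "glacier")), 2, 2),
                     cell_size = 60)
  out <- reclassify(raw)
  expect_equal(as.vector(out$values),
               unname(lc_classes()[c("forest", "waterbodies",
                                     "cropland", "unsuitable")]))
})

test_that("reclassify errors name the unmapped raw code", {
  raw <- grid_raster(matrix(c(1L, 99L), 1, 2))
  expect_error(reclassify(raw), "99")
})

test_that("identity mapping leaves an already-reclassified raster unchanged", {
  lc <- lc_raster(matrix(c(1L, 2L, 3L, 4L, 5L, 1L), 2, 3))
  idmap <- data.frame(raw = unname(lc_classes()), class = names(lc_classes()))
  expect_identical(reclassify(lc, idmap)$values, lc$values)
})

test_that("nearest-neighbour resampling: constant field, identity, tie rule", {
  uni <- lc_raster(matrix(lc_classes()[["forest"]], 4, 4), cell_size = 30)
  out <- resample_nearest(uni, 60)
  expect_true(all(out$values == lc_classes()[["forest"]]))
  expect_equal(dim(out$values), c(2L, 2L))
  expect_identical(resample_nearest(uni, 30), uni)
  # 2x2 checkerboard at factor 2: output centre equidistant from all four
  # source centres; the tie resolves to the smaller row then column index,
  # i.e. the top-left cell
  chk <- lc_raster(matrix(lc_classes()[c("forest", "cropland",
                                         "cropland", "forest")], 2, 2),
                   cell_size = 30)
  one <- resample_nearest(chk, 60)
  expect_equal(dim(one$values), c(1L, 1L))
  expect_equal(as.vector(one$values), unname(lc_classes()[["forest"]]))
  expect_error(resample_nearest(uni, -1), "> 0")
  expect_error(resample_nearest(uni, 10), ">=")
})

test_that("elevation mask is strict: above 3600 unsuitable, at 3600 untouched", {
  lc <- lc_raster(matrix(lc_classes()[["forest"]], 1, 3))
  dem <- grid_raster(matrix(c(3500, 3600, 3700), 1, 3))
  out <- apply_elevation_mask(lc, dem)
  expect_equal(as.vector(out$values),
               unname(lc_classes()[c("forest", "forest", "unsuitable")]))
  # all-lowland raster is a no-op
  low <- grid_raster(matrix(1000, 1, 3))
  expect_identical(apply_elevation_mask(lc, low)$values, lc$values)
  # never un-masks
  masked <- apply_elevation_mask(lc, dem)
  expect_identical(apply_elevation_mask(masked, dem)$values, masked$values)
  bad <- grid_raster(matrix(0, 2, 2))
  expect_error(apply_elevation_mask(lc, bad), "geometry")
})

test_that("footprint burning is by cell centre, exact and idempotent", {
  lc <- lc_raster(matrix(lc_classes()[["forest"]], 4, 4), cell_size = 10)
  fp <- rect_polygon(0, 0, 12, 12)  # contains exactly the centre (5, 5)
  out <- burn_footprint(lc, fp)
  cc <- cell_centers(lc)
  g <- expand.grid(x = cc$x, y = cc$y)
  expected_n <- sum(pts_in_polygon(g$x, g$y, fp))
  expect_equal(sum(out$values == lc_classes()[["unsuitable"]]), expected_n)
  expect_equal(sum(lc$values == lc_classes()[["forest"]]) -
                 sum(out$values == lc_classes()[["forest"]]), expected_n)
  # idempotent
  expect_identical(burn_footprint(out, fp)$values, out$values)
  # disjoint footprint is a no-op
  far <- rect_polygon(1000, 1000, 1100, 1100)
  expect_identical(burn_footprint(lc, far)$values, lc$values)
  expect_error(burn_footprint(lc, matrix(0, 2, 2)), "vertex")
})

test_that("deforestation detection follows the conversion rules", {
  cls <- lc_classes()
  t1 <- lc_raster(matrix(c(cls[["forest"]], cls[["forest"]], cls[["forest"]],
                           cls[["forest"]], cls[["cropland"]], cls[["forest"]]),
                         2, 3))
  t2 <- lc_raster(matrix(c(cls[["cropland"]], cls[["unsuitable"]], cls[["forest"]],
                           cls[["grassland"]], cls[["cropland"]], cls[["waterbodies"]]),
                         2, 3))
  ch <- detect_deforestation(t1, t2)
  chg <- change_classes()
  expect_equal(as.vector(ch$values),
               unname(chg[c("deforested", "deforested", "stable_forest",
                            "other", "other", "other")]))
})

test_that("self-comparison yields stable forest exactly on the forest mask", {
  L <- generate_landscape(landscape_config(width = 30, height = 30, seed = 6))
  x <- L$landcover_2019
  ch <- detect_deforestation(x, x)
  expect_equal(sum(ch$values == change_classes()[["deforested"]]), 0)
  expect_identical(ch$values == change_classes()[["stable_forest"]],
                   x$values == lc_classes()[["forest"]])
})

test_that("ascii grid round trip preserves values and georeferencing", {
  L <- generate_landscape(landscape_config(width = 16, height = 12, seed = 2))
  f <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(L$landcover_2019, f)
  back <- read_ascii_grid(f, integer = TRUE)
  expect_identical(back$values, L$landcover_2019$values)
  expect_true(same_geometry(back, L$landcover_2019))
})
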