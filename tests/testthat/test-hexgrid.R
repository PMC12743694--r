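test_that("10-ha hexagons have the right edge length and exact area", {
  hx <- build_hexgrid(rect_polygon(0, 0, 2000, 2000))
  s_expect <- sqrt(2 * 1e5 / (3 * sqrt(3)))
  expect_equal(hx$s, s_expect, tolerance = 1e-12)
  expect_equal(hx$s, 196.19, tolerance = 1e-3)
  areas <- vapply(hx$vertices, polygon_area, 0)
  expect_true(all(abs(areas - 1e5) / 1e5 < 1e-6))
  expect_error(build_hexgrid(rect_polygon(0, 0, 100, 100), cell_area = -1), "> 0")
})

test_that("tessellation covers the extent with disjoint interiors", {
  ext <- rect_polygon(0, 0, 1500, 1200)
  hx <- build_hexgrid(ext)
  # sampled points of the extent each fall in exactly one hexagon
  withr::local_seed(2)
  px <- runif(200, 1, 1499); py <- runif(200, 1, 1199)
  hits <- sapply(hx$vertices, function(vv) pts_in_polygon(px, py, vv))
  expect_true(all(rowSums(hits) == 1))
})

test_that("hexagon classification follows the 100 % / 10 % rules", {
  chg <- change_classes()
  # 40 x 40 @ 60 m change raster: west half stable forest, east half deforested
  v <- matrix(chg[["stable_forest"]], 40, 40)
  v[, 21:40] <- chg[["deforested"]]
  ch <- grid_raster(v, cell_size = 60)
  class(ch) <- c("change_raster", class(ch))
  hx <- build_hexgrid(raster_extent(ch, as_polygon = TRUE))
  st <- classify_hexes(hx, ch)
  # statuses must agree with the rule applied to the reported fractions
  with_px <- st[st$n_pixels > 0, ]
  expect_true(all(with_px$status[with_px$forest_fraction >= 0.999] == "forested"))
  mid <- with_px$forest_fraction < 0.999 & with_px$deforested_fraction >= 0.10
  expect_true(all(with_px$status[mid] == "deforested"))
  rest <- with_px$forest_fraction < 0.999 & with_px$deforested_fraction < 0.10
  expect_true(all(with_px$status[rest] == "other"))
  expect_true(any(st$status == "forested"))
  expect_true(any(st$status == "deforested"))
  # hexagons well inside each half are pure
  pure_f <- st$n_pixels > 20 & hx$cells$cx < 900
  expect_true(all(st$status[pure_f] == "forested"))
})

test_that("a mixed hexagon below both rules is 'other'", {
  chg <- change_classes()
  v <- matrix(chg[["stable_forest"]], 30, 30)
  v[1:30, 1:2] <- chg[["other"]]        # 6-7 % other
  v[1, 3] <- chg[["deforested"]]        # ~0.1 % deforested
  ch <- grid_raster(v, cell_size = 60)
  hx <- build_hexgrid(raster_extent(ch, as_polygon = TRUE))
  st <- classify_hexes(hx, ch)
  west <- st$n_pixels > 10 & hx$cells$cx < 200
  expect_true(all(st$status[west] %in% c("other", "forested")))
  expect_true(any(st$status[west] == "other"))
})

test_that("patch merging equals flood fill on the adjacency list", {
  withr::local_seed(14)
  ext <- rect_polygon(0, 0, 4000, 4000)
  hx <- build_hexgrid(ext)
  n <- nrow(hx$cells)
  status <- ifelse(runif(n) < 0.5, "forested", "other")
  st <- data.frame(id = hx$cells$id, status = status,
                   forest_fraction = 1, deforested_fraction = 0, n_pixels = 1)
  patches <- merge_forest_patches(hx, st)
  fids <- st$id[st$status == "forested"]
  cc <- hx$cells[match(fids, hx$cells$id), ]
  w <- sqrt(3) * hx$s
  d <- as.matrix(stats::dist(cbind(cc$cx, cc$cy)))
  adj_list <- lapply(seq_along(fids), function(i)
    which(d[i, ] > 0 & d[i, ] <= 1.01 * w))
  comp <- flood_fill_components(adj_list)
  expect_equal(length(patches), max(comp))
  # membership agrees up to labelling
  got <- integer(length(fids))
  for (p in patches) got[match(p$hex_ids, fids)] <- p$id
  expect_equal(length(unique(paste(got, comp))), max(comp))
  # two edge-sharing forested hexes merge into one 20-ha patch, and two
  # separated ones stay apart
  d_all <- as.matrix(stats::dist(cbind(hx$cells$cx, hx$cells$cy)))
  nb <- which(d_all[1, ] > 0 & d_all[1, ] <= 1.01 * w)[1]
  st2 <- st; st2$status <- "other"
  st2$status[c(1, nb)] <- "forested"
  p2 <- merge_forest_patches(hx, st2)
  expect_equal(length(p2), 1)
  expect_equal(p2[[1]]$area, 2e5)
  far_hex <- which(d_all[1, ] > 3 * w)[1]
  st3 <- st; st3$status <- "other"
  st3$status[c(1, far_hex)] <- "forested"
  expect_equal(length(merge_forest_patches(hx, st3)), 2)
})

test_that("interpatch distances match closed forms and the densified oracle", {
  sq1 <- rect_polygon(0, 0, 1, 1)
  sq2 <- rect_polygon(6, 0, 7, 1)
  expect_equal(interpatch_distance(sq1, sq2), 5)
  hx <- build_hexgrid(rect_polygon(0, 0, 1500, 1500))
  # adjacent hexagons touch: distance 0
  w <- sqrt(3) * hx$s
  cc <- hx$cells
  d_cent <- as.matrix(stats::dist(cbind(cc$cx, cc$cy)))
  pair <- which(d_cent > 0 & d_cent <= 1.01 * w, arr.ind = TRUE)[1, ]
  expect_lt(interpatch_distance(hx$vertices[[pair[1]]],
                                hx$vertices[[pair[2]]]), 1e-6)
  # random non-touching pairs agree with boundary densification
  withr::local_seed(3)
  far <- which(d_cent > 3 * w, arr.ind = TRUE)
  for (k in sample(nrow(far), 5)) {
    i <- far[k, 1]; j <- far[k, 2]
    expect_equal(interpatch_distance(hx$vertices[[i]], hx$vertices[[j]]),
                 densified_boundary_distance(hx$vertices[[i]], hx$vertices[[j]]),
                 tolerance = 0.1)
  }
})

test_that("riparian flags equal the brute-force all-pairs intersection test", {
  hx <- build_hexgrid(rect_polygon(0, 0, 3000, 3000))
  river <- cbind(x = seq(0, 3000, by = 50),
                 y = 1500 + 400 * sin(seq(0, 3 * pi, length.out = 61)))
  flags <- riparian_subset(hx, list(river))
  # independent oracle: densify the river to sub-metre spacing; a hexagon
  # containing a sampled point must be flagged, and every flagged hexagon
  # must come within a couple of metres of a sampled point
  dense <- do.call(rbind, lapply(seq_len(nrow(river) - 1), function(i) {
    t <- seq(0, 1, length.out = 80)
    cbind(river[i, 1] + t * (river[i + 1, 1] - river[i, 1]),
          river[i, 2] + t * (river[i + 1, 2] - river[i, 2]))
  }))
  for (k in seq_len(nrow(hx$cells))) {
    vv <- hx$vertices[[k]]
    inside <- any(pts_in_polygon(dense[, 1], dense[, 2], vv))
    if (inside) expect_true(unname(flags[k]))
    if (flags[k]) {
      near <- min(dist_point_polygon_boundary(dense[, 1], dense[, 2], vv))
      expect_true(inside || near < 2)
    }
  }
  expect_true(any(flags))
  expect_false(all(flags))
  # a hexagon a kilometre from the river is not riparian
  far <- which(abs(hx$cells$cy - 1500) > 1950)
  if (length(far)) expect_false(any(flags[far]))
})
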