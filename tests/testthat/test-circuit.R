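test_that("lattice conductances follow the average-resistance scheme", {
  r <- grid_raster(matrix(c(1, 3), 1, 2))
  class(r) <- c("resistance_surface", class(r))
  net <- build_network(r)
  expect_equal(net$edges$conductance, 0.5)   # 1 / ((1 + 3) / 2)
  r2 <- grid_raster(diag(c(1, 1)) + matrix(c(0, 99, 99, 0), 2, 2))
  class(r2) <- c("resistance_surface", class(r2))
  net2 <- build_network(r2)
  # diagonal pair of r = 1 cells: orthogonal value (1) divided by sqrt(2)
  diag_edge <- net2$edges[net2$edges$i == 1 & net2$edges$j == 4, ]
  expect_equal(diag_edge$conductance, 1 / sqrt(2))
  # diagonal pair of r = 99 cells scales the same way
  diag_hi <- net2$edges[net2$edges$i == 3 & net2$edges$j == 2, ]
  expect_equal(diag_hi$conductance, (1 / 99) / sqrt(2))
  expect_error(build_network(grid_raster(matrix(NA_real_, 2, 2))), "no in-extent")
})

test_that("uniform chain: series resistance and unit branch currents", {
  lc <- lc_raster(matrix(1L, 1, 3))
  net <- build_network(build_resistance_surface(lc, uniform_profile(1)))
  sol <- solve_pair(net, 1, 3)
  expect_equal(sol$effective_resistance, 2, tolerance = 1e-12)
  expect_equal(sol$currents$current, c(1, 1), tolerance = 1e-12)
  expect_equal(sol$voltages[3], 0)
  # two-cell graph: effective resistance = 1 / conductance
  lc2 <- lc_raster(matrix(c(1L, 5L), 1, 2))
  prof <- list(forest = 1, grassland = 1, cropland = 1, waterbodies = 1,
               unsuitable = 99)
  net2 <- build_network(build_resistance_surface(lc2, prof))
  g <- net2$edges$conductance
  expect_equal(solve_pair(net2, 1, 2)$effective_resistance, 1 / g)
})

test_that("swapping source and ground flips signs but not magnitudes", {
  withr::local_seed(42)
  net <- random_conductance_graph(40)
  sg <- sample(net$n, 2)
  a <- solve_pair(net, sg[1], sg[2])
  b <- solve_pair(net, sg[2], sg[1])
  expect_equal(abs(a$currents$current), abs(b$currents$current),
               tolerance = 1e-10)
  expect_equal(a$effective_resistance, b$effective_resistance,
               tolerance = 1e-10)
})

test_that("sparse solves agree with the dense pseudoinverse oracle", {
  withr::local_seed(7)
  for (rep in 1:25) {
    net <- random_conductance_graph(60)
    sg <- sample(net$n, 2)
    sol <- solve_pair(net, sg[1], sg[2])
    oracle <- dense_solve_pair(net, sg[1], sg[2])
    expect_lt(max(abs(sol$voltages - oracle)), 1e-8)
    expect_lt(kirchhoff_residual(net, sol$voltages, sg[1], sg[2]), 1e-8)
  }
})

test_that("pair solves across components fail; mixed focal sets skip pairs", {
  lc <- lc_raster(matrix(c(1L, 1L, NA, NA, 1L, 1L), 2, 3))  # NA column splits
  net <- build_network(build_resistance_surface(lc, uniform_profile(1)))
  comp <- net$component
  split_pair <- c(which(comp == 1)[1], which(comp == 2)[1])
  expect_error(solve_pair(net, split_pair[1], split_pair[2]), "different components")
  focal <- net$nodes[c(which(comp == 1)[1:2], which(comp == 2)[1]), ]
  expect_warning(cm <- cumulative_current(net, focal), "skipped")
  expect_equal(cm$n_pairs, 1L)
  expect_equal(cm$n_skipped, 2L)
})

test_that("cumulative current: chain end-to-end and single-pair equivalence", {
  lc <- lc_raster(matrix(1L, 1, 3))
  net <- build_network(build_resistance_surface(lc, uniform_profile(1)))
  cm <- cumulative_current(net, data.frame(row = c(1, 1), col = c(1, 3)))
  expect_equal(as.vector(cm$values), c(1, 1, 1), tolerance = 1e-12)
  expect_equal(cm$n_pairs, 1L)
  # n = 2 focal nodes equals the single solve_pair cell-current map
  L <- generate_landscape(landscape_config(width = 15, height = 15, seed = 3))
  net2 <- build_network(build_resistance_surface(L$landcover_2019,
                                                 enumerate_profiles()[1, ]))
  sol <- solve_pair(net2, 1, net2$n)
  half <- abs(sol$currents$current)
  manual <- numeric(net2$n)
  for (k in seq_len(nrow(net2$edges))) {
    manual[net2$edges$i[k]] <- manual[net2$edges$i[k]] + half[k]
    manual[net2$edges$j[k]] <- manual[net2$edges$j[k]] + half[k]
  }
  manual <- manual / 2
  manual[c(1, net2$n)] <- 1
  cm2 <- cumulative_current(net2, net2$nodes[c(1, net2$n), ])
  got <- cm2$values[cbind(net2$nodes$row, net2$nodes$col)]
  expect_equal(got, manual, tolerance = 1e-10)
})

test_that("current maps are invariant under uniform resistance scaling", {
  L <- generate_landscape(landscape_config(width = 20, height = 20, seed = 8))
  p <- enumerate_profiles()[14, ]
  s1 <- build_resistance_surface(L$landcover_2019, p)
  p10 <- p; p10[, names(lc_classes())] <- p[, names(lc_classes())] * 10
  # scaling pushes values past 100, so build the surface directly
  s10 <- s1; s10$values <- s1$values * 10
  focal <- data.frame(row = c(1, 20, 1, 20), col = c(1, 1, 20, 20))
  m1 <- cumulative_current(build_network(s1), focal)
  m10 <- cumulative_current(build_network(s10), focal)
  expect_equal(m1$values, m10$values, tolerance = 1e-10)
})

test_that("focal sampling stays in the ring, is seeded and exhaustive", {
  L <- generate_landscape(landscape_config(width = 30, height = 30, seed = 5))
  lc <- L$landcover_2019
  extent <- inset_extent(lc, 300)
  s <- build_resistance_surface(lc, enumerate_profiles()[1, ])
  f1 <- sample_focal_nodes(extent, 300, 10, s, seed = 21)
  f2 <- sample_focal_nodes(extent, 300, 10, s, seed = 21)
  expect_identical(f1$points, f2$points)
  expect_equal(nrow(unique(f1$points[, c("row", "col")])), 10)
  expect_false(any(pts_in_polygon(f1$points$x, f1$points$y, extent)))
  d <- dist_point_polygon_boundary(f1$points$x, f1$points$y, extent)
  expect_true(all(d <= 300))
  # a ring with exactly n candidates is selected in full
  tiny <- lc_raster(matrix(1L, 3, 3), cell_size = 10)
  ext2 <- rect_polygon(10, 10, 20, 20)  # ring = the 8 border cells
  s2 <- build_resistance_surface(tiny, uniform_profile(1))
  f3 <- sample_focal_nodes(ext2, 20, 8, s2, seed = 1)
  expect_equal(nrow(f3$points), 8)
  expect_error(sample_focal_nodes(ext2, 20, 9, s2, seed = 1), "candidate")
})

test_that("current concentrates in the pinch corridor", {
  px <- pinch_fixture()
  s <- build_resistance_surface(px$before, enumerate_profiles()[1, ])
  net <- build_network(s)
  nr <- nrow(px$before$values); nc <- ncol(px$before$values)
  focal <- data.frame(row = c(floor(nr / 2), floor(nr / 2)),
                      col = c(5, nc - 4))
  cm <- cumulative_current(net, focal)
  corridor <- cm$values[cbind(px$corridor_cells[, "row"],
                              px$corridor_cells[, "col"])]
  mask <- matrix(FALSE, nr, nc)
  mask[cbind(px$corridor_cells[, "row"], px$corridor_cells[, "col"])] <- TRUE
  mask[cbind(focal$row, focal$col)] <- TRUE
  forest_other <- px$before$values == lc_classes()[["forest"]] & !mask
  # exclude the immediate neighbourhood of focal cells (artificially high)
  near_focal <- abs(row(mask) - focal$row[1]) <= 2 & abs(col(mask) - focal$col[1]) <= 2 |
    abs(row(mask) - focal$row[2]) <= 2 & abs(col(mask) - focal$col[2]) <= 2
  expect_gt(max(corridor), max(cm$values[forest_other & !near_focal]))
})
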