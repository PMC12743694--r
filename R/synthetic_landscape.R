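# Seeded synthetic landscapes with the structure the analysis assumes: a
# five-class land cover for two dates, an elevation gradient crossing the
# 3600 m tree line, a meandering river rasterised to waterbodies, and a
# reservoir-like project footprint straddling the river. Forest pattern comes
# from thresholded smoothed Gaussian noise so that patch graininess is a
# single tunable length scale.

#' Configuration for the synthetic landscape generator
#'
#' Defaults emulate the Himalayan study setting the method was designed for:
#' 60 m cells, ~60 % forest, croplands dominating the non-forest matrix, an
#' elevation span crossing the 3600 m tree line, a small reservoir footprint
#' (~0.6 % of the extent) and ~4 % of the date-1 forest deforested by date 2.
#'
#' @param width,height Grid size in cells (>= 8).
#' @param cell_size Cell side in metres.
#' @param forest_fraction Proportion of the extent forested at date 1.
#' @param fragmentation Smoothing length (cells) of the noise field; larger
#'   values give larger, smoother forest patches.
#' @param river_width River width in cells.
#' @param footprint_fraction Project footprint area as a proportion of the
#'   extent.
#' @param deforestation_fraction Proportion of date-1 forest converted to
#'   cropland or unsuitable by date 2.
#' @param elevation_range Length-2 numeric, min/max elevation in metres.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A validated `landscape_config` list.
#' @export
landscape_config <- function(width = 120, height = 120, cell_size = 60,
                             forest_fraction = 0.6, fragmentation = 6,
                             river_width = 2, footprint_fraction = 0.006,
                             deforestation_fraction = 0.04,
                             elevation_range = c(234, 3859), seed = 1) {
  cfg <- list(width = as.integer(width), height = as.integer(height),
              cell_size = cell_size, forest_fraction = forest_fraction,
              fragmentation = fragmentation, river_width = as.integer(river_width),
              footprint_fraction = footprint_fraction,
              deforestation_fraction = deforestation_fraction,
              elevation_range = as.numeric(elevation_range),
              seed = as.integer(seed))
  frs <- c(forest_fraction, footprint_fraction, deforestation_fraction)
  if (any(!is.finite(frs)) || any(frs < 0) || any(frs > 1))
    stop("all fractions must lie in [0, 1]")
  if (cfg$width < 8 || cfg$height < 8) stop("width and height must be >= 8")
  if (!is.finite(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  if (cfg$fragmentation <= 0) stop("fragmentation must be > 0")
  if (cfg$river_width < 1) stop("river_width must be >= 1")
  if (length(cfg$elevation_range) != 2 ||
      diff(cfg$elevation_range) < 0) stop("elevation_range must be (min, max)")
  class(cfg) <- "landscape_config"
  cfg
}

# Separable Gaussian blur with edge clamping; sigma in cells.
smooth_noise <- function(nr, nc, sigma) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m) {  # blur along rows of m (i.e. over columns)
    n <- ncol(m)
    out <- matrix(0, nrow(m), n)
    for (o in -half:half) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      out <- out + k[o + half + 1] * m[, idx, drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(z))))
}

# River centre column per row: gentle meander from north to south.
river_path_cols <- function(nr, nc) {
  amp <- nc / 8
  nc / 2 + amp * sin(seq(0, 3 * pi, length.out = nr)) + 0.5
}

#' Generate a seeded synthetic landscape
#'
#' Produces two-date land cover, elevation, a project footprint polygon and
#' river polylines on one shared grid. Every date-2 deforested cell was forest
#' at date 1 and becomes cropland or unsuitable; nothing else changes between
#' dates. The footprint overlaps at least one forest and one river cell.
#'
#' @param config A [landscape_config()].
#' @return List with `landcover_2000`, `landcover_2019` (`lc_raster`),
#'   `elevation` (`grid_raster`), `footprint` (vertex matrix), `rivers`
#'   (list of polyline matrices) and the `config`.
#' @export
generate_landscape <- function(config) {
  if (!inherits(config, "landscape_config")) config <- do.call(landscape_config, config)
  nr <- config$height; nc <- config$width; cs <- config$cell_size
  cls <- lc_classes()
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  # forest pattern: thresholded smoothed noise
  zf <- smooth_noise(nr, nc, config$fragmentation)
  lc <- matrix(cls[["cropland"]], nr, nc)
  if (config$forest_fraction > 0) {
    thr <- stats::quantile(zf, 1 - config$forest_fraction, names = FALSE)
    lc[zf >= thr] <- cls[["forest"]]
  }
  # split the non-forest matrix: mostly cropland, some grassland, a little
  # built-up/bare (unsuitable), mirroring a mid-hill agricultural mosaic
  z2 <- smooth_noise(nr, nc, max(2, config$fragmentation / 2))
  nonf <- lc != cls[["forest"]]
  if (any(nonf)) {
    q <- stats::quantile(z2[nonf], c(0.15, 0.97), names = FALSE)
    lc[nonf & z2 <= q[1]] <- cls[["grassland"]]
    lc[nonf & z2 > q[2]] <- cls[["unsuitable"]]
  }

  # river: north-south meander rasterised to waterbodies
  rcols <- river_path_cols(nr, nc)
  halfw <- (config$river_width - 1) / 2
  for (r in seq_len(nr)) {
    c0 <- max(1L, floor(rcols[r] - halfw))
    c1 <- min(nc, ceiling(rcols[r] + halfw))
    lc[r, c0:c1] <- cls[["waterbodies"]]
  }
  xs <- (seq_len(nc) - 0.5) * cs
  ys <- (nr - seq_len(nr) + 0.5) * cs
  river_line <- cbind(x = (rcols - 0.5) * cs, y = ys)

  # elevation: rises to the north, plus smooth relief
  grad <- (nr - seq_len(nr) + 0.5) / nr
  relief <- smooth_noise(nr, nc, config$fragmentation)
  relief <- relief / max(1e-12, stats::sd(relief))
  emin <- config$elevation_range[1]; emax <- config$elevation_range[2]
  efield <- matrix(grad, nr, nc) + 0.04 * relief
  efield[efield < 0] <- 0
  efield[efield > 1] <- 1
  elev <- emin + (emax - emin) * efield

  # footprint: reservoir-shaped rectangle centred on the river, elongated
  # along it; slide along the river until it overlaps forest
  area_fp <- config$footprint_fraction * (nr * nc * cs^2)
  w_fp <- sqrt(area_fp / 3)          # metres; height = 3 * width
  h_fp <- 3 * w_fp
  footprint <- NULL
  rows_try <- unique(round(nr / 2 + c(0, -1, 1, -2, 2, -3, 3) * nr / 8))
  rows_try <- rows_try[rows_try >= 1 & rows_try <= nr]
  mk_fp <- function(r0) {
    cx <- (rcols[r0] - 0.5) * cs
    cy <- (nr - r0 + 0.5) * cs
    rect_polygon(max(0, cx - w_fp / 2), max(0, cy - h_fp / 2),
                 min(nc * cs, cx + w_fp / 2), min(nr * cs, cy + h_fp / 2))
  }
  cellgrid <- expand.grid(x = xs, y = ys)
  for (r0 in rows_try) {
    fp <- mk_fp(r0)
    inside <- pts_in_polygon(cellgrid$x, cellgrid$y, fp)
    covered <- t(lc)[inside]  # cellgrid varies x fastest => column-major of t(lc)
    if (any(covered == cls[["forest"]]) && any(covered == cls[["waterbodies"]])) {
      footprint <- fp
      break
    }
  }
  if (is.null(footprint)) {
    # degenerate covers (e.g. forest_fraction 0 or 1): take the central
    # placement and force one covered cell to forest at both dates
    footprint <- mk_fp(rows_try[1])
    inside <- which(pts_in_polygon(cellgrid$x, cellgrid$y, footprint))
    inside <- inside[t(lc)[inside] != cls[["waterbodies"]]]
    if (length(inside)) {
      i0 <- inside[1]
      r <- ((i0 - 1) %/% nc) + 1; c <- ((i0 - 1) %% nc) + 1
      lc[r, c] <- cls[["forest"]]
    }
  }

  # date-2 cover: clustered deforestation of date-1 forest
  lc2 <- lc
  fcells <- which(lc == cls[["forest"]])
  k <- round(config$deforestation_fraction * length(fcells))
  if (k > 0) {
    z3 <- smooth_noise(nr, nc, max(2, config$fragmentation / 2))
    sel <- fcells[order(z3[fcells], decreasing = TRUE)[seq_len(k)]]
    dest <- ifelse(stats::runif(k) < 0.8, cls[["cropland"]], cls[["unsuitable"]])
    lc2[sel] <- dest
  }

  list(landcover_2000 = lc_raster(lc, cs),
       landcover_2019 = lc_raster(lc2, cs),
       elevation = grid_raster(elev, cs),
       footprint = footprint,
       rivers = list(river_line),
       config = config)
}

#' Pinch-corridor test scenario
#'
#' A small deterministic landscape with two large forest blocks joined by a
#' single three-cell-wide forest corridor through an otherwise unsuitable
#' band, and an after-scenario in which the corridor is burned to unsuitable
#' by the project footprint. The fixture exposes the corridor cell indices so
#' tests can interrogate exactly the burned set.
#'
#' @param nrow,ncol Grid size (<= 100 each).
#' @param cell_size Cell side in metres.
#' @return List with `before`/`after` land cover (`lc_raster`), the
#'   `footprint` polygon covering exactly the corridor, `corridor_cells`
#'   (two-column row/col matrix), `corridor_cols`, `corridor_rows`, and
#'   `rivers` (empty list).
#' @export
pinch_fixture <- function(nrow = 60, ncol = 90, cell_size = 60) {
  stopifnot(nrow <= 100, ncol <= 100, nrow >= 12, ncol >= 12)
  cls <- lc_classes()
  block_w <- floor(ncol * 0.28)
  gap0 <- block_w + 1L
  gap1 <- ncol - block_w
  mid <- floor(nrow / 2)
  corridor_rows <- (mid - 1L):(mid + 1L)
  v <- matrix(cls[["unsuitable"]], nrow, ncol)
  v[, 1:block_w] <- cls[["forest"]]
  v[, (ncol - block_w + 1L):ncol] <- cls[["forest"]]
  v[corridor_rows, gap0:gap1] <- cls[["forest"]]
  before <- lc_raster(v, cell_size)
  va <- v
  va[corridor_rows, gap0:gap1] <- cls[["unsuitable"]]
  after <- lc_raster(va, cell_size)
  corridor_cells <- as.matrix(expand.grid(row = corridor_rows, col = gap0:gap1))
  # footprint rectangle spanning exactly the corridor cells
  xmin <- (gap0 - 1) * cell_size; xmax <- gap1 * cell_size
  ymax_r <- (nrow - min(corridor_rows) + 1) * cell_size
  ymin_r <- (nrow - max(corridor_rows)) * cell_size
  footprint <- rect_polygon(xmin, ymin_r, xmax, ymax_r)
  list(before = before, after = after, footprint = footprint,
       corridor_cells = corridor_cells, corridor_rows = corridor_rows,
       corridor_cols = gap0:gap1, rivers = list())
}
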