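# 10-ha hexagonal tessellation and its overlay with the change and current
# rasters. Hexagons are pointy-top, anchored at the extent's lower-left; the
# edge length follows from the cell area, s = sqrt(2 A / (3 sqrt(3))).

hex_vertices <- function(cx, cy, s) {
  ang <- pi / 180 * (90 + 60 * (0:5))
  cbind(x = cx + s * cos(ang), y = cy + s * sin(ang))
}

#' Build a hexagonal tessellation over an extent
#'
#' Regular pointy-top hexagons of the given area; cells intersecting the
#' extent are retained. Horizontal spacing is `sqrt(3) * s`, vertical
#' spacing `1.5 * s`, with odd rows offset half a cell.
#'
#' @param extent Rectangle polygon (two-column matrix) or bounds
#'   `c(xmin, ymin, xmax, ymax)`.
#' @param cell_area Hexagon area in square metres (default 1e5 = 10 ha).
#' @return A `hex_grid`: data frame `cells` (id, grow, gcol, cx, cy),
#'   `vertices` list of 6x2 matrices, the edge length `s` and `cell_area`.
#' @export
build_hexgrid <- function(extent, cell_area = 1e5) {
  if (!is.numeric(cell_area) || cell_area <= 0) stop("cell_area must be > 0")
  if (is.matrix(extent)) {
    bb <- c(min(extent[, 1]), min(extent[, 2]), max(extent[, 1]), max(extent[, 2]))
    poly <- extent
  } else {
    bb <- unname(extent)
    poly <- rect_polygon(bb[1], bb[2], bb[3], bb[4])
  }
  s <- sqrt(2 * cell_area / (3 * sqrt(3)))
  w <- sqrt(3) * s     # horizontal centre spacing
  hstep <- 1.5 * s     # vertical centre spacing
  nrows <- ceiling((bb[4] - bb[2]) / hstep) + 2L
  ncols <- ceiling((bb[3] - bb[1]) / w) + 2L
  cells <- list(); verts <- list(); id <- 0L
  for (gr in -1L:(nrows - 1L)) {
    cy <- bb[2] + s + gr * hstep
    xoff <- if (abs(gr) %% 2 == 1) w / 2 else 0
    for (gc in -1L:(ncols - 1L)) {
      cx <- bb[1] + w / 2 + xoff + gc * w
      vv <- hex_vertices(cx, cy, s)
      if (!polygons_intersect(vv, poly)) next
      id <- id + 1L
      cells[[id]] <- c(grow = gr, gcol = gc, cx = cx, cy = cy)
      verts[[id]] <- vv
    }
  }
  if (id == 0) stop("extent is empty")
  df <- as.data.frame(do.call(rbind, cells))
  df <- cbind(id = seq_len(id), df)
  structure(list(cells = df, vertices = verts, s = s, cell_area = cell_area,
                 extent = poly),
            class = "hex_grid")
}

# Linear (column-major) raster cell indices whose centres fall inside a hexagon
hex_pixel_index <- function(vv, r) {
  cc <- cell_centers(r)
  cs <- r$cell_size
  cols <- which(cc$x >= min(vv[, 1]) - cs & cc$x <= max(vv[, 1]) + cs)
  rows <- which(cc$y >= min(vv[, 2]) - cs & cc$y <= max(vv[, 2]) + cs)
  if (!length(cols) || !length(rows)) return(integer(0))
  g <- expand.grid(row = rows, col = cols)
  inside <- pts_in_polygon(cc$x[g$col], cc$y[g$row], vv)
  g <- g[inside, , drop = FALSE]
  (g$col - 1L) * nrow(r$values) + g$row
}

#' Classify hexagons as forested / deforested / other
#'
#' A hexagon is `forested` when (up to a small rasterisation tolerance) all
#' of its pixels are stable forest; otherwise it is `deforested` when at
#' least `min_deforested` of its pixels are deforested; otherwise `other`.
#' Fractions are computed over the in-extent pixels whose centre falls in
#' the hexagon.
#'
#' @param hexes A `hex_grid`.
#' @param change A `change_raster` from [detect_deforestation()].
#' @param min_forest Forested-fraction rule (default 0.999, i.e. "100 %"
#'   with tolerance for edge pixels).
#' @param min_deforested Deforested-fraction rule (default 0.10).
#' @return Data frame: id, status, forest_fraction, deforested_fraction,
#'   n_pixels.
#' @export
classify_hexes <- function(hexes, change, min_forest = 0.999,
                           min_deforested = 0.10) {
  chg <- change_classes()
  n <- nrow(hexes$cells)
  ff <- df <- numeric(n); np <- integer(n)
  status <- rep("other", n)
  for (k in seq_len(n)) {
    px <- hex_pixel_index(hexes$vertices[[k]], change)
    vals <- change$values[px]
    vals <- vals[!is.na(vals)]
    np[k] <- length(vals)
    if (!length(vals)) next
    ff[k] <- mean(vals == chg[["stable_forest"]])
    df[k] <- mean(vals == chg[["deforested"]])
    status[k] <- if (ff[k] >= min_forest) "forested"
                 else if (df[k] >= min_deforested) "deforested"
                 else "other"
  }
  data.frame(id = hexes$cells$id, status = status, forest_fraction = ff,
             deforested_fraction = df, n_pixels = np,
             stringsAsFactors = FALSE)
}

#' Mean current density of each hexagon
#'
#' @param hexes A `hex_grid`.
#' @param current A current or consensus map.
#' @param ids Hexagon ids to evaluate (default all).
#' @return Named numeric vector of per-hexagon mean current (NA where no
#'   valid pixel falls inside).
#' @export
hex_mean_current <- function(hexes, current, ids = hexes$cells$id) {
  out <- vapply(ids, function(k) {
    px <- hex_pixel_index(hexes$vertices[[k]], current)
    v <- current$values[px]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  names(out) <- ids
  out
}

hex_sum_current <- function(hexes, current, ids) {
  vapply(ids, function(k) {
    px <- hex_pixel_index(hexes$vertices[[k]], current)
    v <- current$values[px]
    if (all(is.na(v))) 0 else sum(v, na.rm = TRUE)
  }, 0)
}

#' Merge adjacent forested hexagons into habitat patches
#'
#' Connected components of the edge-adjacency graph over forested hexagons
#' (the six neighbours of a hexagon sit exactly one centre-spacing away);
#' deforested cells are never merged. Patch area is the summed hexagon area
#' and, when a current map is supplied, the patch attribute is the summed
#' pixel current divided by the patch area (mean current density).
#'
#' @param hexes A `hex_grid`.
#' @param statuses Data frame from [classify_hexes()].
#' @param current Optional current/consensus map for patch attributes.
#' @return List of `habitat_patch`es: id, hex_ids, area, attribute,
#'   geometry (list of member hexagon vertex matrices), centers.
#' @export
merge_forest_patches <- function(hexes, statuses, current = NULL) {
  fids <- statuses$id[statuses$status == "forested"]
  if (!length(fids)) return(list())
  cc <- hexes$cells[match(fids, hexes$cells$id), ]
  w <- sqrt(3) * hexes$s
  n <- length(fids)
  edges <- NULL
  if (n > 1) {
    d2 <- as.matrix(stats::dist(cbind(cc$cx, cc$cy)))
    adj <- which(d2 > 0 & d2 <= 1.01 * w, arr.ind = TRUE)
    adj <- adj[adj[, 1] < adj[, 2], , drop = FALSE]
    edges <- adj
  }
  g <- igraph::graph_from_data_frame(
    d = if (is.null(edges) || nrow(edges) == 0)
      data.frame(from = integer(0), to = integer(0))
    else data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  memb <- igraph::components(g)$membership[as.character(seq_len(n))]
  patches <- lapply(sort(unique(memb)), function(m) {
    members <- fids[memb == m]
    area <- length(members) * hexes$cell_area
    attr_val <- if (is.null(current)) NA_real_ else
      sum(hex_sum_current(hexes, current, members)) / area
    structure(list(id = m, hex_ids = members, area = area,
                   attribute = attr_val,
                   geometry = hexes$vertices[match(members, hexes$cells$id)],
                   centers = as.matrix(hexes$cells[match(members, hexes$cells$id),
                                                   c("cx", "cy")])),
              class = "habitat_patch")
  })
  patches
}

#' Edge-to-edge distance between two patch geometries
#'
#' Minimum Euclidean distance between the boundaries of two geometries, each
#' a polygon vertex matrix or a list of them (a multi-hexagon patch); 0 when
#' they touch or overlap.
#'
#' @param g1,g2 Geometries as described.
#' @return Distance in metres.
#' @export
interpatch_distance <- function(g1, g2) {
  l1 <- if (is.matrix(g1)) list(g1) else g1
  l2 <- if (is.matrix(g2)) list(g2) else g2
  best <- Inf
  for (p1 in l1) {
    for (p2 in l2) {
      # quick lower bound from centroids: skip hopeless pairs
      c1 <- colMeans(p1); c2 <- colMeans(p2)
      rad1 <- max(sqrt((p1[, 1] - c1[1])^2 + (p1[, 2] - c1[2])^2))
      rad2 <- max(sqrt((p2[, 1] - c2[1])^2 + (p2[, 2] - c2[2])^2))
      lb <- sqrt(sum((c1 - c2)^2)) - rad1 - rad2
      if (lb >= best) next
      d <- dist_polygon_polygon(p1, p2)
      if (d < best) best <- d
      if (best == 0) return(0)
    }
  }
  best
}

patch_geometry <- function(p) if (inherits(p, "habitat_patch")) p$geometry else p

#' Pairwise edge-to-edge distance matrix between patches
#'
#' @param patches List of `habitat_patch`es (or geometries).
#' @return Symmetric matrix of distances with zero diagonal.
#' @export
patch_distance_matrix <- function(patches) {
  n <- length(patches)
  d <- matrix(0, n, n)
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- interpatch_distance(patch_geometry(patches[[i]]),
                                                patch_geometry(patches[[j]]))
    }
  }
  d
}

#' Flag hexagons intersecting rivers
#'
#' A hexagon is riparian when its geometry overlaps, intersects or contains
#' any river polyline (a single intersection test subsumes all three).
#'
#' @param hexes A `hex_grid`.
#' @param rivers List of polyline vertex matrices.
#' @param ids Hexagon ids to test (default all).
#' @return Logical vector named by id.
#' @export
riparian_subset <- function(hexes, rivers, ids = hexes$cells$id) {
  out <- vapply(ids, function(k) {
    vv <- hexes$vertices[[match(k, hexes$cells$id)]]
    for (ln in rivers) if (polygon_intersects_polyline(vv, ln)) return(TRUE)
    FALSE
  }, TRUE)
  names(out) <- ids
  out
}
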