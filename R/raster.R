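# Minimal single-band raster container. `values` is a matrix whose first row
# is the northern edge; NA encodes NoData. Georeferencing is an origin (lower
# left corner), a square cell size in metres and a CRS label. The analysis
# refuses to mix rasters from different CRSs or grids: reprojection is out of
# scope and fails loudly.

#' Land-cover class codes
#'
#' The five reclassified land-cover categories used throughout the analysis:
#' forest (1), grassland (2), cropland (3), waterbodies (4), unsuitable (5).
#'
#' @return Named integer vector of class codes.
#' @export
lc_classes <- function() {
  c(forest = 1L, grassland = 2L, cropland = 3L,
    waterbodies = 4L, unsuitable = 5L)
}

#' Change-detection class codes
#'
#' @return Named integer vector: stable_forest (1), deforested (2), other (3).
#' @export
change_classes <- function() {
  c(stable_forest = 1L, deforested = 2L, other = 3L)
}

#' Create a grid raster
#'
#' @param values Matrix; row 1 is the northern row. NA is NoData.
#' @param cell_size Square cell side in metres (> 0).
#' @param origin Length-2 numeric, (xmin, ymin) of the lower-left corner.
#' @param crs CRS label; rasters combined in any operation must share it.
#' @return A `grid_raster` object.
#' @export
grid_raster <- function(values, cell_size = 60, origin = c(0, 0),
                        crs = "local-metric") {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2) stop("`origin` must be length 2 (xmin, ymin)")
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin), crs = as.character(crs)),
            class = "grid_raster")
}

#' Create a land-cover raster
#'
#' Like [grid_raster()] but the in-extent values must be drawn from the five
#' codes of [lc_classes()].
#'
#' @inheritParams grid_raster
#' @return A `grid_raster` with validated class codes.
#' @export
lc_raster <- function(values, cell_size = 60, origin = c(0, 0),
                      crs = "local-metric") {
  v <- values[!is.na(values)]
  if (length(v) && !all(v %in% lc_classes()))
    stop("land-cover values outside the 5 reclassified codes: ",
         paste(sort(unique(v[!v %in% lc_classes()])), collapse = ", "))
  r <- grid_raster(values, cell_size, origin, crs)
  class(r) <- c("lc_raster", class(r))
  r
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<%s> %d x %d cells @ %g m, origin (%g, %g), crs '%s'\n",
              class(x)[1], nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2], x$crs))
  tab <- table(x$values, useNA = "ifany")
  cat("  values:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Do two rasters share the same grid geometry?
#'
#' @param a,b `grid_raster` objects.
#' @return Logical scalar.
#' @export
same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin)) &&
    identical(a$crs, b$crs)
}

stop_if_misaligned <- function(a, b, what = "rasters") {
  if (!identical(a$crs, b$crs))
    stop("CRS mismatch between ", what, " ('", a$crs, "' vs '", b$crs,
         "'); reprojection is out of scope")
  if (!same_geometry(a, b))
    stop("grid geometry mismatch between ", what)
  invisible(TRUE)
}

#' Cell-centre coordinates
#'
#' @param r A `grid_raster`.
#' @return List with `x` (length ncol, west to east) and `y` (length nrow,
#'   north to south, matching matrix row order).
#' @export
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cell_size
  list(x = r$origin[1] + (seq_len(nc) - 0.5) * cs,
       y = r$origin[2] + (nr - seq_len(nr) + 0.5) * cs)
}

#' Raster extent
#'
#' @param r A `grid_raster`.
#' @param as_polygon Return a 4x2 rectangle vertex matrix instead of bounds.
#' @return Either `c(xmin, ymin, xmax, ymax)` or a rectangle polygon.
#' @export
raster_extent <- function(r, as_polygon = FALSE) {
  b <- c(xmin = r$origin[1], ymin = r$origin[2],
         xmax = r$origin[1] + ncol(r$values) * r$cell_size,
         ymax = r$origin[2] + nrow(r$values) * r$cell_size)
  if (as_polygon) rect_polygon(b[1], b[2], b[3], b[4]) else b
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by standard GIS tools.
#'
#' @param r A `grid_raster`.
#' @param path Output file path.
#' @param nodata NoData sentinel written for NA cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  hdr <- c(sprintf("ncols %d", ncol(r$values)),
           sprintf("nrows %d", nrow(r$values)),
           sprintf("xllcorner %.10g", r$origin[1]),
           sprintf("yllcorner %.10g", r$origin[2]),
           sprintf("cellsize %.10g", r$cell_size),
           sprintf("NODATA_value %g", nodata))
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @param crs CRS label to attach (ASCII grids carry none).
#' @param integer Coerce values to integer (for categorical rasters).
#' @return A `grid_raster`.
#' @export
read_ascii_grid <- function(path, crs = "local-metric", integer = FALSE) {
  lines <- readLines(path, n = 6)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]), 0),
                         tolower(vapply(kv, `[`, "", 1)))
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == hdr[["nodata_value"]]] <- NA
  if (integer) storage.mode(v) <- "integer"
  grid_raster(v, cell_size = hdr[["cellsize"]],
              origin = c(hdr[["xllcorner"]], hdr[["yllcorner"]]), crs = crs)
}

#' Write simple features as GeoJSON
#'
#' Supports a polygon (2-column matrix), a list of polylines, or a data frame
#' of points with `x`/`y` columns. Properties beyond the geometry are carried
#' through for points.
#'
#' @param geom Geometry as described above.
#' @param path Output path.
#' @param type One of "polygon", "polylines", "points".
#' @param properties Optional named list stored on every feature.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(geom, path, type = c("polygon", "polylines", "points"),
                          properties = NULL) {
  type <- match.arg(type)
  props <- if (is.null(properties)) stats::setNames(list(), character()) else properties
  feat <- switch(type,
    polygon = list(list(
      type = "Feature", properties = props,
      geometry = list(type = "Polygon",
                      coordinates = list(rbind(geom, geom[1, , drop = FALSE]))))),
    polylines = lapply(geom, function(ln) list(
      type = "Feature", properties = props,
      geometry = list(type = "LineString", coordinates = ln))),
    points = lapply(seq_len(nrow(geom)), function(i) list(
      type = "Feature",
      properties = c(props, as.list(geom[i, setdiff(names(geom), c("x", "y")),
                                         drop = FALSE])),
      geometry = list(type = "Point", coordinates = c(geom$x[i], geom$y[i]))))
  )
  obj <- list(type = "FeatureCollection", features = feat)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
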