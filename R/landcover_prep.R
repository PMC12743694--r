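# Scenario preparation: reclassification to the five analysis categories,
# nearest-neighbour resampling to a coarser working resolution, masking above
# the tree line, burning the project footprint to unsuitable (the
# after-construction scenario), and two-date deforestation detection.

#' Default raw-class reclassification table
#'
#' Maps the national land-cover product's classes onto the five broader
#' analysis categories: forest and other wooded land to forest; water body and
#' riverbed to waterbodies; glacier, snow, built-up area, bare soil and bare
#' rock to unsuitable; cropland and grassland unchanged.
#'
#' @return Data frame with columns `raw` (integer code), `name` and `class`.
#' @export
reclass_table <- function() {
  data.frame(
    raw = 1:11,
    name = c("forest", "other wooded land", "water body", "riverbed",
             "cropland", "grassland", "glacier", "snow", "built-up area",
             "bare soil", "bare rock"),
    class = c("forest", "forest", "waterbodies", "waterbodies", "cropland",
              "grassland", rep("unsuitable", 5)),
    stringsAsFactors = FALSE)
}

#' Reclassify a raw categorical raster to the five analysis classes
#'
#' @param raw A `grid_raster` of raw integer class codes.
#' @param mapping Data frame with columns `raw` (codes present in `raw`) and
#'   `class` (names from [lc_classes()]). Defaults to [reclass_table()].
#' @return An `lc_raster` on the same grid.
#' @export
reclassify <- function(raw, mapping = reclass_table()) {
  stopifnot(inherits(raw, "grid_raster"))
  if (!all(c("raw", "class") %in% names(mapping)))
    stop("`mapping` needs columns `raw` and `class`")
  if (!all(mapping$class %in% names(lc_classes())))
    stop("mapping targets unknown classes: ",
         paste(setdiff(mapping$class, names(lc_classes())), collapse = ", "))
  present <- unique(raw$values[!is.na(raw$values)])
  missing <- setdiff(present, mapping$raw)
  if (length(missing))
    stop("no mapping entry for raw class code(s): ",
         paste(sort(missing), collapse = ", "))
  lut <- stats::setNames(lc_classes()[mapping$class], as.character(mapping$raw))
  out <- raw$values
  ok <- !is.na(out)
  out[ok] <- lut[as.character(raw$values[ok])]
  storage.mode(out) <- "integer"
  lc_raster(out, raw$cell_size, raw$origin, raw$crs)
}

# Nearest source index for output centres at positions t (in source cell
# units, so source centre j sits at j - 0.5). Equidistant ties go to the
# smaller index.
nearest_index <- function(t_units, n) {
  j <- ceiling(t_units - 0.5)
  pmin(pmax(j, 1L), n)
}

#' Resample a categorical raster to a coarser grid (nearest neighbour)
#'
#' Each output cell takes the class of the source cell whose centre is nearest
#' the output cell centre; equidistant ties resolve to the smaller row, then
#' column index. The output grid shares the source origin.
#'
#' @param lc An `lc_raster` (or any categorical `grid_raster`).
#' @param target_cell_size Output cell size in metres (>= source size).
#' @return Resampled raster of the same class.
#' @export
resample_nearest <- function(lc, target_cell_size) {
  stopifnot(inherits(lc, "grid_raster"))
  if (!is.numeric(target_cell_size) || target_cell_size <= 0)
    stop("target_cell_size must be > 0")
  s <- lc$cell_size
  if (target_cell_size < s)
    stop("target_cell_size must be >= the source cell size")
  if (target_cell_size == s) return(lc)
  nr <- nrow(lc$values); nc <- ncol(lc$values)
  ratio <- target_cell_size / s
  nr_out <- max(1L, round(nr / ratio)); nc_out <- max(1L, round(nc / ratio))
  # output centre positions measured in source-cell units from the grid edge
  tx <- (seq_len(nc_out) - 0.5) * ratio
  ty <- (seq_len(nr_out) - 0.5) * ratio   # from the top edge (row direction)
  src_c <- nearest_index(tx, nc)
  src_r <- nearest_index(ty, nr)
  out <- lc$values[src_r, src_c, drop = FALSE]
  res <- grid_raster(out, target_cell_size, lc$origin, lc$crs)
  class(res) <- class(lc)
  res
}

#' Mask land above the tree line as unsuitable
#'
#' Cells with elevation strictly greater than `threshold` become unsuitable;
#' cells at exactly the threshold keep their class.
#'
#' @param lc An `lc_raster`.
#' @param dem A `grid_raster` of elevations on the identical grid.
#' @param threshold Elevation threshold in metres (default 3600, the upper
#'   tree line).
#' @return Masked `lc_raster`.
#' @export
apply_elevation_mask <- function(lc, dem, threshold = 3600) {
  stop_if_misaligned(lc, dem, "land cover and elevation")
  out <- lc$values
  hi <- !is.na(dem$values) & dem$values > threshold & !is.na(out)
  out[hi] <- lc_classes()[["unsuitable"]]
  lc_raster(out, lc$cell_size, lc$origin, lc$crs)
}

#' Burn the project footprint into the land cover
#'
#' Cells whose centre lies inside the footprint polygon become unsuitable;
#' the result is the after-construction scenario land cover. The operation is
#' idempotent.
#'
#' @param lc An `lc_raster`.
#' @param footprint Two-column vertex matrix in the same CRS.
#' @return Burned `lc_raster`.
#' @export
burn_footprint <- function(lc, footprint) {
  if (!is.matrix(footprint) || ncol(footprint) != 2 || nrow(footprint) < 3)
    stop("footprint must be a polygon vertex matrix (>= 3 vertices)")
  if (polygon_area(footprint) <= 0) stop("footprint polygon has zero area")
  cc <- cell_centers(lc)
  g <- expand.grid(x = cc$x, y = cc$y)       # x fastest => row-major over cells
  inside <- pts_in_polygon(g$x, g$y, footprint)
  out <- t(lc$values)
  out[inside & !is.na(out)] <- lc_classes()[["unsuitable"]]
  lc_raster(t(out), lc$cell_size, lc$origin, lc$crs)
}

#' Detect deforestation between two dates
#'
#' Per-cell change classes: `stable_forest` where both dates are forest,
#' `deforested` where date-1 forest became cropland or unsuitable, `other`
#' everywhere else (including forest converted to grassland or waterbodies,
#' which does not count as deforestation).
#'
#' @param lc_t1,lc_t2 `lc_raster`s on the identical grid.
#' @return A `grid_raster` of [change_classes()] codes (class `change_raster`).
#' @export
detect_deforestation <- function(lc_t1, lc_t2) {
  stop_if_misaligned(lc_t1, lc_t2, "the two land-cover dates")
  cls <- lc_classes(); chg <- change_classes()
  v1 <- lc_t1$values; v2 <- lc_t2$values
  ok <- !is.na(v1) & !is.na(v2)
  out <- matrix(chg[["other"]], nrow(v1), ncol(v1))
  out[ok & v1 == cls[["forest"]] & v2 == cls[["forest"]]] <- chg[["stable_forest"]]
  out[ok & v1 == cls[["forest"]] &
        (v2 == cls[["cropland"]] | v2 == cls[["unsuitable"]])] <- chg[["deforested"]]
  out[!ok] <- NA
  storage.mode(out) <- "integer"
  r <- grid_raster(out, lc_t1$cell_size, lc_t1$origin, lc_t1$crs)
  class(r) <- c("change_raster", class(r))
  r
}
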