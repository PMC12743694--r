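# Factorial resistance-surface ensemble. Forest is always the most permeable
# class (resistance 1) and unsuitable the least (100); cropland, grassland and
# waterbodies each take a low/medium/high level, giving 3^3 = 27 profiles by
# default. Resistances are dimensionless per-cell traversal costs.

#' Default per-class resistance levels
#'
#' @return Named list of allowed resistance values per class: forest fixed at
#'   1, unsuitable fixed at 100, and low (10) / medium (50) / high (90) for
#'   cropland, grassland and waterbodies.
#' @export
default_resistance_levels <- function() {
  list(forest = 1, grassland = c(10, 50, 90), cropland = c(10, 50, 90),
       waterbodies = c(10, 50, 90), unsuitable = 100)
}

#' Enumerate the factorial set of resistance profiles
#'
#' Full Cartesian product of the per-class levels, ordered lexicographically
#' by (cropland, grassland, waterbodies); `profile_id` runs 1..N in that
#' order.
#'
#' @param levels Named list of allowed resistances per class; see
#'   [default_resistance_levels()].
#' @return Data frame with one row per profile: `profile_id`, `forest`,
#'   `grassland`, `cropland`, `waterbodies`, `unsuitable`.
#' @export
enumerate_profiles <- function(levels = default_resistance_levels()) {
  need <- names(lc_classes())
  if (!all(need %in% names(levels)))
    stop("levels must name every class: ", paste(need, collapse = ", "))
  if (any(vapply(levels[need], length, 0L) == 0))
    stop("every class needs at least one resistance level")
  rng <- unlist(levels[need])
  if (any(rng < 1 | rng > 100)) stop("resistances must lie in [1, 100]")
  g <- expand.grid(waterbodies = levels$waterbodies,
                   grassland = levels$grassland,
                   cropland = levels$cropland,
                   forest = levels$forest,
                   unsuitable = levels$unsuitable,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$cropland, g$grassland, g$waterbodies), , drop = FALSE]
  out <- data.frame(profile_id = seq_len(nrow(g)),
                    forest = g$forest, grassland = g$grassland,
                    cropland = g$cropland, waterbodies = g$waterbodies,
                    unsuitable = g$unsuitable, row.names = NULL)
  out
}

#' Rasterise a resistance profile over a land cover
#'
#' Per-cell lookup of the profile's class resistance; NoData propagates.
#'
#' @param lc An `lc_raster`.
#' @param profile One row of [enumerate_profiles()] (data frame or named
#'   list/vector with the five class resistances).
#' @return A `grid_raster` with class `resistance_surface` and attached
#'   `profile_id`.
#' @export
build_resistance_surface <- function(lc, profile) {
  stopifnot(inherits(lc, "grid_raster"))
  p <- as.list(profile)
  res <- unlist(p[names(lc_classes())])
  if (length(res) != 5 || any(is.na(res)))
    stop("profile must give a resistance for each of the 5 classes")
  out <- matrix(NA_real_, nrow(lc$values), ncol(lc$values))
  ok <- !is.na(lc$values)
  out[ok] <- res[lc$values[ok]]
  r <- grid_raster(out, lc$cell_size, lc$origin, lc$crs)
  class(r) <- c("resistance_surface", class(r))
  r$profile_id <- if (!is.null(p$profile_id)) p$profile_id else NA_integer_
  r
}

#' Write the profile manifest as CSV
#'
#' @param profiles Data frame from [enumerate_profiles()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_manifest <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}
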