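# Ensemble reduction: near-duplicate current maps (Spearman rho above the
# threshold) are dropped by a greedy keep-first scan in profile order, the
# retained maps are summed into one consensus map per scenario, and the two
# scenarios are compared as a signed percent-change map.

map_values_matrix <- function(maps) {
  vals <- vapply(maps, function(m) as.numeric(m$values), numeric(length(maps[[1]]$values)))
  vals
}

#' Drop near-duplicate current maps by rank correlation
#'
#' Greedy scan in input (profile) order: a map is retained iff its Spearman
#' rho with every already-retained map does not exceed `rho_threshold`. Rho
#' is computed over the jointly valid (non-NoData) cells with average ranks
#' for ties; two constant maps count as perfectly correlated.
#'
#' @param maps Ordered list of `current_map`s on one grid.
#' @param rho_threshold Spearman coefficient above which a map is a
#'   duplicate (default 0.99).
#' @return List with `retained` (the kept maps), `retained_ids` (their
#'   positions / profile ids) and the full pairwise decisions.
#' @export
spearman_dedup <- function(maps, rho_threshold = 0.99) {
  if (length(maps) < 1) stop("need at least one map")
  for (m in maps[-1]) stop_if_misaligned(maps[[1]], m, "current maps")
  vals <- map_values_matrix(maps)
  valid <- stats::complete.cases(vals)
  v <- vals[valid, , drop = FALSE]
  ranks <- apply(v, 2, rank)  # average ranks for ties
  keep <- integer(0)
  for (k in seq_along(maps)) {
    dup <- FALSE
    for (r in keep) {
      s1 <- stats::sd(ranks[, k]); s2 <- stats::sd(ranks[, r])
      rho <- if (s1 == 0 || s2 == 0) {
        if (isTRUE(all.equal(v[, k], v[, r]))) 1 else 0
      } else {
        stats::cor(ranks[, k], ranks[, r])
      }
      if (rho > rho_threshold) { dup <- TRUE; break }
    }
    if (!dup) keep <- c(keep, k)
  }
  ids <- vapply(maps[keep], function(m)
    if (is.null(m$profile_id) || is.na(m$profile_id)) NA_integer_
    else as.integer(m$profile_id), 1L)
  if (anyNA(ids)) ids <- keep
  list(retained = maps[keep], retained_ids = ids,
       rho_threshold = rho_threshold)
}

#' Sum retained current maps into a consensus map
#'
#' @param retained List of `current_map`s (e.g. `spearman_dedup()$retained`).
#' @param retained_ids Optional profile ids recorded on the result.
#' @return A `consensus_map`: `grid_raster` of the element-wise sum.
#' @export
sum_consensus <- function(retained, retained_ids = NULL) {
  if (length(retained) < 1) stop("need at least one retained map")
  for (m in retained[-1]) stop_if_misaligned(retained[[1]], m, "current maps")
  acc <- retained[[1]]$values
  for (m in retained[-1]) acc <- acc + m$values
  r <- grid_raster(acc, retained[[1]]$cell_size, retained[[1]]$origin,
                   retained[[1]]$crs)
  class(r) <- c("consensus_map", class(r))
  r$retained_ids <- if (is.null(retained_ids)) seq_along(retained) else retained_ids
  r
}

#' Percent change between two consensus maps
#'
#' `100 * (after - before) / before` per cell. Cells where both scenarios
#' carry zero current are 0; cells where current appears from nothing
#' (before 0, after > 0) are masked undefined (NA with `mask = TRUE`).
#'
#' @param before,after `consensus_map`s on one grid.
#' @return A `change_map`: `grid_raster` of signed percent change with a
#'   logical `mask` matrix marking undefined cells.
#' @export
percent_change <- function(before, after) {
  stop_if_misaligned(before, after, "consensus maps")
  b <- before$values; a <- after$values
  out <- matrix(NA_real_, nrow(b), ncol(b))
  mask <- matrix(FALSE, nrow(b), ncol(b))
  ok <- !is.na(b) & !is.na(a)
  pos <- ok & b > 0
  out[pos] <- 100 * (a[pos] - b[pos]) / b[pos]
  zz <- ok & b == 0 & a == 0
  out[zz] <- 0
  undef <- ok & b == 0 & a > 0
  mask[undef] <- TRUE
  r <- grid_raster(out, before$cell_size, before$origin, before$crs)
  class(r) <- c("change_map", class(r))
  r$mask <- mask
  r
}
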