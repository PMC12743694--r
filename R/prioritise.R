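# Candidate filtering, ranking and export. The percentile filter keeps
# deforested hexagons whose mean after-construction current density lies
# strictly above the q-th percentile of the deforested population; the
# ranking selects, per dispersal distance, the N candidates with highest
# varIIC, N chosen so the selected area matches the forest area lost to the
# project.

#' Filter deforested hexagons by current-density percentile
#'
#' @param mean_currents Named numeric vector of per-hexagon mean
#'   after-construction current density over the deforested cells (names =
#'   hexagon ids); see [hex_mean_current()].
#' @param q Percentile (default 20); the threshold is the linear-interpolation
#'   (type 7) percentile of the supplied distribution.
#' @return List with `ids` (retained hexagon ids), `threshold` and the input
#'   `mean_currents`. Warns and returns zero ids when no cell lies strictly
#'   above the threshold (e.g. an all-equal distribution).
#' @export
percentile_filter <- function(mean_currents, q = 20) {
  if (!length(mean_currents)) stop("need at least one deforested cell")
  mc <- mean_currents[!is.na(mean_currents)]
  thr <- stats::quantile(mc, q / 100, names = FALSE, type = 7)
  keep <- names(mc)[mc > thr]
  if (!length(keep))
    warning("no deforested cell lies strictly above the ", q,
            "th percentile (threshold ", signif(thr, 4), ")")
  list(ids = as.integer(keep), threshold = thr, mean_currents = mc)
}

#' Rank candidates and build the priority selection
#'
#' Per distance, the `N` candidates with highest varIIC are selected (ties
#' broken by ascending id), where `N = round(lost_forest_area / cell_area)`
#' (round half up). Overlap categories count, over the union of selected
#' candidates, in how many distances each was selected; the category
#' percentages sum to 100.
#'
#' @param scores Long data frame with columns `id`, `distance`, `variic`.
#' @param lost_forest_area Forest area removed by the project, m^2.
#' @param cell_area Hexagon area, m^2 (default 1e5).
#' @return A `priority_ranking`: `n_select`, `by_distance` (per-distance
#'   ranked data frames with a `selected` flag), `selected` (id lists),
#'   `overlap` (id, n_distances) and `summary` (category, pct).
#' @export
rank_candidates <- function(scores, lost_forest_area, cell_area = 1e5) {
  stopifnot(all(c("id", "distance", "variic") %in% names(scores)))
  n_sel <- floor(lost_forest_area / cell_area + 0.5)
  if (n_sel <= 0) stop("selection size N is not positive")
  dists <- sort(unique(scores$distance))
  by_distance <- list(); selected <- list()
  for (d in dists) {
    sub <- scores[scores$distance == d, , drop = FALSE]
    ord <- order(-sub$variic, sub$id)
    sub <- sub[ord, , drop = FALSE]
    sub$rank <- seq_len(nrow(sub))
    sub$selected <- sub$rank <= n_sel
    by_distance[[as.character(d)]] <- sub
    selected[[as.character(d)]] <- sub$id[sub$selected]
  }
  union_ids <- sort(unique(unlist(selected)))
  n_in <- vapply(union_ids, function(i)
    sum(vapply(selected, function(s) i %in% s, TRUE)), 0L)
  overlap <- data.frame(id = union_ids, n_distances = n_in)
  summary <- data.frame(
    category = seq_along(dists),
    pct = vapply(seq_along(dists), function(k)
      100 * mean(n_in == k), 0))
  structure(list(n_select = n_sel, distances = dists,
                 by_distance = by_distance, selected = selected,
                 overlap = overlap, summary = summary),
            class = "priority_ranking")
}

#' @export
print.priority_ranking <- function(x, ...) {
  cat(sprintf("<priority_ranking> N = %d per distance\n", x$n_select))
  for (d in names(x$selected)) {
    sel <- x$by_distance[[d]]
    sel <- sel[sel$selected, ]
    cat(sprintf("  d = %s m: %d selected, varIIC %.4g .. %.4g\n", d,
                nrow(sel), min(sel$variic), max(sel$variic)))
  }
  cat("  overlap:",
      paste(sprintf("%d-distance %.0f%%", x$summary$category, x$summary$pct),
            collapse = ", "), "\n")
  invisible(x)
}

#' Export patches and candidates in Conefor plain-text format
#'
#' Writes the node file (id, attribute) and the pairwise distance file
#' (id1, id2, distance) so the IIC/varIIC computations can be verified with
#' external connectivity software.
#'
#' @param patches List of `habitat_patch`es.
#' @param candidates Optional data frame with `id`, `attribute` and a
#'   parallel `geometries` list.
#' @param nodes_path,dists_path Output file paths.
#' @param geometries Candidate geometries matching `candidates`.
#' @return Invisible list of the two paths.
#' @export
export_conefor <- function(patches, candidates = NULL, nodes_path, dists_path,
                           geometries = NULL) {
  a <- patch_attr_vector(patches)
  ids <- seq_along(a)
  geoms <- lapply(patches, patch_geometry)
  if (!is.null(candidates)) {
    ids <- c(ids, max(ids) + seq_len(nrow(candidates)))
    a <- c(a, candidates$attribute)
    geoms <- c(geoms, geometries)
  }
  nodes <- data.frame(id = ids, attribute = a)
  utils::write.table(format(nodes, digits = 17, scientific = FALSE, trim = TRUE),
                     nodes_path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  n <- length(ids)
  out <- list()
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      out[[length(out) + 1]] <- c(ids[i], ids[j],
                                  interpatch_distance(geoms[[i]], geoms[[j]]))
    }
  }
  dd <- do.call(rbind, out)
  utils::write.table(format(as.data.frame(dd), digits = 17,
                            scientific = FALSE, trim = TRUE),
                     dists_path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(list(nodes = nodes_path, distances = dists_path))
}

#' Read back Conefor node and distance files
#'
#' @param nodes_path,dists_path Paths written by [export_conefor()].
#' @return List with `nodes` (id, attribute) and `distances`
#'   (id1, id2, distance) data frames.
#' @export
read_conefor <- function(nodes_path, dists_path) {
  nodes <- utils::read.table(nodes_path,
                             col.names = c("id", "attribute"))
  dists <- utils::read.table(dists_path,
                             col.names = c("id1", "id2", "distance"))
  list(nodes = nodes, distances = dists)
}
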