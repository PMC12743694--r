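# Integral Index of Connectivity on the binary patch graph. Two patches are
# linked when their edge-to-edge distance is at most the dispersal threshold
# d; nl_ij is the minimum number of links between i and j (BFS); pairs in
# different components contribute nothing.
#
#   IIC = [ sum_i sum_j a_i * a_j / (1 + nl_ij) ] / A_L^2
#
# varIIC of a candidate is the percent increase of IIC when the candidate is
# added as a new node with its own attribute, links recomputed.

patch_attr_vector <- function(patches) {
  if (is.numeric(patches)) return(patches)
  vapply(patches, function(p) if (is.list(p)) p$attribute else as.numeric(p), 0)
}

iic_numerator <- function(a, nl) {
  wt <- 1 / (1 + nl)
  wt[!is.finite(nl)] <- 0
  as.numeric(t(a) %*% wt %*% a)
}

link_counts <- function(distmat, d) {
  adj <- (distmat <= d) * 1
  diag(adj) <- 0
  dimnames(adj) <- NULL
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::distances(g)   # unweighted link counts; Inf across components
}

#' Integral Index of Connectivity
#'
#' @param patches List of `habitat_patch`es, or a numeric vector of patch
#'   attributes when `distmat` is supplied.
#' @param d Dispersal distance threshold in metres (> 0).
#' @param A_L Total landscape (analysis extent) area, in units consistent
#'   with the attributes.
#' @param distmat Optional precomputed edge-to-edge distance matrix.
#' @return The IIC value (dimensionless).
#' @export
compute_iic <- function(patches, d, A_L, distmat = NULL) {
  if (!is.numeric(d) || d <= 0) stop("d must be > 0")
  if (!is.numeric(A_L) || A_L <= 0) stop("A_L must be > 0")
  a <- patch_attr_vector(patches)
  if (length(a) < 1) stop("need at least one patch")
  if (is.null(distmat)) distmat <- patch_distance_matrix(patches)
  nl <- link_counts(distmat, d)
  iic_numerator(a, nl) / A_L^2
}

#' varIIC of adding one candidate node
#'
#' The candidate is evaluated as a new patch with its own attribute; links
#' and shortest-path link counts are recomputed with the candidate present.
#' `varIIC = 100 * (IIC_with - IIC_base) / IIC_base`; node addition can only
#' add terms and shorten paths, so varIIC >= 0.
#'
#' @param candidate List with `attribute` and `geometry` (polygon matrix or
#'   list of them), or just an attribute when `cand_dists` is supplied.
#' @param patches List of `habitat_patch`es (or attribute vector with
#'   `distmat`).
#' @param d Dispersal distance threshold (metres).
#' @param A_L Landscape area.
#' @param distmat Optional patch-patch distance matrix.
#' @param cand_dists Optional vector of candidate-to-patch distances.
#' @param base_iic Optional precomputed base IIC (> 0).
#' @return varIIC in percent.
#' @export
variic_add <- function(candidate, patches, d, A_L, distmat = NULL,
                       cand_dists = NULL, base_iic = NULL) {
  a <- patch_attr_vector(patches)
  if (is.null(distmat)) distmat <- patch_distance_matrix(patches)
  if (is.null(base_iic)) base_iic <- compute_iic(a, d, A_L, distmat)
  if (base_iic <= 0) stop("base IIC is 0: degenerate landscape")
  a_c <- if (is.list(candidate)) candidate$attribute else as.numeric(candidate)
  if (is.null(cand_dists)) {
    geom <- candidate$geometry
    cand_dists <- vapply(patches, function(p)
      interpatch_distance(geom, patch_geometry(p)), 0)
  }
  n <- length(a)
  dist_ext <- rbind(cbind(distmat, cand_dists), c(cand_dists, 0))
  nl <- link_counts(dist_ext, d)
  iic_with <- iic_numerator(c(a, a_c), nl) / A_L^2
  100 * (iic_with - base_iic) / base_iic
}

#' Score every candidate hexagon at every dispersal distance
#'
#' One-at-a-time node addition over the candidate set for each threshold,
#' reusing the patch-patch distances and each candidate's distances to the
#' patches across thresholds.
#'
#' @param candidates Data frame with `id` and `attribute`, plus a parallel
#'   list `geometries` of polygon matrices.
#' @param geometries List of candidate geometries (same order as
#'   `candidates`).
#' @param patches List of `habitat_patch`es.
#' @param distances Vector of thresholds in metres.
#' @param A_L Landscape area.
#' @return Long data frame: id, distance, variic.
#' @export
score_candidates <- function(candidates, geometries, patches, distances, A_L) {
  distmat <- patch_distance_matrix(patches)
  cand_d <- lapply(geometries, function(g)
    vapply(patches, function(p) interpatch_distance(g, patch_geometry(p)), 0))
  out <- list()
  for (d in distances) {
    base <- compute_iic(patches, d, A_L, distmat)
    sc <- vapply(seq_len(nrow(candidates)), function(k)
      variic_add(list(attribute = candidates$attribute[k]),
                 patches, d, A_L, distmat = distmat,
                 cand_dists = cand_d[[k]], base_iic = base), 0)
    out[[length(out) + 1]] <- data.frame(id = candidates$id, distance = d,
                                         variic = sc)
  }
  do.call(rbind, out)
}
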