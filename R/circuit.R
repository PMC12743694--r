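# From-scratch circuit-theory connectivity. A resistance raster becomes an
# undirected conductance network on the 8-neighbour lattice; current flow
# between focal-node pairs is solved exactly through a sparse Cholesky
# factorization of the reduced graph Laplacian (one factorization per
# component, reused across every pair right-hand side), and per-cell current
# densities are accumulated over all pairs.

#' Build the 8-neighbour conductance network of a resistance surface
#'
#' Orthogonal neighbours i, j receive conductance `1 / ((r_i + r_j) / 2)`
#' (the average-resistance scheme); diagonal neighbours get that value
#' divided by sqrt(2) to account for the longer traversal. NoData cells are
#' excluded from the graph.
#'
#' @param resistance A `resistance_surface` (or any positive-valued
#'   `grid_raster`).
#' @return A `conductance_graph`: node table (id, row, col), edge table
#'   (i, j, conductance), component membership, the node-index matrix and the
#'   source grid geometry.
#' @export
build_network <- function(resistance) {
  v <- resistance$values
  nr <- nrow(v); nc <- ncol(v)
  ok <- !is.na(v)
  if (!any(ok)) stop("resistance raster has no in-extent cells")
  if (any(v[ok] <= 0)) stop("resistances must be positive")
  idx <- matrix(NA_integer_, nr, nc)
  idx[ok] <- seq_len(sum(ok))
  n <- sum(ok)
  rows <- row(v)[ok]; cols <- col(v)[ok]

  edge_block <- function(dr, dc, diagonal) {
    r1 <- if (dr > 0) seq_len(nr - dr) else seq_len(nr)
    r2 <- r1 + dr
    if (dc >= 0) { c1 <- seq_len(nc - dc); c2 <- c1 + dc }
    else { c1 <- seq(1 - dc, nc); c2 <- c1 + dc }
    i <- idx[r1, c1, drop = FALSE]; j <- idx[r2, c2, drop = FALSE]
    ri <- v[r1, c1, drop = FALSE]; rj <- v[r2, c2, drop = FALSE]
    keep <- !is.na(i) & !is.na(j)
    g <- 1 / ((ri[keep] + rj[keep]) / 2)
    if (diagonal) g <- g / sqrt(2)
    data.frame(i = i[keep], j = j[keep], conductance = g)
  }
  edges <- rbind(edge_block(0, 1, FALSE),   # east
                 edge_block(1, 0, FALSE),   # south
                 edge_block(1, 1, TRUE),    # south-east
                 edge_block(1, -1, TRUE))   # south-west
  g <- igraph::graph_from_data_frame(
    edges[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)$membership[as.character(seq_len(n))]
  structure(list(n = n, nodes = data.frame(id = seq_len(n), row = rows, col = cols),
                 edges = edges, component = unname(comp), node_index = idx,
                 dim = c(nr, nc),
                 geometry = list(cell_size = resistance$cell_size,
                                 origin = resistance$origin, crs = resistance$crs),
                 profile_id = resistance$profile_id),
            class = "conductance_graph")
}

network_laplacian <- function(net) {
  e <- net$edges
  L <- Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i),
                            x = -c(e$conductance, e$conductance),
                            dims = c(net$n, net$n))
  Matrix::forceSymmetric(L + Matrix::Diagonal(net$n, -Matrix::rowSums(L)))
}

# n x m sparse incidence used to accumulate |edge current| onto both endpoints
node_edge_incidence <- function(net) {
  m <- nrow(net$edges)
  Matrix::sparseMatrix(i = c(net$edges$i, net$edges$j), j = rep(seq_len(m), 2),
                       x = 1, dims = c(net$n, m))
}

#' Solve one pairwise current flow
#'
#' Injects unit current at `source` and extracts it at `ground` (voltage 0),
#' solving the Laplacian system exactly on the component containing both
#' nodes.
#'
#' @param graph A `conductance_graph`.
#' @param source,ground Node ids (distinct, same component).
#' @return List with `voltages` (length-n, NA outside the solved component,
#'   0 at ground), `currents` (edge table with signed current i -> j), and
#'   `effective_resistance` (= voltage at the source).
#' @export
solve_pair <- function(graph, source, ground) {
  if (source == ground) stop("source and ground must differ")
  comp <- graph$component
  if (comp[source] != comp[ground])
    stop("source and ground lie in different components")
  keep <- which(comp == comp[source])
  pos <- match(seq_len(graph$n), keep)
  L <- network_laplacian(graph)[keep, keep, drop = FALSE]
  ref <- pos[ground]
  b <- numeric(length(keep))
  b[pos[source]] <- 1
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(L[-ref, -ref, drop = FALSE]),
                         LDL = FALSE)
  v_red <- as.numeric(Matrix::solve(ch, b[-ref], system = "A"))
  v_comp <- numeric(length(keep))
  v_comp[-ref] <- v_red
  voltages <- rep(NA_real_, graph$n)
  voltages[keep] <- v_comp
  e <- graph$edges
  cur <- e$conductance * (voltages[e$i] - voltages[e$j])
  cur[is.na(cur)] <- 0
  list(voltages = voltages,
       currents = data.frame(i = e$i, j = e$j, current = cur),
       effective_resistance = voltages[source])
}

#' Sample focal nodes in a buffer ring around the study area
#'
#' Draws `n` distinct raster cells uniformly at random (seeded) from the ring
#' of in-extent cells lying outside the study-area polygon but within
#' `buffer_width` of its boundary. NoData cells are never selected.
#'
#' @param extent Study-area polygon (two-column vertex matrix).
#' @param buffer_width Ring width in metres.
#' @param n Number of focal nodes (>= 2).
#' @param resistance A `resistance_surface` (or land cover) providing the
#'   grid and NoData pattern.
#' @param seed Integer seed.
#' @return A `focal_nodes` object: data frame of points (x, y, row, col) plus
#'   the buffer width and seed.
#' @export
sample_focal_nodes <- function(extent, buffer_width, n, resistance, seed) {
  if (n < 2) stop("need at least 2 focal nodes")
  cc <- cell_centers(resistance)
  g <- expand.grid(col = seq_along(cc$x), row = seq_along(cc$y))
  px <- cc$x[g$col]; py <- cc$y[g$row]
  valid <- !is.na(resistance$values[cbind(g$row, g$col)])
  inside <- pts_in_polygon(px, py, extent)
  d <- dist_point_polygon_boundary(px, py, extent)
  ring <- valid & !inside & d <= buffer_width
  cand <- which(ring)
  if (length(cand) < n)
    stop("buffer ring holds only ", length(cand), " candidate cells; need ", n)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  pick <- if (length(cand) == n) cand else sample(cand, n)
  structure(list(points = data.frame(x = px[pick], y = py[pick],
                                     row = g$row[pick], col = g$col[pick]),
                 buffer_width = buffer_width, seed = seed),
            class = "focal_nodes")
}

#' Shrink a raster extent inward
#'
#' @param r A `grid_raster`.
#' @param width Inset width in metres on every side.
#' @return Rectangle polygon of the inner study area.
#' @export
inset_extent <- function(r, width) {
  b <- raster_extent(r)
  if (b["xmax"] - b["xmin"] <= 2 * width || b["ymax"] - b["ymin"] <= 2 * width)
    stop("inset width leaves an empty study area")
  rect_polygon(b["xmin"] + width, b["ymin"] + width,
               b["xmax"] - width, b["ymax"] - width)
}

focal_node_ids <- function(net, focal) {
  pts <- if (inherits(focal, "focal_nodes")) focal$points else focal
  ids <- net$node_index[cbind(pts$row, pts$col)]
  if (any(is.na(ids))) stop("a focal node falls on a NoData cell")
  ids
}

#' Accumulate current density over all focal pairs
#'
#' Solves every unordered focal pair in turn (deterministic order) and sums
#' per-cell current densities. A cell's current for one pair is half the sum
#' of the absolute currents on its incident edges; the two focal cells carry
#' the injected current, 1. Pairs whose endpoints fall in different network
#' components are skipped with a warning.
#'
#' @param graph A `conductance_graph`.
#' @param focal A `focal_nodes` object (or data frame with `row`, `col`).
#' @return A `current_map`: `grid_raster` of cumulative current density with
#'   fields `n_pairs`, `n_skipped` and `profile_id`.
#' @export
cumulative_current <- function(graph, focal) {
  ids <- focal_node_ids(graph, focal)
  if (length(unique(ids)) < 2) stop("need >= 2 distinct focal cells")
  comp <- graph$component
  pairs <- utils::combn(ids, 2)
  acc <- numeric(graph$n)
  n_pairs <- 0L; n_skipped <- 0L
  B <- node_edge_incidence(graph)
  L <- network_laplacian(graph)
  e <- graph$edges
  # one factorization per component that hosts >= 2 focal nodes
  for (cm in unique(comp[ids])) {
    in_comp <- ids[comp[ids] == cm]
    if (length(unique(in_comp)) < 2) next
    keep <- which(comp == cm)
    pos <- match(seq_len(graph$n), keep)
    ref <- keep[length(keep)]
    Lr <- L[keep, keep, drop = FALSE]
    ch <- Matrix::Cholesky(
      Matrix::forceSymmetric(Lr[-pos[ref], -pos[ref], drop = FALSE]),
      LDL = FALSE)
    red_pos <- pos
    red_pos[keep] <- ifelse(pos[keep] > pos[ref], pos[keep] - 1L, pos[keep])
    edge_in <- comp[e$i] == cm
    for (k in seq_len(ncol(pairs))) {
      s <- pairs[1, k]; gnd <- pairs[2, k]
      if (comp[s] != cm || comp[gnd] != cm) next
      b <- numeric(length(keep) - 1L)
      if (s != ref) b[red_pos[s]] <- 1
      if (gnd != ref) b[red_pos[gnd]] <- b[red_pos[gnd]] - 1
      v_red <- as.numeric(Matrix::solve(ch, b, system = "A"))
      v <- numeric(graph$n)
      v[keep[-pos[ref]]] <- v_red
      cur <- abs(e$conductance[edge_in] *
                   (v[e$i[edge_in]] - v[e$j[edge_in]]))
      contrib <- as.numeric(B[, edge_in, drop = FALSE] %*% cur) / 2
      contrib[s] <- 1; contrib[gnd] <- 1
      acc <- acc + contrib
      n_pairs <- n_pairs + 1L
    }
  }
  n_skipped <- ncol(pairs) - n_pairs
  if (n_skipped > 0)
    warning(n_skipped, " focal pair(s) skipped: endpoints in different components")
  out <- matrix(NA_real_, graph$dim[1], graph$dim[2])
  out[!is.na(graph$node_index)] <- acc[graph$node_index[!is.na(graph$node_index)]]
  r <- grid_raster(out, graph$geometry$cell_size, graph$geometry$origin,
                   graph$geometry$crs)
  class(r) <- c("current_map", class(r))
  r$n_pairs <- n_pairs
  r$n_skipped <- n_skipped
  r$profile_id <- graph$profile_id
  r
}
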