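# Independent oracles used across the suite. They deliberately avoid the
# package's own code paths: dense Moore-Penrose pseudoinverse for circuit
# solves, an explicit double-loop + hand-written BFS for the IIC, flood fill
# for patch merging, and densified boundary sampling for distances.

# Build a conductance_graph object from an explicit edge list (abstract
# graph, no raster behind it) so solve_pair can run on it.
make_abstract_graph <- function(n, edges) {
  g <- igraph::graph_from_data_frame(edges[, c("i", "j")], directed = FALSE,
                                     vertices = data.frame(name = seq_len(n)))
  comp <- unname(igraph::components(g)$membership[as.character(seq_len(n))])
  structure(list(n = n, nodes = data.frame(id = seq_len(n)), edges = edges,
                 component = comp, node_index = matrix(seq_len(n), 1, n),
                 dim = c(1L, n),
                 geometry = list(cell_size = 1, origin = c(0, 0), crs = "x"),
                 profile_id = NA_integer_),
            class = "conductance_graph")
}

random_conductance_graph <- function(n_max = 100) {
  n <- sample(5:n_max, 1)
  # random spanning tree keeps the graph connected, plus extra chords
  perm <- sample(n)
  tree <- data.frame(i = perm[-1],
                     j = perm[vapply(2:n, function(k) sample(k - 1, 1), 1L)])
  extra <- max(0, rpois(1, n / 2))
  chords <- if (extra > 0) {
    ij <- matrix(sample(n, 2 * extra, replace = TRUE), ncol = 2)
    ij <- ij[ij[, 1] != ij[, 2], , drop = FALSE]
    data.frame(i = ij[, 1], j = ij[, 2])
  } else data.frame(i = integer(0), j = integer(0))
  e <- rbind(tree, chords)
  e$conductance <- runif(nrow(e), 0.1, 10)
  make_abstract_graph(n, e)
}

dense_laplacian <- function(graph) {
  L <- matrix(0, graph$n, graph$n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[k]; j <- graph$edges$j[k]
    g <- graph$edges$conductance[k]
    L[i, j] <- L[i, j] - g
    L[j, i] <- L[j, i] - g
    L[i, i] <- L[i, i] + g
    L[j, j] <- L[j, j] + g
  }
  L
}

# Dense pseudoinverse oracle for one pair solve; voltages referenced to the
# ground node.
dense_solve_pair <- function(graph, source, ground) {
  L <- dense_laplacian(graph)
  b <- numeric(graph$n)
  b[source] <- 1
  b[ground] <- -1
  v <- MASS::ginv(L) %*% b
  as.numeric(v - v[ground])
}

kirchhoff_residual <- function(graph, voltages, source, ground) {
  L <- dense_laplacian(graph)
  v <- voltages
  v[is.na(v)] <- 0
  r <- as.numeric(L %*% v)
  r[source] <- r[source] - 1
  r[ground] <- r[ground] + 1
  max(abs(r))
}

# Explicit BFS link counts on an adjacency matrix (no igraph).
bfs_link_counts <- function(adj) {
  n <- nrow(adj)
  nl <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(adj[u, ] & is.infinite(dist))
      dist[nb] <- dist[u] + 1
      queue <- c(queue, nb)
    }
    nl[s, ] <- dist
  }
  nl
}

# Brute-force IIC: explicit double loop over ordered pairs.
brute_iic <- function(a, distmat, d, A_L) {
  adj <- distmat <= d
  diag(adj) <- FALSE
  nl <- bfs_link_counts(adj)
  num <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(a)) {
      w <- if (i == j) 1 else if (is.finite(nl[i, j])) 1 / (1 + nl[i, j]) else 0
      num <- num + a[i] * a[j] * w
    }
  }
  num / A_L^2
}

# Flood fill over an adjacency list: independent component counter.
flood_fill_components <- function(adj_list) {
  n <- length(adj_list)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[u] > 0) next
      comp[u] <- cur
      stack <- c(stack, adj_list[[u]][comp[adj_list[[u]]] == 0])
    }
  }
  comp
}

# Min distance between two polygons by densely sampling both boundaries.
densified_boundary_distance <- function(p1, p2, pts_per_edge = 60) {
  densify <- function(p) {
    n <- nrow(p)
    out <- NULL
    for (i in seq_len(n)) {
      a <- p[i, ]; b <- p[if (i == n) 1 else i + 1, ]
      t <- seq(0, 1, length.out = pts_per_edge + 1)[-(pts_per_edge + 1)]
      out <- rbind(out, cbind(a[1] + t * (b[1] - a[1]),
                              a[2] + t * (b[2] - a[2])))
    }
    out
  }
  d1 <- densify(p1); d2 <- densify(p2)
  min(sqrt(outer(d1[, 1], d2[, 1], "-")^2 + outer(d1[, 2], d2[, 2], "-")^2))
}

uniform_profile <- function(r = 1) {
  list(forest = r, grassland = r, cropland = r, waterbodies = r, unsuitable = r)
}

# Random abstract patch sets for the IIC oracle: point-like patches with
# Euclidean centre distances.
random_patch_set <- function(n_max = 50, span = 5000) {
  n <- sample(2:n_max, 1)
  xy <- matrix(runif(2 * n, 0, span), ncol = 2)
  distmat <- as.matrix(stats::dist(xy))
  list(a = runif(n, 0.1, 10), distmat = distmat)
}
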