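# Brute-force graph metrics for small graphs (<= ~8 nodes), independent of
# igraph: Floyd-Warshall shortest paths, path-enumeration betweenness,
# triangle-count clustering, Freeman centralizations and modularity.

# adjacency matrix from an edge list (two-column matrix of 1-based indices)
bf_adjacency <- function(edges, n) {
  A <- matrix(0, n, n)
  for (i in seq_len(nrow(edges))) {
    A[edges[i, 1], edges[i, 2]] <- 1
    A[edges[i, 2], edges[i, 1]] <- 1
  }
  A
}

bf_shortest_paths <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf); diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# number of shortest paths between every pair, by dynamic programming on D
bf_path_counts <- function(A, D) {
  n <- nrow(A)
  C <- matrix(0, n, n)
  ord <- order(D)  # fill in increasing distance
  for (idx in ord) {
    i <- (idx - 1) %% n + 1; j <- (idx - 1) %/% n + 1
    if (i == j || !is.finite(D[i, j])) next
    if (D[i, j] == 1) { C[i, j] <- 1; next }
    mids <- which(A[i, ] > 0 & D[, j] == D[i, j] - 1)
    C[i, j] <- sum(C[cbind(mids, j)])
  }
  C
}

# betweenness of every node: sum over pairs of fraction of shortest paths
# through the node
bf_betweenness <- function(A) {
  n <- nrow(A)
  D <- bf_shortest_paths(A)
  C <- bf_path_counts(A, D)
  b <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || s == v || t == v) next
    if (!is.finite(D[s, t]) || C[s, t] == 0) next
    if (D[s, v] + D[v, t] == D[s, t])
      b[v] <- b[v] + C[s, v] * C[v, t] / C[s, t]
  }
  b
}

bf_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    links / choose(length(nb), 2)
  }, numeric(1))
}

# all brute-force metrics on one connected small graph
bf_metrics <- function(edges, n) {
  A <- bf_adjacency(edges, n)
  D <- bf_shortest_paths(A)
  deg <- rowSums(A)
  E <- nrow(edges)
  fin <- D[lower.tri(D)][is.finite(D[lower.tri(D)])]
  btw <- bf_betweenness(A)
  # Freeman centralization, normalized by the star maximum
  deg_centr <- sum(max(deg) - deg) / ((n - 1) * (n - 2))
  btw_max <- (n - 1)^2 * (n - 2) / 2        # star hub betweenness times (n-1)
  btw_centr <- sum(max(btw) - btw) / btw_max
  list(average_degree = 2 * E / n,
       density = 2 * E / (n * (n - 1)),
       average_clustering_coefficient = mean(bf_clustering(A)),
       diameter = max(fin),
       average_path_length = mean(fin),
       degree_centralization = deg_centr,
       betweenness_centralization = btw_centr)
}

# modularity of a given partition: Q = sum_c (e_cc - a_c^2)
bf_modularity <- function(edges, n, membership) {
  E <- nrow(edges)
  comms <- unique(membership)
  Q <- 0
  for (cc in comms) {
    inside <- sum(membership[edges[, 1]] == cc & membership[edges[, 2]] == cc)
    dsum <- sum(vapply(which(membership == cc), function(v)
      sum(edges == v), numeric(1)))
    Q <- Q + inside / E - (dsum / (2 * E))^2
  }
  Q
}

# igraph network from an index edge list, with rho/q attributes so it mimics
# build_network() output
toy_network <- function(edges, n, rho = 0.9, q = 0.001) {
  df <- data.frame(otu1 = paste0("v", edges[, 1]),
                   otu2 = paste0("v", edges[, 2]),
                   rho = rho, q = q)
  igraph::graph_from_data_frame(df, directed = FALSE,
    vertices = data.frame(name = paste0("v", seq_len(n))))
}
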