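# Independent oracles, deliberately naive: used only to check the package's
# efficient implementations on small inputs.

# Distribution of the overlap between a fixed set of n1 sites and every
# possible placement of n2 sites among n, by exhaustive enumeration.
# Returns P(overlap = j) for j = 0..min(n1, n2).
enum_overlap_dist <- function(n, n1, n2) {
  placements <- utils::combn(n, n2)
  overlaps <- apply(placements, 2, function(s) sum(s <= n1))
  vapply(0:min(n1, n2), function(j) mean(overlaps == j), numeric(1))
}

# Geodesic distances and counts from the adjacency matrix alone, via matrix
# powers: (A^k)[s, t] counts walks of length k, and every walk whose length
# equals the geodesic distance is a shortest path.
power_paths <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  count <- diag(n)
  pow <- diag(n)
  for (k in seq_len(n - 1)) {
    pow <- pow %*% adj
    new <- is.infinite(dist) & pow > 0
    dist[new] <- k
    count[new] <- pow[new]
  }
  list(dist = dist, count = count)
}

# Unnormalized betweenness over unordered pairs, fractional credit on ties.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  pp <- power_paths(adj)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (is.infinite(pp$dist[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (pp$dist[s, v] + pp$dist[v, t] == pp$dist[s, t]) {
        btw[v] <- btw[v] + pp$count[s, v] * pp$count[v, t] / pp$count[s, t]
      }
    }
  }
  btw
}

# Newman-Girvan modularity straight from its definition.
direct_modularity <- function(adj, membership) {
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  q <- 0
  for (c in unique(membership)) {
    in_c <- membership == c
    e_c <- sum(adj[in_c, in_c, drop = FALSE]) / 2
    k_c <- sum(deg[in_c])
    q <- q + e_c / m - (k_c / (2 * m))^2
  }
  q
}

# Small labelled incidence matrix built from a plain 0/1 vector.
make_incidence <- function(values, n_samples, taxa) {
  incidence_matrix(matrix(values, nrow = n_samples,
                          dimnames = list(paste0("s", seq_len(n_samples)),
                                          taxa)))
}

# Random adjacency matrix of a simple undirected graph.
random_adjacency <- function(n, p = 0.4) {
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  adj + t(adj)
}

# Wrap an adjacency matrix as the package's network object.
adjacency_network <- function(adj) {
  dimnames(adj) <- list(paste0("t", seq_len(nrow(adj))),
                        paste0("t", seq_len(nrow(adj))))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  structure(list(graph = g,
                 edges = as.data.frame(igraph::as_edgelist(g)),
                 min_shared_samples = 1),
            class = "cooccur_network")
}
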