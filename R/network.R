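#' Build a taxon co-occurrence network
#'
#' Nodes are taxa; two taxa are joined by an (unweighted, undirected) edge
#' when they co-occur in at least \code{min_shared_samples} samples. All
#' taxa appear as nodes, including isolated ones. The number of shared
#' samples is retained as an edge attribute for export, but the metrics are
#' computed on the unweighted simple graph.
#'
#' @param x an \code{\link{incidence_matrix}} (or coercible matrix).
#' @param min_shared_samples minimum number of shared samples for an edge
#'   (default 1).
#' @return an object of class \code{cooccur_network} with components
#'   \code{graph} (an igraph object), \code{edges} (data frame
#'   \code{taxon_a}, \code{taxon_b}, \code{shared_samples}) and
#'   \code{min_shared_samples}.
#' @examples
#' fx <- study_fixture(seed = 1)
#' net <- build_network(fx$matrix)
#' net
#' @export
build_network <- function(x, min_shared_samples = 1) {
  x <- incidence_matrix(x)
  if (min_shared_samples < 1) stop("min_shared_samples must be >= 1")
  shared <- crossprod(unclass(x))
  adj <- (shared >= min_shared_samples) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  el <- igraph::as_edgelist(g)
  edges <- data.frame(
    taxon_a = el[, 1], taxon_b = el[, 2],
    shared_samples = shared[cbind(el[, 1], el[, 2])],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(graph = g, edges = edges,
                 min_shared_samples = min_shared_samples),
            class = "cooccur_network")
}

#' @export
print.cooccur_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf("Co-occurrence network: %d taxa, %d edges (>= %d shared sample%s)\n",
              igraph::vcount(g), igraph::ecount(g), x$min_shared_samples,
              if (x$min_shared_samples == 1) "" else "s"))
  if (igraph::vcount(g) >= 2) {
    cat(sprintf("  density %.3f, %d connected component%s\n",
                net_density(x), igraph::count_components(g),
                if (igraph::count_components(g) == 1) "" else "s"))
  }
  invisible(x)
}

as_graph <- function(net) {
  if (inherits(net, "cooccur_network")) net$graph
  else if (inherits(net, "igraph")) net
  else stop("expected a cooccur_network or igraph object")
}

#' Node degree
#'
#' Number of direct connections (edges) each taxon has in the network.
#'
#' @param net a \code{\link{build_network}} result.
#' @return named integer vector of degrees.
#' @export
net_degree <- function(net) {
  d <- igraph::degree(as_graph(net))
  storage.mode(d) <- "integer"
  d
}

#' Betweenness centrality
#'
#' How often a taxon lies on shortest paths between other taxa: for node v,
#' the sum over unordered pairs \{s, t\} of the fraction of s-t geodesics
#' passing through v. Unweighted and unnormalized; all tied geodesics
#' receive fractional credit.
#'
#' @param net a \code{\link{build_network}} result.
#' @return named numeric vector of betweenness values.
#' @export
net_betweenness <- function(net) {
  igraph::betweenness(as_graph(net), directed = FALSE, normalized = FALSE)
}

#' Edge density
#'
#' Proportion of realized edges among the \eqn{n(n-1)/2} possible ones.
#'
#' @param net a \code{\link{build_network}} result.
#' @return density in [0, 1].
#' @export
net_density <- function(net) {
  g <- as_graph(net)
  if (igraph::vcount(g) < 2) stop("density needs at least 2 nodes")
  igraph::edge_density(g)
}

#' Connected components ("clusters")
#'
#' Maximal sets of mutually reachable taxa, plus the number of modules with
#' more than two members.
#'
#' @param net a \code{\link{build_network}} result.
#' @return list with \code{membership} (named integer vector of component
#'   labels), \code{sizes}, \code{n_components} and \code{n_large_modules}
#'   (components with > 2 nodes).
#' @export
net_components <- function(net) {
  cl <- igraph::components(as_graph(net))
  list(membership = cl$membership,
       sizes = as.integer(cl$csize),
       n_components = cl$no,
       n_large_modules = sum(cl$csize > 2L))
}

#' Newman-Girvan modularity of a community partition
#'
#' \deqn{Q = \sum_c \left[\frac{e_c}{m} - \left(\frac{k_c}{2m}\right)^2\right]}
#' where m is the number of edges, e_c the edges within community c and k_c
#' its total degree. Q is 0 whenever all nodes share one community, and is
#' undefined on an edgeless graph.
#'
#' @param net a \code{\link{build_network}} result.
#' @param membership community labels, one per node (any vector; matched by
#'   node name if named). Defaults to the connected-component partition.
#' @return modularity Q.
#' @export
net_modularity <- function(net, membership = NULL) {
  g <- as_graph(net)
  if (igraph::ecount(g) == 0) stop("modularity is undefined on an edgeless graph")
  membership <- resolve_membership(g, membership)
  igraph::modularity(g, membership)
}

resolve_membership <- function(g, membership) {
  if (is.null(membership)) {
    return(igraph::components(g)$membership)
  }
  if (length(membership) != igraph::vcount(g)) {
    stop("membership must assign a label to every node")
  }
  nm <- igraph::V(g)$name
  if (!is.null(names(membership)) && !is.null(nm)) {
    if (!setequal(names(membership), nm)) {
      stop("membership names do not match node names")
    }
    membership <- membership[nm]
  }
  as.integer(factor(membership))
}

#' Permutation test for network modularity
#'
#' Shuffles the multiset of community labels uniformly at random
#' \code{n_permutations} times, recomputes modularity for each shuffle, and
#' reports the proportion of permuted values greater than or equal to the
#' observed modularity. With all labels identical every shuffle reproduces
#' the observed partition and the p-value is 1.
#'
#' @param net a \code{\link{build_network}} result.
#' @param membership community labels (default: connected components).
#' @param n_permutations number of label shuffles (default 1000).
#' @param seed RNG seed for reproducibility; recorded in the result.
#' @return object of class \code{modularity_perm}: \code{observed_modularity},
#'   \code{n_permutations}, \code{p_value}, \code{seed},
#'   \code{permuted_summary} (min/mean/max) and \code{permuted} (the full
#'   null distribution).
#' @examples
#' fx <- study_fixture(seed = 1)
#' net <- build_network(fx$matrix)
#' modularity_permutation_test(net, n_permutations = 100, seed = 42)
#' @export
modularity_permutation_test <- function(net, membership = NULL,
                                        n_permutations = 1000, seed = NULL) {
  g <- as_graph(net)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  membership <- resolve_membership(g, membership)
  q_obs <- net_modularity(net, membership)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  q_perm <- vapply(seq_len(n_permutations), function(i) {
    igraph::modularity(g, sample(membership))
  }, numeric(1))
  # tolerance guards floating-point ties between identical partitions
  p <- mean(q_perm >= q_obs - 1e-10)
  structure(list(observed_modularity = q_obs,
                 n_permutations = n_permutations,
                 p_value = p,
                 seed = seed,
                 permuted_summary = c(min = min(q_perm), mean = mean(q_perm),
                                      max = max(q_perm)),
                 permuted = q_perm),
            class = "modularity_perm")
}

#' @export
print.modularity_perm <- function(x, ...) {
  cat("Modularity permutation test\n")
  cat(sprintf("  observed Q = %.4f, %d shuffles, p = %.4f\n",
              x$observed_modularity, x$n_permutations, x$p_value))
  cat(sprintf("  permuted Q: min %.4f, mean %.4f, max %.4f\n",
              x$permuted_summary[["min"]], x$permuted_summary[["mean"]],
              x$permuted_summary[["max"]]))
  if (!is.null(x$seed)) cat(sprintf("  seed: %s\n", format(x$seed)))
  invisible(x)
}

#' Per-node and graph-level network metrics
#'
#' Convenience wrapper computing degree, betweenness, density, components
#' and the modularity of the component partition in one pass.
#'
#' @param net a \code{\link{build_network}} result.
#' @param metadata optional taxon metadata (columns \code{taxon_id},
#'   \code{phylum}, \code{family}); phylum is joined onto the node table.
#' @return object of class \code{network_metrics}: \code{nodes} (data frame
#'   taxon, [phylum,] degree, betweenness), \code{density},
#'   \code{n_components}, \code{n_large_modules}, \code{modularity}
#'   (NA on an edgeless graph).
#' @export
network_metrics <- function(net, metadata = NULL) {
  g <- as_graph(net)
  deg <- net_degree(net)
  btw <- net_betweenness(net)
  comp <- net_components(net)
  nodes <- data.frame(taxon = names(deg), degree = as.integer(deg),
                      betweenness = as.numeric(btw),
                      row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    nodes$phylum <- metadata$phylum[match(nodes$taxon, metadata$taxon_id)]
    nodes <- nodes[, c("taxon", "phylum", "degree", "betweenness")]
  }
  q <- if (igraph::ecount(g) > 0) net_modularity(net, comp$membership) else NA_real_
  structure(list(nodes = nodes,
                 density = if (igraph::vcount(g) >= 2) net_density(net) else NA_real_,
                 n_components = comp$n_components,
                 n_large_modules = comp$n_large_modules,
                 modularity = q),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("Network metrics: %d nodes, density %.3f, %d component%s (%d with > 2 taxa)\n",
              nrow(x$nodes), x$density, x$n_components,
              if (x$n_components == 1) "" else "s", x$n_large_modules))
  cat(sprintf("  modularity of component partition: %s\n",
              format(x$modularity)))
  top <- x$nodes[order(-x$nodes$degree), ][seq_len(min(5, nrow(x$nodes))), ]
  cat("  highest-degree taxa:\n")
  print(top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Export the network edge list as CSV/TSV
#'
#' Columns \code{taxon_a}, \code{taxon_b}, \code{shared_samples}.
#'
#' @param net a \code{\link{build_network}} result.
#' @param path output file path.
#' @param sep field delimiter.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(net, path, sep = ",") {
  stopifnot(inherits(net, "cooccur_network"))
  utils::write.table(net$edges, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export the network in GML format
#'
#' @param net a \code{\link{build_network}} result.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_network_gml <- function(net, path) {
  stopifnot(inherits(net, "cooccur_network"))
  g <- net$graph
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    igraph::E(g)$shared_samples <- net$edges$shared_samples[
      match(paste(el[, 1], el[, 2]),
            paste(net$edges$taxon_a, net$edges$taxon_b))]
  }
  igraph::write_graph(g, path, format = "gml")
  invisible(path)
}
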