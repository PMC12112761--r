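test_that("network edges follow the shared-sample rule", {
  # A and B share sample 1; C never co-occurs
  m <- make_incidence(c(1, 0, 1, 0, 0, 1), 2, c("A", "B", "C"))
  net <- build_network(m)
  expect_identical(sort(igraph::V(net$graph)$name), c("A", "B", "C"))
  expect_identical(nrow(net$edges), 1L)
  expect_setequal(unlist(net$edges[1, c("taxon_a", "taxon_b")]), c("A", "B"))
  expect_identical(net$edges$shared_samples[1], 1)
  expect_error(build_network(m, min_shared_samples = 0), ">= 1")

  # raising the threshold drops weak edges
  m2 <- make_incidence(c(1, 1, 1, 1, 1, 0), 3, c("A", "B"))
  expect_identical(nrow(build_network(m2, 3)$edges), 0L)
  expect_identical(nrow(build_network(m2, 2)$edges), 1L)

  # the study-shaped fixture keeps all 23 taxa as nodes
  fx <- study_fixture(seed = 4)
  expect_identical(igraph::vcount(build_network(fx$matrix)$graph), 23)
})

test_that("degree and density obey the handshake lemma", {
  k4 <- adjacency_network(matrix(1, 4, 4) - diag(4))
  expect_identical(unname(net_degree(k4)), rep(3L, 4))
  expect_equal(net_density(k4), 1)

  path3 <- adjacency_network(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_identical(unname(net_degree(path3)), c(1L, 2L, 1L))

  empty <- adjacency_network(matrix(0, 3, 3))
  expect_equal(net_density(empty), 0)

  set.seed(10)
  for (rep in 1:10) {
    adj <- random_adjacency(sample(3:9, 1))
    net <- adjacency_network(adj)
    deg <- net_degree(net)
    expect_identical(sum(deg), 2L * nrow(net$edges))
    n <- nrow(adj)
    expect_equal(net_density(net), sum(deg) / (n * (n - 1)))
  }
})

test_that("betweenness matches brute-force geodesic counting", {
  path3 <- adjacency_network(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(unname(net_betweenness(path3)), c(0, 1, 0))

  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  expect_equal(unname(net_betweenness(adjacency_network(star))), c(3, 0, 0, 0))

  cycle4 <- matrix(0, 4, 4)
  cycle4[cbind(1:4, c(2, 3, 4, 1))] <- 1
  cycle4 <- cycle4 + t(cycle4)
  expect_equal(unname(net_betweenness(adjacency_network(cycle4))),
               rep(0.5, 4))

  set.seed(21)
  for (rep in 1:30) {
    adj <- random_adjacency(sample(4:8, 1), p = runif(1, 0.2, 0.8))
    expect_equal(unname(net_betweenness(adjacency_network(adj))),
                 brute_betweenness(adj), tolerance = 1e-10)
  }
})

test_that("components and large modules are counted correctly", {
  two_edges <- matrix(0, 4, 4)
  two_edges[1, 2] <- two_edges[2, 1] <- 1
  two_edges[3, 4] <- two_edges[4, 3] <- 1
  comp <- net_components(adjacency_network(two_edges))
  expect_identical(comp$n_components, 2)
  expect_identical(comp$n_large_modules, 0L)

  triangle_plus_isolate <- matrix(0, 4, 4)
  triangle_plus_isolate[1:3, 1:3] <- 1 - diag(3)
  comp2 <- net_components(adjacency_network(triangle_plus_isolate))
  expect_identical(comp2$n_components, 2)
  expect_identical(comp2$n_large_modules, 1L)
  expect_identical(sort(comp2$sizes), c(1L, 3L))
})

test_that("modularity matches its definition and is 0 for one community", {
  two_edges <- matrix(0, 4, 4)
  two_edges[1, 2] <- two_edges[2, 1] <- 1
  two_edges[3, 4] <- two_edges[4, 3] <- 1
  net <- adjacency_network(two_edges)
  expect_equal(net_modularity(net, c(1, 1, 2, 2)), 0.5)
  expect_equal(net_modularity(net, c(1, 2, 1, 2)), -0.5)
  expect_equal(net_modularity(net, rep(1, 4)), 0)
  # default membership: connected components
  expect_equal(net_modularity(net), 0.5)
  expect_error(net_modularity(adjacency_network(matrix(0, 3, 3))),
               "edgeless")
  expect_error(net_modularity(net, c(1, 2)), "every node")

  set.seed(33)
  for (rep in 1:15) {
    adj <- random_adjacency(sample(4:9, 1))
    if (sum(adj) == 0) next
    net_r <- adjacency_network(adj)
    membership <- sample(1:3, nrow(adj), replace = TRUE)
    expect_equal(net_modularity(net_r, membership),
                 direct_modularity(adj, membership), tolerance = 1e-12)
    expect_equal(net_modularity(net_r, rep(1, nrow(adj))), 0)
  }
})

test_that("permutation test reproduces analytic shuffle probabilities", {
  two_edges <- matrix(0, 4, 4)
  two_edges[1, 2] <- two_edges[2, 1] <- 1
  two_edges[3, 4] <- two_edges[4, 3] <- 1
  net <- adjacency_network(two_edges)

  # all-equal labels: every shuffle reproduces the partition, p = 1
  res <- modularity_permutation_test(net, membership = rep(1, 4),
                                     n_permutations = 1000, seed = 5)
  expect_identical(res$p_value, 1)
  expect_equal(res$observed_modularity, 0)
  expect_equal(unname(res$permuted_summary), c(0, 0, 0))

  # perfect 2-community labels on two disjoint edges: 2 of the 6 distinct
  # arrangements reproduce Q = 0.5, the rest fall below
  res2 <- modularity_permutation_test(net, membership = c(1, 1, 2, 2),
                                      n_permutations = 2000, seed = 8)
  expect_equal(res2$observed_modularity, 0.5)
  expect_equal(res2$p_value, 1 / 3, tolerance = 0.05)

  # determinism under a fixed seed
  resA <- modularity_permutation_test(net, membership = c(1, 1, 2, 2),
                                      n_permutations = 200, seed = 99)
  resB <- modularity_permutation_test(net, membership = c(1, 1, 2, 2),
                                      n_permutations = 200, seed = 99)
  expect_identical(resA$permuted, resB$permuted)
  expect_identical(resA$p_value, resB$p_value)
  expect_error(modularity_permutation_test(net, n_permutations = 0), ">= 1")
})

test_that("metrics bundle and exports are consistent", {
  fx <- study_fixture(seed = 6)
  net <- build_network(fx$matrix)
  metrics <- network_metrics(net, metadata = fx$metadata)
  expect_identical(nrow(metrics$nodes), 23L)
  expect_identical(names(metrics$nodes),
                   c("taxon", "phylum", "degree", "betweenness"))
  expect_identical(unname(metrics$nodes$degree),
                   unname(as.integer(net_degree(net))))
  expect_equal(metrics$density, net_density(net))

  edge_path <- tempfile(fileext = ".csv")
  write_edge_list(net, edge_path)
  edges <- utils::read.csv(edge_path)
  expect_identical(nrow(edges), nrow(net$edges))
  expect_true(all(edges$shared_samples >= 1))

  gml_path <- tempfile(fileext = ".gml")
  write_network_gml(net, gml_path)
  reread <- igraph::read_graph(gml_path, format = "gml")
  expect_identical(igraph::vcount(reread), 23)
  expect_identical(igraph::ecount(reread), igraph::ecount(net$graph))
})
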