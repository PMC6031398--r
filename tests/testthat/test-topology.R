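test_that("clustering coefficient matches hand counts", {
  k3 <- graph_from_adj(random_graph(3, p_edge = 1.1, seed = 1))
  expect_equal(global_metrics(k3)$clustering_coefficient, 1)
  path3 <- igraph::make_graph(~ a - b, b - c)
  expect_equal(global_metrics(path3)$clustering_coefficient, 0)
  # K4 minus one edge: the two degree-2 nodes close their single triangle
  # (C = 1); each degree-3 node sits on 2 of its 3 neighbour pairs
  # (C = 2/3), so the average is (1 + 1 + 2/3 + 2/3) / 4 = 5/6
  adj <- matrix(1, 4, 4) - diag(4)
  adj[1, 2] <- adj[2, 1] <- 0
  expect_equal(global_metrics(graph_from_adj(adj))$clustering_coefficient,
               5 / 6, tolerance = 1e-12)
})

test_that("modularity formula: single community gives zero", {
  for (s in 1:5) {
    g <- graph_from_adj(random_graph(8, 0.4, seed = s))
    expect_equal(modularity_q(g, rep(1, 8)), 0, tolerance = 1e-12)
  }
})

test_that("fast greedy finds the two-triangle partition with Q = 5/14", {
  g <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d, a - d)
  mod <- fast_greedy_modules(g)
  expect_equal(mod$n_modules, 2)
  expect_equal(mod$Q, 5 / 14, tolerance = 1e-9)
  expect_equal(modularity_q(g, mod$membership), mod$Q, tolerance = 1e-12)
})

test_that("ring of cliques resolves into its cliques", {
  n_cl <- 4; k <- 5
  el <- NULL
  for (c0 in 0:(n_cl - 1)) {
    v <- c0 * k + 1:k
    el <- rbind(el, t(combn(v, 2)))
  }
  for (c0 in 0:(n_cl - 1))
    el <- rbind(el, c(c0 * k + 1, ((c0 + 1) %% n_cl) * k + 2))
  g <- igraph::graph_from_edgelist(apply(el, 2, as.character),
                                   directed = FALSE)
  mod <- fast_greedy_modules(g)
  expect_equal(mod$n_modules, 4)
  expect_gt(mod$Q, 0.4)
})

test_that("fast-greedy Q never exceeds the exhaustive optimum", {
  for (s in 1:6) {
    adj <- random_graph(7, 0.35, seed = 100 + s)
    if (sum(adj) == 0) next
    g <- graph_from_adj(adj)
    mod <- fast_greedy_modules(g)
    expect_lte(mod$Q, brute_best_modularity(adj) + 1e-9)
  }
})

test_that("centralities match closed forms on path and star", {
  path3 <- igraph::make_graph(~ a - b, b - c)
  ct <- centralities(path3)
  expect_equal(ct["b", "betweenness"], 1)
  expect_equal(ct["a", "betweenness"], 0)
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3")
  cs <- centralities(star)
  expect_equal(cs["hub", "closeness"], 1)
  expect_equal(cs["l1", "closeness"], 3 / 5)
})

test_that("centralities agree with brute force on random graphs", {
  for (s in 1:15) {
    adj <- random_graph(sample(6:12, 1), 0.3, seed = 300 + s)
    g <- graph_from_adj(adj)
    ct <- centralities(g)
    expect_equal(ct$betweenness, brute_betweenness(adj), tolerance = 1e-9)
    expect_equal(ct$closeness, brute_closeness(adj), tolerance = 1e-9)
  }
})

test_that("keystones rank by betweenness/closeness rank-sum", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("l", 1:5))
  ks <- keystones(star, top_k = 3)
  expect_equal(ks$node[1], "hub")
  # barbell: two K4 joined by a path through two bridge nodes
  g <- igraph::make_graph(~ a-b, a-c, a-d, b-c, b-d, c-d,
                          e-f, e-g, e-h, f-g, f-h, g-h,
                          d-x, x-y, y-e)
  ksb <- keystones(g, top_k = 2)
  expect_setequal(ksb$node, c("x", "y"))
  small <- igraph::make_graph(~ a - b)
  expect_warning(ka <- keystones(small, top_k = 5), "top_k")
  expect_equal(nrow(ka), 2)
})

test_that("abundance plays no role in keystone identification", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("rarehub", paste0("l", 1:4))
  igraph::V(star)$mean_rel_abundance <- c(0.001, 0.3, 0.3, 0.2, 0.199)
  ks <- keystones(star, top_k = 1)
  expect_equal(ks$node, "rarehub")
  expect_lt(ks$mean_rel_abundance, 0.01)
})

test_that("same-phylum co-presence counts positive classified edges only", {
  el <- rbind(c("a", "b"), c("a", "c"), c("b", "d"), c("c", "d"), c("a", "d"))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$sign <- c("+", "+", "+", "+", "-")
  igraph::V(g)$phylum <- c("P1", "P1", "P2", "P2")
  # positive edges: ab (same P1), ac (diff), bd (diff), cd (same P2) -> 2/4
  sp <- same_phylum_fraction(g)
  expect_equal(sp$fraction, 0.5)
  expect_equal(sp$n_positive_classified, 4)
  # adding a negative edge never changes the fraction (a-d is negative)
  g2 <- igraph::delete_edges(g, 5)
  expect_equal(same_phylum_fraction(g2)$fraction, 0.5)
  # unclassified endpoints leave the denominator
  igraph::V(g)$phylum <- c("P1", "unclassified", "P2", "P2")
  sp3 <- same_phylum_fraction(g)
  expect_equal(sp3$n_excluded_unclassified, 2)
  expect_equal(sp3$fraction, 0.5)  # ac diff, cd same
})

test_that("network comparison flags fragmentation orderings", {
  mk <- function(nmod, q) {
    r <- list(n_nodes = 10, n_edges = 12, n_positive = 10,
              clustering_coefficient = 0.2, Q = q, n_modules = nmod,
              same_phylum = list(fraction = 0.3))
    class(r) <- "topology_report"
    r
  }
  cmp <- compare_networks(mk(39, 0.81), mk(27, 0.74),
                          labels = c("river", "tribs"))
  expect_equal(cmp$more_fragmented, "river")
  expect_equal(compare_networks(mk(5, 0.5), mk(5, 0.5))$more_fragmented,
               "equal")
  expect_equal(compare_networks(mk(9, 0.5), mk(5, 0.6))$more_fragmented,
               "inconclusive")
})

test_that("topology report is internally consistent", {
  sim <- generate_community(synthetic_spec(
    n_core = 16, n_tail = 20, n_blocks = 3, block_size = 4,
    n_exclusion = 0, seed = 55))
  rar <- rarefy_table(sim$table, "min", seed = 2)
  prev <- filter_prevalence(filter_low_abundance(rar))
  nw <- infer_network(prev, sim$taxonomy, B = 40, top_n = 40, seed = 5)
  tr <- topology_report(nw$network, sim$taxonomy)
  expect_lte(tr$n_positive, tr$n_edges)
  expect_equal(tr$Q, modularity_q(nw$network, tr$membership),
               tolerance = 1e-9)
  expect_equal(length(tr$membership), tr$n_nodes)
})
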