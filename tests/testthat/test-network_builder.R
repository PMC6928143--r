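test_that("a clique of eligible molecules lands in a single network", {
  cl <- utils::combn(sprintf("C%d", 1:5), 2)
  edges <- data.frame(from = cl[1, ], to = cl[2, ], relation = "direct")
  g <- interaction_graph(edges)
  nets <- build_networks(sprintf("C%d", 1:5), g, max_size = 35)
  expect_length(nets, 1)
  expect_true(all(sprintf("C%d", 1:5) %in% nets[[1]]$nodes))
})

test_that("disconnected components produce separate networks", {
  edges <- data.frame(from = c("A1", "A2", "B1", "B2"),
                      to = c("A2", "A3", "B2", "B3"),
                      relation = "direct")
  g <- interaction_graph(edges)
  nets <- build_networks(c("A1", "B1"), g, max_size = 35)
  expect_gte(length(nets), 2)
  comp_a <- c("A1", "A2", "A3")
  for (net in nets) {
    expect_true(all(net$nodes %in% comp_a) || !any(net$nodes %in% comp_a))
  }
})

test_that("greedy growth matches an independent naive re-implementation", {
  for (seed in c(3, 17, 29, 41)) {
    edges <- random_edge_table(12, 0.3, seed = seed)
    g <- interaction_graph(edges)
    nodes <- graph_nodes_for_test(g)
    eligible <- sort(sample(nodes, 4))
    got <- build_networks(eligible, g, max_size = 35)
    want <- naive_build_networks(eligible, edges, max_size = 35)
    expect_equal(lapply(got, `[[`, "nodes"), want,
                 info = sprintf("seed %d", seed))
  }
  # small cap exercises truncation
  edges <- random_edge_table(15, 0.25, seed = 5)
  g <- interaction_graph(edges)
  eligible <- graph_nodes_for_test(g)[c(1, 4, 8, 11)]
  got <- build_networks(eligible, g, max_size = 6)
  want <- naive_build_networks(eligible, edges, max_size = 6)
  expect_equal(lapply(got, `[[`, "nodes"), want)
})

test_that("networks respect the size cap, connectivity and eligible partition", {
  for (seed in c(2, 9, 23)) {
    edges <- random_edge_table(25, 0.12, seed = seed)
    g <- interaction_graph(edges)
    nodes <- graph_nodes_for_test(g)
    eligible <- sample(nodes, 10)
    nets <- build_networks(eligible, g, max_size = 8)
    seen_elig <- character(0)
    for (net in nets) {
      expect_lte(length(net$nodes), 8)
      expect_true(all(net$eligible_nodes %in% net$nodes))
      sub <- igraph::induced_subgraph(g$igraph, net$nodes)
      expect_true(igraph::is_connected(sub))
      expect_length(intersect(net$eligible_nodes, seen_elig), 0)
      seen_elig <- c(seen_elig, net$eligible_nodes)
    }
    expect_setequal(seen_elig, intersect(eligible, nodes))
  }
})

test_that("network construction is deterministic", {
  edges <- random_edge_table(20, 0.2, seed = 13)
  g <- interaction_graph(edges)
  eligible <- graph_nodes_for_test(g)[seq(1, 20, by = 3)]
  expect_identical(build_networks(eligible, g, max_size = 10),
                   build_networks(eligible, g, max_size = 10))
  expect_error(build_networks(eligible, g, max_size = 1), ">= 2")
})

test_that("score_network applies the -log10 overlap tail", {
  universe <- sprintf("S%02d", 1:10)
  pws <- list(P = list(name = "P", members = universe[1:3],
                       cancer_related = FALSE, panel_label = NA_character_))
  g <- interaction_graph(data.frame(from = universe[1], to = universe[2],
                                    relation = "direct"))
  kb <- knowledge_base(g, pws, universe = universe)

  eligible <- universe[1:5]
  net <- molecular_network(1, nodes = universe[1:5],
                           eligible_nodes = universe[1:5])
  scored <- score_network(net, eligible, kb)
  # k=5, K=5, n=5, N=10 -> p = 1/252
  expect_equal(scored$score, -log10(enum_hyper_tail(5, 5, 5, 10)),
               tolerance = 1e-10)
  expect_equal(round(scored$score, 3), 2.401)

  none <- molecular_network(2, nodes = universe[6:8],
                            eligible_nodes = character(0))
  expect_equal(score_network(none, universe[9], kb)$score, 0)
  expect_gte(score_network(none, universe[6], kb)$score, 0)
})

test_that("extract_hubs applies the induced-degree threshold", {
  star <- data.frame(from = "HUB", to = sprintf("L%d", 1:5), relation = "direct")
  g <- interaction_graph(star)
  net <- molecular_network(1, nodes = c("HUB", sprintf("L%d", 1:5)),
                           eligible_nodes = "HUB")
  hubs <- extract_hubs(net, g, min_links = 5)
  expect_equal(hubs$identifier, "HUB")
  expect_equal(hubs$degree, 5L)

  ring <- data.frame(from = sprintf("R%d", 1:6),
                     to = sprintf("R%d", c(2:6, 1)), relation = "indirect")
  g2 <- interaction_graph(ring)
  net2 <- molecular_network(1, nodes = sprintf("R%d", 1:6),
                            eligible_nodes = character(0))
  expect_equal(nrow(extract_hubs(net2, g2)), 0)
  expect_error(extract_hubs(net2, g2, min_links = 0), ">= 1")
})

test_that("extract_hubs equals brute-force degree filtering on random subgraphs", {
  for (seed in c(4, 12, 31, 57)) {
    edges <- random_edge_table(25, 0.25, seed = seed)
    g <- interaction_graph(edges)
    nodes <- graph_nodes_for_test(g)
    members <- sort(sample(nodes, 15))
    net <- molecular_network(1, nodes = members, eligible_nodes = character(0))
    for (min_links in c(2, 5)) {
      got <- extract_hubs(net, g, min_links = min_links)
      expect_setequal(got$identifier, brute_hubs(edges, members, min_links))
      expect_true(all(diff(got$degree) <= 0))
    }
  }
})

test_that("coverage_percent rounds half away from zero", {
  net_of <- function(k, n) molecular_network(
    1, nodes = sprintf("N%02d", 1:n),
    eligible_nodes = if (k > 0) sprintf("N%02d", 1:k) else character(0))
  expect_equal(coverage_percent(net_of(23, 35)), 66L)
  expect_equal(coverage_percent(net_of(18, 35)), 51L)
  expect_equal(coverage_percent(net_of(0, 35)), 0L)
  expect_equal(coverage_percent(net_of(1, 8)), 13L)  # 12.5 rounds up
})
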