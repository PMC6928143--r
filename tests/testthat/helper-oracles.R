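# Independent brute-force oracles and toy-data builders used across tests.
# These deliberately avoid the package's own code paths.

# P(X >= k) by exhaustive enumeration of all C(N, n) draws (N <= 12 or so)
enum_hyper_tail <- function(k, K, n, N) {
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d %in% marked) >= k)
  mean(hits)
}

# step-up BH from the definition: p(i) * m / i with cumulative minimum
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# per-node degree by scanning an edge data.frame (from, to)
scan_degrees <- function(edges, nodes) {
  vapply(nodes, function(v) sum(edges$from == v) + sum(edges$to == v),
         integer(1))
}

# brute-force hub filter on the induced subgraph of `members`
brute_hubs <- function(edges, members, min_links = 5) {
  sub <- edges[edges$from %in% members & edges$to %in% members, , drop = FALSE]
  deg <- scan_degrees(sub, members)
  sort(members[deg >= min_links])
}

# exhaustive target-decoy cutoff scan (all distinct scores as cutoffs)
exhaustive_fdr_cutoff <- function(scores, is_decoy, alpha) {
  best <- NULL
  for (cut in sort(unique(scores), decreasing = TRUE)) {
    acc <- scores >= cut
    nt <- sum(acc & !is_decoy)
    if (nt == 0) next
    if (sum(acc & is_decoy) / nt <= alpha) best <- cut
  }
  best
}

# literal step-by-step re-implementation of the documented greedy growth,
# kept naive (recomputes everything from scratch each step)
naive_build_networks <- function(eligible, edges, max_size = 35) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  deg <- scan_degrees(edges, nodes)
  names(deg) <- nodes
  nbr <- function(v) {
    sort(unique(c(edges$to[edges$from == v], edges$from[edges$to == v])))
  }
  unassigned <- sort(intersect(eligible, nodes))
  nets <- list()
  while (length(unassigned) > 0) {
    pool_deg <- deg[unassigned]
    seed <- sort(unassigned[pool_deg == max(pool_deg)])[1]
    members <- seed
    repeat {
      if (length(members) >= max_size) break
      cand <- setdiff(unique(unlist(lapply(members, nbr))), members)
      # assigned eligible nodes are consumed
      consumed <- setdiff(eligible, unassigned)
      cand <- setdiff(cand, consumed)
      if (length(cand) == 0) break
      gain <- vapply(cand, function(c) {
        length(intersect(nbr(c), intersect(members, eligible)))
      }, integer(1))
      best <- cand[order(-gain, -deg[cand], cand)][1]
      members <- c(members, best)
    }
    nets[[length(nets) + 1L]] <- sort(members)
    unassigned <- setdiff(unassigned, members)
  }
  nets
}

# random undirected simple graph as an edge table + loaded interaction_graph
random_edge_table <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  data.frame(from = pairs[1, keep], to = pairs[2, keep],
             relation = sample(c("direct", "indirect"), sum(keep),
                               replace = TRUE),
             stringsAsFactors = FALSE)
}

# tiny knowledge base: 3 disjoint pathways over a 12-gene universe plus a
# path graph for interactions
toy_kb <- function() {
  genes <- sprintf("T%02d", 1:12)
  pathways <- list(
    PWA = list(name = "PWA", members = genes[1:4], cancer_related = TRUE,
               panel_label = "panel_a"),
    PWB = list(name = "PWB", members = genes[5:8], cancer_related = FALSE,
               panel_label = NA_character_),
    PWC = list(name = "PWC", members = genes[9:12], cancer_related = FALSE,
               panel_label = NA_character_)
  )
  edges <- data.frame(from = genes[-12], to = genes[-1],
                      relation = "direct", stringsAsFactors = FALSE)
  knowledge_base(interaction_graph(edges), pathways, universe = genes)
}

graph_nodes_for_test <- function(g) igraph::V(g$igraph)$name

write_tsv_fixture <- function(df) {
  path <- tempfile("fixture_", fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
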