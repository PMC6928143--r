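#' Construct bounded molecular subnetworks
#'
#' Deterministic seed-and-extend construction of connected subnetworks from a
#' dataset's network-eligible molecules. Repeatedly seeds a new network with
#' the unassigned eligible node of highest full-graph degree (lexicographic
#' tie-break) and grows it greedily: at each step the candidate set is every
#' graph neighbour of the current network not yet in it, and the candidate
#' added is the one maximizing, in order, (1) the number of new connections
#' it adds to eligible molecules already in the network (the seed-extension
#' cohesion criterion), (2) its total graph degree, (3) lexicographic
#' order (alphabetically first wins). Growth stops at
#' `max_size` nodes or when no connected candidate remains. Every eligible
#' node is assigned to at most one network; non-eligible "filler" nodes may
#' recur across networks.
#'
#' @param eligible character vector of network-eligible identifiers.
#' @param graph an `interaction_graph`.
#' @param max_size maximum nodes per network (default 35).
#' @param dataset_serial optional serial carried through to the networks.
#' @return List of `molecular_network` objects, numbered in construction
#'   order. Scores are not yet assigned (see [score_network]).
#' @export
build_networks <- function(eligible, graph, max_size = 35, dataset_serial = NA_integer_) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (length(max_size) != 1L || is.na(max_size) || max_size < 2) {
    stop("`max_size` must be >= 2", call. = FALSE)
  }
  eligible <- unique(toupper(eligible))
  nodes <- graph_nodes(graph)
  n <- length(nodes)
  elig_flag <- nodes %in% eligible
  if (!any(elig_flag)) return(list())

  deg <- as.integer(igraph::degree(graph$igraph))
  adj <- lapply(igraph::as_adj_list(graph$igraph), as.integer)
  unassigned <- elig_flag          # eligible and not yet placed in a network
  in_net <- logical(n)
  networks <- list()
  net_id <- 0L

  while (any(unassigned)) {
    pool <- which(unassigned)
    top <- pool[deg[pool] == max(deg[pool])]
    seed <- top[order(nodes[top])][1L]
    members <- seed
    in_net[seed] <- TRUE
    # eligible nodes already claimed by an earlier network are consumed and
    # may not recur; non-eligible filler nodes may
    open <- function(v) v[!in_net[v] & (!elig_flag[v] | unassigned[v])]
    cand <- open(adj[[seed]])
    # gain[v]: edges from v to eligible nodes already in this network
    gain <- integer(n)
    gain[adj[[seed]]] <- 1L

    while (length(members) < max_size && length(cand) > 0) {
      best <- cand[order(-gain[cand], -deg[cand], nodes[cand])[1L]]
      members <- c(members, best)
      in_net[best] <- TRUE
      if (elig_flag[best]) {
        a <- adj[[best]]
        gain[a] <- gain[a] + 1L
      }
      cand <- open(unique(c(cand, adj[[best]])))
    }

    net_id <- net_id + 1L
    member_names <- sort(nodes[members])
    networks[[net_id]] <- molecular_network(
      network_id = net_id, nodes = member_names,
      eligible_nodes = sort(nodes[members[elig_flag[members]]]),
      dataset_serial = dataset_serial
    )
    unassigned[members] <- FALSE
    in_net[members] <- FALSE
  }
  networks
}

#' A scored molecular subnetwork
#'
#' @param network_id integer id within its dataset.
#' @param nodes character vector of member identifiers.
#' @param eligible_nodes subset of `nodes` that came from the dataset.
#' @param score non-negative network score (-log10 overlap p); `NA` until
#'   [score_network] is applied.
#' @param function_labels pass-through annotation strings.
#' @param dataset_serial originating dataset serial.
#' @return A `molecular_network` object.
#' @export
molecular_network <- function(network_id, nodes, eligible_nodes,
                              score = NA_real_, function_labels = character(0),
                              dataset_serial = NA_integer_) {
  if (!all(eligible_nodes %in% nodes)) {
    stop("eligible_nodes must be a subset of nodes", call. = FALSE)
  }
  structure(
    list(network_id = as.integer(network_id), nodes = nodes,
         eligible_nodes = eligible_nodes, score = score,
         function_labels = function_labels,
         dataset_serial = as.integer(dataset_serial)),
    class = "molecular_network"
  )
}

#' @export
print.molecular_network <- function(x, ...) {
  cat(sprintf("<molecular_network %d> %d nodes (%d eligible), score %s\n",
              x$network_id, length(x$nodes), length(x$eligible_nodes),
              ifelse(is.na(x$score), "unscored", sprintf("%.1f", x$score))))
  invisible(x)
}

#' Score a network by eligible-molecule over-representation
#'
#' The network score is \eqn{-\log_{10}} of the upper-tail hypergeometric
#' probability of observing at least the network's eligible-node overlap:
#' `k = |eligible in nodes|`, `K = |nodes|`, `n = |eligible in universe|`,
#' `N = |universe|`. A network with no eligible nodes has p = 1 and score 0.
#'
#' @param network a `molecular_network`.
#' @param eligible the dataset's eligible identifiers.
#' @param kb a [knowledge_base].
#' @return The network with its `score` field set.
#' @export
score_network <- function(network, eligible, kb) {
  stopifnot(inherits(network, "molecular_network"), inherits(kb, "knowledge_base"))
  eligible <- unique(toupper(eligible))
  k <- length(intersect(eligible, network$nodes))
  K <- length(network$nodes)
  n <- length(intersect(eligible, kb$universe))
  N <- length(kb$universe)
  p <- hypergeom_tail(k, K, n, N)
  network$score <- max(0, -log10(p))
  network
}

#' Extract hub molecules from a network
#'
#' A hub molecule is a node directly or indirectly connected (adjacent via an
#' edge of either relation type) to at least `min_links` other nodes of the
#' same network, i.e. its degree in the induced subgraph is >= `min_links`.
#'
#' @param network a `molecular_network`.
#' @param graph the `interaction_graph` the network was built from.
#' @param min_links hub threshold (default 5).
#' @return data.frame with columns `identifier`, `degree`, `network_id`,
#'   `dataset_serial`, sorted by degree descending then identifier.
#' @export
extract_hubs <- function(network, graph, min_links = 5) {
  stopifnot(inherits(network, "molecular_network"), inherits(graph, "interaction_graph"))
  if (length(min_links) != 1L || is.na(min_links) || min_links < 1) {
    stop("`min_links` must be >= 1", call. = FALSE)
  }
  if (!all(network$nodes %in% graph_nodes(graph))) {
    stop("network nodes must all be present in the graph", call. = FALSE)
  }
  sub <- igraph::induced_subgraph(graph$igraph, network$nodes)
  deg <- igraph::degree(sub)
  names(deg) <- igraph::V(sub)$name
  hubs <- deg[deg >= min_links]
  if (length(hubs) == 0) {
    return(data.frame(identifier = character(0), degree = integer(0),
                      network_id = integer(0), dataset_serial = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(identifier = names(hubs), degree = as.integer(hubs),
                    network_id = network$network_id,
                    dataset_serial = network$dataset_serial,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$identifier), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Eligible-node coverage of a network, in percent
#'
#' `round(100 * |eligible nodes| / |nodes|)`, rounding halves away from zero
#' (23 of 35 gives 66; 18 of 35 gives 51).
#'
#' @param network a `molecular_network`.
#' @return Integer percentage.
#' @export
coverage_percent <- function(network) {
  stopifnot(inherits(network, "molecular_network"))
  n <- length(network$nodes)
  if (n == 0) stop("network has no nodes", call. = FALSE)
  as.integer(floor(100 * length(network$eligible_nodes) / n + 0.5))
}
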