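#' Read canonical pathway gene sets (GMT)
#'
#' One pathway per line: `name <TAB> description <TAB> member1 <TAB> ...`.
#' The description field may carry annotation tags of the form
#' `cancer_related=1;panel=<label>`; untagged pathways default to
#' `cancer_related = FALSE` and no panel label.
#'
#' @param path path to a GMT file.
#' @return A named list of `pathway_definition` objects, each a list with
#'   fields `name`, `members` (uppercase character vector), `cancer_related`,
#'   `panel_label`.
#' @export
load_gene_sets <- function(path) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  seen <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("%s line %d: GMT line needs name, description and >=1 member",
                   path, i), call. = FALSE)
    }
    name <- fields[[1]]
    if (name %in% seen) {
      stop(sprintf("%s line %d: duplicate pathway name '%s'", path, i, name),
           call. = FALSE)
    }
    seen <- c(seen, name)
    members <- unique(toupper(fields[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop(sprintf("%s line %d: pathway '%s' has no members", path, i, name),
           call. = FALSE)
    }
    tags <- parse_gmt_tags(fields[[2]])
    out[[i]] <- list(name = name, members = members,
                     cancer_related = tags$cancer_related,
                     panel_label = tags$panel_label)
  }
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

parse_gmt_tags <- function(description) {
  cancer <- FALSE
  panel <- NA_character_
  if (nzchar(description)) {
    for (tok in strsplit(description, ";", fixed = TRUE)[[1]]) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2L) {
        if (kv[[1]] == "cancer_related") cancer <- kv[[2]] %in% c("1", "true", "TRUE")
        if (kv[[1]] == "panel") panel <- kv[[2]]
      }
    }
  }
  list(cancer_related = cancer, panel_label = panel)
}

#' Read a molecular interaction graph (SIF dialect)
#'
#' Tab-separated triples `source <TAB> relation <TAB> target`, with relation
#' `direct` or `indirect`. The graph is undirected: duplicate and reversed
#' edges are collapsed, keeping the `direct` label when labels conflict.
#' Self-loops are dropped with a warning. Both relation types contribute
#' equally to adjacency and degree.
#'
#' @param path path to the SIF file.
#' @return An `interaction_graph` object backed by an undirected
#'   \pkg{igraph} graph with edge attribute `relation`.
#' @export
load_interactions <- function(path) {
  if (!file.exists(path)) stop(sprintf("SIF file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  src <- character(length(lines)); rel <- character(length(lines))
  dst <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 3L) {
      stop(sprintf("%s line %d: expected `source<TAB>relation<TAB>target`",
                   path, i), call. = FALSE)
    }
    if (!fields[[2]] %in% c("direct", "indirect")) {
      stop(sprintf("%s line %d: unknown relation '%s' (expected direct/indirect)",
                   path, i, fields[[2]]), call. = FALSE)
    }
    src[i] <- toupper(fields[[1]]); rel[i] <- fields[[2]]
    dst[i] <- toupper(fields[[3]])
  }
  interaction_graph(data.frame(from = src, to = dst, relation = rel,
                               stringsAsFactors = FALSE))
}

#' Construct an interaction graph from an edge table
#'
#' @param edges data.frame with columns `from`, `to`, `relation`
#'   (direct/indirect).
#' @param node_class optional named character vector of node class labels
#'   (e.g. kinase, transcription regulator).
#' @return An `interaction_graph` object.
#' @export
interaction_graph <- function(edges, node_class = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to", "relation") %in% names(edges)))
  if (!all(edges$relation %in% c("direct", "indirect"))) {
    stop("edge relation must be 'direct' or 'indirect'", call. = FALSE)
  }
  self <- edges$from == edges$to
  if (any(self)) {
    warning(sprintf("dropping %d self-loop edge(s)", sum(self)), call. = FALSE)
    edges <- edges[!self, , drop = FALSE]
  }
  if (nrow(edges) == 0) {
    verts <- sort(unique(as.character(names(node_class))))
    g <- igraph::graph_from_data_frame(
      data.frame(from = character(0), to = character(0)),
      directed = FALSE, vertices = data.frame(name = verts))
    if (length(verts) > 0) igraph::V(g)$node_class <- unname(node_class[verts])
    return(structure(list(igraph = g), class = "interaction_graph"))
  }
  # canonical unordered pair; 'direct' wins label conflicts
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  rel <- tapply(edges$relation, key, function(r) {
    if (any(r == "direct")) "direct" else "indirect"
  })
  keys <- sort(names(rel))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edf <- data.frame(from = vapply(parts, `[[`, character(1), 1L),
                    to = vapply(parts, `[[`, character(1), 2L),
                    relation = as.character(rel[keys]),
                    stringsAsFactors = FALSE)
  verts <- sort(unique(c(edf$from, edf$to, names(node_class))))
  g <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                     vertices = data.frame(name = verts))
  cls <- rep("other", length(verts))
  if (!is.null(node_class)) {
    hit <- match(verts, names(node_class))
    cls[!is.na(hit)] <- node_class[hit[!is.na(hit)]]
  }
  igraph::V(g)$node_class <- cls
  structure(list(igraph = g), class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph> %d nodes, %d edges\n",
              igraph::vcount(x$igraph), igraph::ecount(x$igraph)))
  invisible(x)
}

graph_nodes <- function(graph) igraph::V(graph$igraph)$name

graph_degree <- function(graph) {
  stats::setNames(igraph::degree(graph$igraph), graph_nodes(graph))
}

# adjacency as a named list of character vectors; precomputed once per run
graph_adjacency <- function(graph) {
  adj <- igraph::as_adj_list(graph$igraph)
  nm <- graph_nodes(graph)
  lapply(stats::setNames(adj, nm), function(v) nm[as.integer(v)])
}

#' Adjacent molecules of a node
#'
#' All nodes adjacent to `node` regardless of whether the relationship is
#' direct or indirect.
#'
#' @param graph an `interaction_graph`.
#' @param node a node identifier.
#' @return Character vector of neighbouring node identifiers (possibly empty).
#' @export
node_neighbors <- function(graph, node) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (!node %in% graph_nodes(graph)) {
    stop(sprintf("node '%s' is not in the graph", node), call. = FALSE)
  }
  nb <- igraph::neighbors(graph$igraph, node)
  sort(igraph::V(graph$igraph)$name[as.integer(nb)])
}

#' Assemble a knowledge base
#'
#' Bundles the interaction graph, the canonical pathway collection and the
#' identifier universe used as the enrichment background. When `universe` is
#' omitted it defaults to the union of all pathway members and all graph
#' nodes (the "all pathway annotations" background).
#'
#' @param graph an `interaction_graph`.
#' @param pathways a named list of pathway definitions from [load_gene_sets].
#' @param universe optional character vector of identifiers; must contain
#'   every pathway member and every graph node.
#' @return A `knowledge_base` object.
#' @export
knowledge_base <- function(graph, pathways, universe = NULL) {
  stopifnot(inherits(graph, "interaction_graph"), is.list(pathways))
  members <- unique(unlist(lapply(pathways, `[[`, "members"), use.names = FALSE))
  nodes <- graph_nodes(graph)
  implied <- sort(unique(c(members, nodes)))
  if (is.null(universe)) {
    universe <- implied
  } else {
    universe <- sort(unique(toupper(universe)))
    missing <- setdiff(implied, universe)
    if (length(missing) > 0) {
      stop(sprintf("universe lacks %d identifier(s) used by the graph/pathways (e.g. %s)",
                   length(missing), missing[1L]), call. = FALSE)
    }
  }
  structure(list(graph = graph, pathways = pathways, universe = universe),
            class = "knowledge_base")
}

kb_known_ids <- function(kb) {
  unique(c(graph_nodes(kb$graph),
           unlist(lapply(kb$pathways, `[[`, "members"), use.names = FALSE)))
}

#' Load a knowledge base from GMT and SIF files
#'
#' @param gmt_path pathway gene sets (GMT).
#' @param sif_path interaction edges (SIF dialect).
#' @param universe optional explicit background universe.
#' @return A `knowledge_base`.
#' @export
load_knowledge_base <- function(gmt_path, sif_path, universe = NULL) {
  knowledge_base(load_interactions(sif_path), load_gene_sets(gmt_path),
                 universe = universe)
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf("<knowledge_base> %d pathways, %d graph nodes, universe %d\n",
              length(x$pathways), igraph::vcount(x$graph$igraph),
              length(x$universe)))
  invisible(x)
}
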