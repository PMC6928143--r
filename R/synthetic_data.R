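#' Configuration for the synthetic benchmark generator
#'
#' Builds the configuration describing a synthetic knowledge base and a
#' nine-dataset omics bundle with planted hub molecules, planted enriched
#' pathways and planted phosphopeptide ratios, so that every pipeline stage
#' can be exercised end-to-end against a known truth ledger.
#'
#' The default dataset sizes mirror the nine-dataset NFPA study layout:
#' serial 1 quantitative transcriptomics (114 up, 166 down), 2 quantitative
#' proteomics (21, 29), 3 mapping proteins (218), 4 mapping nitroproteins
#' (12), 5 invasive-tumour transcriptomics (233, 113), 6 invasive-tumour
#' proteomics (30, 27), 7 control mapping proteins (1469), 8 control
#' nitroproteins (8), 9 control phosphoproteins (28).
#'
#' @param seed integer master seed; the whole bundle is reproducible from it.
#' @param n_universe universe size (default 2000).
#' @param n_pathways number of canonical pathway gene sets (default 300).
#' @param pathway_size_range min/max members per sampled pathway.
#' @param planted_pathway_size fixed size of planted pathways (default 30).
#' @param graph_attachment preferential-attachment edges per new node.
#' @param dataset_sizes named list serial -> `c(n_up, n_down)` for
#'   quantitative serials or a single count for mapping serials.
#' @param planted_hubs data.frame `identifier`, `serials` (comma-joined
#'   subset of 1-6); `NULL` selects the default 20-hub design.
#' @param planted_pathways data.frame `pathway`, `serials`, `overlap_frac`;
#'   `NULL` selects the default 10-pathway design over serials 1, 3 and 5.
#' @param ptm_planted data.frame `gene`, `peptide`, `sites`, `signed_ratio`;
#'   `NULL` selects a default panel tied to the planted hubs.
#' @param noise_sigma log-normal multiplicative noise on peak areas.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1,
                             n_universe = 2000,
                             n_pathways = 300,
                             pathway_size_range = c(10, 40),
                             planted_pathway_size = 30,
                             graph_attachment = 3,
                             dataset_sizes = NULL,
                             planted_hubs = NULL,
                             planted_pathways = NULL,
                             ptm_planted = NULL,
                             noise_sigma = 0.1) {
  stopifnot(n_universe > 0, n_pathways > 0, graph_attachment >= 1,
            length(pathway_size_range) == 2,
            pathway_size_range[1] >= 2,
            pathway_size_range[2] <= n_universe,
            noise_sigma >= 0)
  universe <- sprintf("G%04d", seq_len(n_universe))
  if (is.null(dataset_sizes)) dataset_sizes <- default_dataset_sizes()
  if (is.null(planted_hubs)) planted_hubs <- default_planted_hubs(universe)
  if (is.null(planted_pathways)) planted_pathways <- default_planted_pathways()
  if (is.null(ptm_planted)) ptm_planted <- default_ptm_planted(planted_hubs)

  hub_serials <- strsplit(planted_hubs$serials, ",")
  if (!all(unlist(hub_serials) %in% as.character(1:6))) {
    stop("planted hub serials must be a subset of 1..6", call. = FALSE)
  }
  if (any(planted_pathways$overlap_frac <= 0 | planted_pathways$overlap_frac > 1)) {
    stop("pathway overlap fractions must lie in (0, 1]", call. = FALSE)
  }
  if (any(abs(ptm_planted$signed_ratio) < 1)) {
    stop("planted signed ratios must have magnitude >= 1", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_universe = n_universe,
         universe = universe, n_pathways = n_pathways,
         pathway_size_range = pathway_size_range,
         planted_pathway_size = planted_pathway_size,
         graph_attachment = graph_attachment,
         dataset_sizes = dataset_sizes, planted_hubs = planted_hubs,
         planted_pathways = planted_pathways, ptm_planted = ptm_planted,
         noise_sigma = noise_sigma),
    class = "synthetic_config"
  )
}

default_dataset_sizes <- function() {
  list(`1` = c(114, 166), `2` = c(21, 29), `3` = 218, `4` = 12,
       `5` = c(233, 113), `6` = c(30, 27), `7` = 1469, `8` = 8, `9` = 28)
}

dataset_layout <- function() {
  data.frame(
    serial = 1:9,
    kind = c("quant_transcriptomics", "quant_proteomics", "mapping_protein",
             "mapping_nitration", "quant_transcriptomics", "quant_proteomics",
             "mapping_protein", "mapping_nitration", "mapping_phospho"),
    group = c(rep("nfpa", 4), rep("invasive_nfpa", 2), rep("control", 3)),
    stringsAsFactors = FALSE
  )
}

# 20 hubs; serial sets sized so that per-serial planted rows stay within the
# dataset quotas (serial 2 holds at most 7 seven-molecule cliques, serial 6 at
# most 8, serial 4 one)
default_planted_hubs <- function(universe) {
  sets <- c("1,2,3,4,5,6", "1,2,3,5,6", "1,2,3,5", "2,3,5,6",
            "1,2,3", "2,3,5", "1,2,5", "1,3,5", "1,5,6", "3,5,6",
            "1,3,6", "1,3,5", "1,3,5", "1,3,5", "1,3,5", "1,5,6",
            "1,5,6", "1,3,5", "1,3,5", "1,3,5")
  data.frame(identifier = universe[100 + seq_along(sets)],
             serials = sets, stringsAsFactors = FALSE)
}

default_planted_pathways <- function() {
  sets <- c("1,3", "3,5", "1,5", "1,3,5", "1,5",
            "3,5", "1,5", "1,3,5", "1,5", "3,5")
  data.frame(pathway = sprintf("PW%03d", seq_along(sets)),
             serials = sets, overlap_frac = 0.5, stringsAsFactors = FALSE)
}

# phosphopeptides for up to 12 of the planted hubs (mix of ratios above and
# below the 2.5-fold threshold) plus 3 non-hub molecules
default_ptm_planted <- function(planted_hubs) {
  hub_genes <- utils::head(planted_hubs$identifier, 12)
  hub_ratios <- utils::head(c(3.2, -2.5, 2.5, 4.1, -3.0, 2.8, 5.5, -2.6,
                              2.0, -1.8, 1.4, 2.2), length(hub_genes))
  genes <- c(hub_genes, "G1501", "G1502", "G1503")
  ratios <- c(hub_ratios, 2.5, -1.5, 6.0)
  peptides <- sprintf("SAM#PLEPEPK%s", LETTERS[seq_along(genes)])
  data.frame(gene = genes, peptide = peptides,
             sites = sprintf("S%d", 3 + seq_along(genes)),
             signed_ratio = ratios, stringsAsFactors = FALSE)
}

# dedicated clique partners, six per hub, allocated from the tail of the
# universe so they never collide with the hub identifiers
hub_partners <- function(config) {
  n_hub <- nrow(config$planted_hubs)
  n <- config$n_universe
  first <- n - 6L * n_hub + 1L
  if (first < 1 || any(config$planted_hubs$identifier %in% config$universe[first:n])) {
    stop("universe too small to allocate clique partners for the planted hubs",
         call. = FALSE)
  }
  partners <- lapply(seq_len(n_hub), function(i) {
    config$universe[first + 6L * (i - 1L) + 0:5]
  })
  names(partners) <- config$planted_hubs$identifier
  partners
}

#' Generate the synthetic knowledge base
#'
#' Builds a preferential-attachment interaction graph over the universe,
#' wires a clique around each planted hub (the hub plus six dedicated partner
#' molecules, guaranteeing induced degree of at least 5 once the hub's
#' dataset neighbourhood is selected), and samples canonical pathway gene
#' sets, with planted pathways at a fixed size. Fully reproducible from the
#' config seed.
#'
#' @param config a [synthetic_config].
#' @return List with `kb` (a [knowledge_base]) and `truth` (planted-hub and
#'   planted-pathway ledgers).
#' @export
generate_kb <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  uni <- config$universe
  n <- config$n_universe

  pa <- igraph::sample_pa(n, m = config$graph_attachment, directed = FALSE)
  el <- igraph::as_edgelist(pa, names = FALSE)
  edges <- data.frame(from = uni[el[, 1]], to = uni[el[, 2]],
                      relation = sample(c("direct", "indirect"), nrow(el),
                                        replace = TRUE),
                      stringsAsFactors = FALSE)

  partners <- hub_partners(config)
  # planted modules are isolated 7-cliques: hub and partner molecules carry
  # only their clique edges, so no other subnetwork can absorb part of a
  # module and the construction guarantee (induced hub degree >= 5 once the
  # module's dataset neighbourhood is selected) holds deterministically
  module_nodes <- c(names(partners), unlist(partners, use.names = FALSE))
  edges <- edges[!(edges$from %in% module_nodes | edges$to %in% module_nodes), ,
                 drop = FALSE]
  for (hub in names(partners)) {
    clique <- c(hub, partners[[hub]])
    pairs <- utils::combn(clique, 2)
    edges <- rbind(edges, data.frame(from = pairs[1, ], to = pairs[2, ],
                                     relation = "direct",
                                     stringsAsFactors = FALSE))
  }
  classes <- sample(c("kinase", "transcription regulator", "growth factor",
                      "enzyme", "other"), n, replace = TRUE,
                    prob = c(0.15, 0.15, 0.1, 0.2, 0.4))
  graph <- interaction_graph(edges, node_class = stats::setNames(classes, uni))

  planted_names <- config$planted_pathways$pathway
  pathways <- vector("list", config$n_pathways)
  for (j in seq_len(config$n_pathways)) {
    name <- sprintf("PW%03d", j)
    size <- if (name %in% planted_names) config$planted_pathway_size else
      sample(seq(config$pathway_size_range[1], config$pathway_size_range[2]), 1)
    members <- sort(sample(uni, size))
    pathways[[j]] <- list(
      name = name, members = members,
      cancer_related = (j %% 5 == 0),
      panel_label = if (j %% 5 == 0) sprintf("panel_%d", (j %% 9) + 1) else NA_character_
    )
  }
  names(pathways) <- vapply(pathways, `[[`, character(1), "name")
  kb <- knowledge_base(graph, pathways, universe = uni)

  # self-audit: every planted hub must satisfy its construction guarantee
  deg <- graph_degree(graph)
  if (any(deg[config$planted_hubs$identifier] < 5)) {
    stop("internal error: a planted hub has full-graph degree < 5", call. = FALSE)
  }
  truth <- list(planted_hubs = config$planted_hubs,
                planted_pathways = config$planted_pathways)
  list(kb = kb, truth = truth)
}

#' Generate the nine-dataset omics bundle
#'
#' For each serial the generator first places the planted material (for each
#' planted pathway assigned to the serial, `ceil(overlap_frac * size)` of its
#' members; for each planted hub assigned to the serial, the hub and its six
#' clique partners), then fills up to the serial's quota with molecules drawn
#' uniformly from the universe. Quantitative serials receive signed
#' fold-changes with magnitudes log-uniform in [1.5, 10], signs satisfying
#' the up/down quotas.
#'
#' @param config a [synthetic_config].
#' @param kb the [knowledge_base] from [generate_kb].
#' @return Named list of nine [omics_dataset] objects (`"1"` .. `"9"`).
#' @export
generate_datasets <- function(config, kb) {
  stopifnot(inherits(config, "synthetic_config"), inherits(kb, "knowledge_base"))
  set.seed(config$seed + 1L)
  layout <- dataset_layout()
  partners <- hub_partners(config)
  hub_serials <- lapply(strsplit(config$planted_hubs$serials, ","), as.integer)
  names(hub_serials) <- config$planted_hubs$identifier
  pw_serials <- lapply(strsplit(config$planted_pathways$serials, ","), as.integer)

  datasets <- list()
  for (row in seq_len(nrow(layout))) {
    s <- layout$serial[row]
    size_spec <- config$dataset_sizes[[as.character(s)]]
    quota <- sum(size_spec)

    planted <- character(0)
    for (j in seq_along(pw_serials)) {
      if (!s %in% pw_serials[[j]]) next
      pw <- kb$pathways[[config$planted_pathways$pathway[j]]]
      take <- ceiling(config$planted_pathways$overlap_frac[j] * length(pw$members))
      planted <- c(planted, sample(pw$members, take))
    }
    for (hub in names(hub_serials)) {
      if (!s %in% hub_serials[[hub]]) next
      planted <- c(planted, hub, partners[[hub]])
    }
    planted <- unique(planted)
    if (length(planted) > quota) {
      stop(sprintf("serial %d: planted material (%d) exceeds the dataset quota (%d)",
                   s, length(planted), quota), call. = FALSE)
    }
    fill <- sample(setdiff(config$universe, planted), quota - length(planted))
    ids <- sample(c(planted, fill))

    if (length(size_spec) == 2) {
      mags <- exp(stats::runif(quota, log(1.5), log(10)))
      signs <- c(rep(1, size_spec[1]), rep(-1, size_spec[2]))
      rec <- data.frame(identifier = ids, fold_change = signs * mags,
                        stringsAsFactors = FALSE)
    } else {
      rec <- data.frame(identifier = ids, stringsAsFactors = FALSE)
    }
    datasets[[as.character(s)]] <- omics_dataset(rec, serial = s,
                                                 kind = layout$kind[row],
                                                 group = layout$group[row])
  }
  datasets
}

#' Generate the phosphopeptide quantification table
#'
#' For each planted peptide the control group receives a log-normal base
#' intensity split over two injections; the tumour group receives the control
#' total multiplied by the planted signed ratio (or divided by its magnitude
#' when negative). Each injection is then perturbed by multiplicative
#' log-normal noise `exp(N(0, noise_sigma^2))`; with `noise_sigma = 0` the
#' planted signed ratios are recovered exactly.
#'
#' @param config a [synthetic_config].
#' @return data.frame with columns `protein`, `gene`, `peptide`, `sites`,
#'   `tumor_1`, `tumor_2`, `control_1`, `control_2`.
#' @export
generate_ptm_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  pl <- config$ptm_planted
  n <- nrow(pl)
  base <- exp(stats::rnorm(n, log(1e6), 0.5))
  ratio <- pl$signed_ratio
  tumor_total <- ifelse(ratio >= 1, base * ratio, base / abs(ratio))
  jitter <- function(m) m * exp(stats::rnorm(length(m), 0, config$noise_sigma))
  data.frame(
    protein = paste0(pl$gene, "_PROT"), gene = pl$gene,
    peptide = pl$peptide, sites = pl$sites,
    tumor_1 = jitter(tumor_total / 2), tumor_2 = jitter(tumor_total / 2),
    control_1 = jitter(base / 2), control_2 = jitter(base / 2),
    stringsAsFactors = FALSE
  )
}

#' Generate and write the full synthetic bundle
#'
#' Emits `kb.gmt`, `kb.sif`, `dataset_1.tsv` .. `dataset_9.tsv`,
#' `ptm_quant.tsv`, `function_map.tsv` and `truth.json` into `dir`. Every
#' file is byte-identical across runs with the same config.
#'
#' @param config a [synthetic_config].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory `kb`, `datasets`, `ptm_table`,
#'   `truth` and the file `paths`.
#' @export
generate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kbgen <- generate_kb(config)
  datasets <- generate_datasets(config, kbgen$kb)
  ptm <- generate_ptm_table(config)

  paths <- list(
    gmt = file.path(dir, "kb.gmt"), sif = file.path(dir, "kb.sif"),
    ptm = file.path(dir, "ptm_quant.tsv"),
    function_map = file.path(dir, "function_map.tsv"),
    truth = file.path(dir, "truth.json"),
    datasets = stats::setNames(file.path(dir, sprintf("dataset_%d.tsv", 1:9)),
                               as.character(1:9))
  )
  write_gmt(kbgen$kb$pathways, paths$gmt)
  write_sif(kbgen$kb$graph, paths$sif)
  for (s in names(datasets)) {
    write_dataset_tsv(datasets[[s]], paths$datasets[[s]])
  }
  utils::write.table(ptm, paths$ptm, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fmap <- function_map_from_kb(kbgen$kb)
  utils::write.table(fmap, paths$function_map, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- c(kbgen$truth,
             list(planted_ptm = config$ptm_planted))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(list(kb = kbgen$kb, datasets = datasets, ptm_table = ptm,
                 truth = truth, paths = paths))
}

write_gmt <- function(pathways, path) {
  lines <- vapply(pathways, function(pw) {
    desc <- if (isTRUE(pw$cancer_related)) {
      if (is.na(pw$panel_label)) "cancer_related=1"
      else sprintf("cancer_related=1;panel=%s", pw$panel_label)
    } else "na"
    paste(c(pw$name, desc, pw$members), collapse = "\t")
  }, character(1))
  writeLines(unname(lines), path)
}

write_sif <- function(graph, path) {
  el <- igraph::as_edgelist(graph$igraph, names = TRUE)
  rel <- igraph::E(graph$igraph)$relation
  a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
  ord <- order(a, b)
  writeLines(paste(a[ord], rel[ord], b[ord], sep = "\t"), path)
}

write_dataset_tsv <- function(dataset, path) {
  rec <- dataset$records
  if (is_quant_kind(dataset$kind)) {
    out <- data.frame(identifier = rec$identifier,
                      fold_change = sprintf("%.6g", rec$fold_change),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(identifier = rec$identifier, stringsAsFactors = FALSE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# panel/category plumbing labels derived from node classes
function_map_from_kb <- function(kb) {
  g <- kb$graph$igraph
  data.frame(identifier = igraph::V(g)$name,
             panel_label = paste0("panel_", gsub(" ", "_", igraph::V(g)$node_class)),
             category_label = igraph::V(g)$node_class,
             stringsAsFactors = FALSE)
}
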