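#' Pipeline configuration
#'
#' Collects all inputs and thresholds for an end-to-end run. All referenced
#' paths must resolve at construction time. Thresholds default to the study
#' values: hub threshold 5 links, high-frequency threshold 3 datasets,
#' network size cap 35 nodes, shared-pathway minimum 2 datasets, adjusted-p
#' significance 0.05, large-change fold threshold 2.5.
#'
#' @param kb_gmt,kb_sif knowledge-base file paths (GMT gene sets, SIF edges).
#' @param datasets data.frame with columns `path`, `serial`, `kind`, `group`.
#' @param function_map optional TSV path (`identifier`, `panel_label`,
#'   `category_label`) for hub-panel assembly.
#' @param ptm_table optional phosphopeptide quantification TSV path.
#' @param out_dir output directory for reports.
#' @param min_links,min_freq,max_size,min_datasets,alpha,fc_threshold
#'   analysis thresholds (see Description).
#' @param counted_serials serials counted in hub frequency (default 1-6, the
#'   tumour-group datasets).
#' @param seed integer recorded in the run manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(kb_gmt, kb_sif, datasets, function_map = NULL,
                            ptm_table = NULL, out_dir = tempfile("hubnet_run_"),
                            min_links = 5, min_freq = 3, max_size = 35,
                            min_datasets = 2, alpha = 0.05, fc_threshold = 2.5,
                            counted_serials = 1:6, seed = 1) {
  stopifnot(is.data.frame(datasets),
            all(c("path", "serial", "kind", "group") %in% names(datasets)))
  paths <- c(kb_gmt, kb_sif, datasets$path, function_map, ptm_table)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop(sprintf("input path(s) not found: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(datasets$serial)) {
    stop("dataset serials must be distinct", call. = FALSE)
  }
  stopifnot(min_links >= 1, min_freq >= 1, max_size >= 2, min_datasets >= 1,
            alpha > 0, alpha < 1, fc_threshold >= 1)
  structure(
    list(kb_gmt = kb_gmt, kb_sif = kb_sif, datasets = datasets,
         function_map = function_map, ptm_table = ptm_table,
         out_dir = out_dir, min_links = min_links, min_freq = min_freq,
         max_size = max_size, min_datasets = min_datasets, alpha = alpha,
         fc_threshold = fc_threshold, counted_serials = counted_serials,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full meta-analysis pipeline
#'
#' Executes load, de-duplication, identifier classification, pathway
#' enrichment, network construction and scoring, hub extraction, cross-dataset
#' hub frequency, high-frequency filtering and PTM cross-tabulation, and
#' writes per-stage reports plus a JSON summary into the configured output
#' directory. The run is deterministic: identical inputs yield identical
#' outputs.
#'
#' @param config a [pipeline_config].
#' @return Invisibly, a list with `summary`, `per_dataset` counts,
#'   `hub_table` (the annotated high-frequency table), `shared` (shared
#'   pathway records) and `networks`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  kb <- load_knowledge_base(config$kb_gmt, config$kb_sif)
  labels <- pathway_labels(kb)

  per_dataset <- list()
  enrichments <- list()
  occurrences <- list()
  all_networks <- list()

  for (i in seq_len(nrow(config$datasets))) {
    d <- config$datasets[i, ]
    serial <- as.integer(d$serial)
    message(sprintf("[hubnet] dataset %d: %s", serial, d$path))
    ds <- load_dataset(d$path, serial = serial, kind = d$kind, group = d$group)
    cls <- classify_ids(ds, kb)
    eligible <- cls$network_eligible_ids

    enr <- enrich_dataset(eligible, kb, alpha = config$alpha)
    enrichments[[as.character(serial)]] <- enr
    utils::write.table(
      enr, file.path(config$out_dir, sprintf("enrichment_%d.tsv", serial)),
      sep = "\t", quote = FALSE, row.names = FALSE)

    nets <- build_networks(eligible, kb$graph, max_size = config$max_size,
                           dataset_serial = serial)
    nets <- lapply(nets, score_network, eligible = eligible, kb = kb)
    all_networks[[as.character(serial)]] <- nets

    hubs <- do.call(rbind, c(
      lapply(nets, extract_hubs, graph = kb$graph,
             min_links = config$min_links),
      list(data.frame(identifier = character(0), degree = integer(0),
                      network_id = integer(0), dataset_serial = integer(0),
                      stringsAsFactors = FALSE))))
    occurrences[[as.character(serial)]] <- hubs
    write_networks_jsonl(
      nets, hubs, file.path(config$out_dir, sprintf("networks_%d.jsonl", serial)))

    per_dataset[[as.character(serial)]] <- data.frame(
      serial = serial, n_records = nrow(ds$records),
      n_eligible = length(eligible), n_networks = length(nets),
      n_significant_pathways = sum(enr$significant),
      n_hubs = nrow(hubs), stringsAsFactors = FALSE)
  }

  shared <- shared_pathways(enrichments, min_datasets = config$min_datasets,
                            labels = labels)
  utils::write.table(shared, file.path(config$out_dir, "shared_pathways.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  occ <- do.call(rbind, occurrences)
  freq <- hub_frequency(occ, counted_serials = config$counted_serials)
  high <- high_frequency_filter(freq, min_freq = config$min_freq)

  ptm_hits <- numeric(0)
  ptm_meas <- NULL
  if (!is.null(config$ptm_table)) {
    rows <- utils::read.delim(config$ptm_table, stringsAsFactors = FALSE)
    quant <- quantify_table(rows, fc_threshold = config$fc_threshold)
    ptm_meas <- quant$measurements
    if (nrow(ptm_meas) > 0) {
      ptm_hits <- tapply(abs(ptm_meas$signed_ratio), ptm_meas$gene, max)
      ptm_hits <- stats::setNames(as.numeric(ptm_hits), names(ptm_hits))
    }
    utils::write.table(ptm_meas, file.path(config$out_dir, "ptm_measurements.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cross <- ptm_crosstab(high, ptm_hits, threshold = config$fc_threshold)
  write_hub_table(cross$records, file.path(config$out_dir, "high_frequency_hubs.tsv"))

  panels <- NULL
  if (!is.null(config$function_map) && nrow(occ) > 0) {
    fmap <- utils::read.delim(config$function_map, stringsAsFactors = FALSE)
    panels <- assemble_panels(occ, fmap)
  }

  pd <- do.call(rbind, per_dataset)
  summary <- aggregate_summary(pd)
  summary$n_high_frequency_hubs <- nrow(high)
  summary$n_ptm_detected <- cross$summary$n_detected
  summary$n_large_change <- cross$summary$n_large_change
  summary$percent_detected <- cross$summary$percent_detected
  jsonlite::write_json(
    list(summary = summary, per_dataset = pd,
         config = list(seed = config$seed, min_links = config$min_links,
                       min_freq = config$min_freq, max_size = config$max_size,
                       min_datasets = config$min_datasets, alpha = config$alpha,
                       fc_threshold = config$fc_threshold)),
    file.path(config$out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")

  invisible(list(summary = summary, per_dataset = pd, hub_table = cross$records,
                 crosstab = cross$summary, shared = shared,
                 networks = all_networks, panels = panels,
                 ptm_measurements = ptm_meas, enrichments = enrichments))
}

#' Aggregate per-dataset counts into study totals
#'
#' Totals are arithmetic sums of the per-dataset fields; for example
#' per-dataset network counts (15, 4, 12, 1, 13, 3, 10, 1, 3) aggregate to
#' 62 networks.
#'
#' @param per_dataset data.frame with column `serial` and any of
#'   `n_records`, `n_eligible`, `n_networks`, `n_significant_pathways`,
#'   `n_hubs`.
#' @return List of totals: `total_networks`, `total_pathways`, `total_hubs`,
#'   `total_records`, `total_eligible` (only for columns present).
#' @export
aggregate_summary <- function(per_dataset) {
  stopifnot(is.data.frame(per_dataset), "serial" %in% names(per_dataset))
  if (anyDuplicated(per_dataset$serial)) {
    stop("per-dataset serials must be distinct", call. = FALSE)
  }
  out <- list(n_datasets = nrow(per_dataset))
  pairs <- c(n_records = "total_records", n_eligible = "total_eligible",
             n_networks = "total_networks",
             n_significant_pathways = "total_pathways", n_hubs = "total_hubs")
  for (col in names(pairs)) {
    if (col %in% names(per_dataset)) {
      out[[pairs[[col]]]] <- sum(per_dataset[[col]])
    }
  }
  out
}

write_networks_jsonl <- function(networks, hubs, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (net in networks) {
    net_hubs <- hubs[hubs$network_id == net$network_id, , drop = FALSE]
    obj <- list(network_id = net$network_id, nodes = net$nodes,
                eligible_nodes = net$eligible_nodes,
                score = round(net$score, 1),
                coverage_percent = coverage_percent(net),
                hubs = data.frame(identifier = net_hubs$identifier,
                                  degree = net_hubs$degree))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows"), con)
  }
  invisible(path)
}

write_hub_table <- function(records, path) {
  out <- data.frame(
    identifier = records$identifier, frequency = records$frequency,
    dataset_serials = records$dataset_serials,
    ptm_detected = ifelse(records$ptm_detected, "Y", ""),
    large_change = ifelse(records$ptm_detected,
                          ifelse(records$ptm_large_change, "Y", "N"), ""),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
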