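#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` marked items when `n` items are drawn without replacement from a
#' universe of `N` items of which `K` are marked. This is the one-sided
#' over-representation p-value (Fisher's exact right tail).
#'
#' @param k observed overlap, `0 <= k <= min(K, n)`.
#' @param K pathway (marked) size, `K <= N`.
#' @param n query size, `n <= N`.
#' @param N universe size.
#' @return A probability in (0, 1].
#' @export
hypergeom_tail <- function(k, K, n, N) {
  check_count <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
      stop(sprintf("`%s` must be a single non-negative integer", nm), call. = FALSE)
    }
  }
  check_count(k, "k"); check_count(K, "K"); check_count(n, "n"); check_count(N, "N")
  if (K > N || n > N) stop("K and n must not exceed N", call. = FALSE)
  if (k > min(K, n)) stop("k must not exceed min(K, n)", call. = FALSE)
  if (k == 0) return(1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment, order-aligned with the
#' input; outputs are capped at 1 and never below the raw p-values.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-dataset canonical pathway over-representation
#'
#' Tests every pathway in the knowledge base for over-representation of the
#' dataset's network-eligible molecules, using the one-sided hypergeometric
#' tail with the knowledge-base universe as background, then applies
#' Benjamini-Hochberg correction across all pathways of the dataset.
#' Significance is adjusted p strictly below `alpha`.
#'
#' @param eligible character vector of network-eligible identifiers.
#'   Identifiers outside the universe are dropped with a warning.
#' @param kb a [knowledge_base].
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return data.frame with one row per pathway, columns `pathway`, `k`, `K`,
#'   `n`, `N`, `p_value`, `adjusted_p`, `significant`, `overlap`
#'   (semicolon-joined members), sorted by `adjusted_p` then `pathway`.
#' @export
enrich_dataset <- function(eligible, kb, alpha = 0.05) {
  stopifnot(inherits(kb, "knowledge_base"))
  eligible <- unique(toupper(eligible))
  if (length(eligible) == 0 || length(kb$pathways) == 0) {
    return(empty_enrichment())
  }
  outside <- setdiff(eligible, kb$universe)
  if (length(outside) > 0) {
    warning(sprintf("%d eligible identifier(s) outside the KB universe dropped (e.g. %s)",
                    length(outside), outside[1L]), call. = FALSE)
  }
  query <- intersect(eligible, kb$universe)
  N <- length(kb$universe)
  n <- length(query)
  if (n == 0) return(empty_enrichment())

  rows <- lapply(kb$pathways, function(pw) {
    ov <- sort(intersect(query, pw$members))
    p <- hypergeom_tail(length(ov), length(pw$members), n, N)
    data.frame(pathway = pw$name, k = length(ov), K = length(pw$members),
               n = n, N = N, p_value = p,
               overlap = paste(ov, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adjusted_p <- bh_adjust(res$p_value)
  res$significant <- res$adjusted_p < alpha
  res <- res[order(res$adjusted_p, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("pathway", "k", "K", "n", "N", "p_value", "adjusted_p",
          "significant", "overlap")]
}

empty_enrichment <- function() {
  data.frame(pathway = character(0), k = integer(0), K = integer(0),
             n = integer(0), N = integer(0), p_value = numeric(0),
             adjusted_p = numeric(0), significant = logical(0),
             overlap = character(0), stringsAsFactors = FALSE)
}

#' Pathways shared across datasets
#'
#' Intersects per-dataset significant pathways and keeps those significant in
#' at least `min_datasets` datasets, annotating each with cancer-related and
#' panel labels.
#'
#' @param per_dataset named list, one enrichment data.frame
#'   (from [enrich_dataset]) per dataset serial; names are the serials.
#' @param min_datasets minimum number of datasets (default 2).
#' @param labels optional data.frame with columns `pathway`, `cancer_related`,
#'   `panel_label`; defaults taken from `kb` pathway tags when supplied via
#'   [pathway_labels].
#' @return data.frame with columns `pathway`, `dataset_serials` (comma-joined),
#'   `n_datasets`, `cancer_related`, `panel_label`, sorted by `n_datasets`
#'   descending then `pathway`.
#' @export
shared_pathways <- function(per_dataset, min_datasets = 2, labels = NULL) {
  if (length(min_datasets) != 1L || is.na(min_datasets) || min_datasets < 1) {
    stop("`min_datasets` must be >= 1", call. = FALSE)
  }
  serials <- names(per_dataset)
  if (is.null(serials) || anyDuplicated(serials)) {
    stop("`per_dataset` must be a named list with distinct serials", call. = FALSE)
  }
  hits <- list()
  for (s in serials) {
    res <- per_dataset[[s]]
    sig <- res$pathway[res$significant]
    for (pw in sig) hits[[pw]] <- c(hits[[pw]], s)
  }
  if (length(hits) == 0) return(empty_shared())
  rows <- lapply(sort(names(hits)), function(pw) {
    ser <- sort(as.integer(hits[[pw]]))
    data.frame(pathway = pw,
               dataset_serials = paste(ser, collapse = ","),
               n_datasets = length(ser), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_datasets >= min_datasets, , drop = FALSE]
  if (nrow(out) == 0) return(empty_shared())
  out$cancer_related <- FALSE
  out$panel_label <- NA_character_
  if (!is.null(labels)) {
    hit <- match(out$pathway, labels$pathway)
    ok <- !is.na(hit)
    out$cancer_related[ok] <- as.logical(labels$cancer_related[hit[ok]])
    out$panel_label[ok] <- as.character(labels$panel_label[hit[ok]])
  }
  out <- out[order(-out$n_datasets, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_shared <- function() {
  data.frame(pathway = character(0), dataset_serials = character(0),
             n_datasets = integer(0), cancer_related = logical(0),
             panel_label = character(0), stringsAsFactors = FALSE)
}

#' Pathway label table from a knowledge base
#'
#' @param kb a [knowledge_base].
#' @return data.frame with columns `pathway`, `cancer_related`, `panel_label`.
#' @export
pathway_labels <- function(kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  data.frame(
    pathway = vapply(kb$pathways, `[[`, character(1), "name"),
    cancer_related = vapply(kb$pathways, `[[`, logical(1), "cancer_related"),
    panel_label = vapply(kb$pathways, `[[`, character(1), "panel_label"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
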