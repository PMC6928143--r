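#' Group hub occurrences into functional panels
#'
#' Hub molecules are grouped into panels by their primary molecular function
#' (growth factors and receptors, kinases, transcription regulators, ...),
#' with panels further grouped into functional categories. Both labels come
#' from a curated function map supplied as input; occurrences missing from
#' the map are collected into an `"unassigned"` panel with a warning.
#'
#' @param occurrences data.frame with columns `identifier`, `dataset_serial`.
#' @param function_map data.frame with columns `identifier`, `panel_label`,
#'   `category_label`.
#' @return Named list of `hub_panel` objects ordered by panel label; each has
#'   fields `panel_label`, `category_label` and `members_by_dataset` (a named
#'   list: serial -> sorted identifier vector).
#' @export
assemble_panels <- function(occurrences, function_map) {
  stopifnot(is.data.frame(occurrences))
  if (nrow(occurrences) == 0) return(list())
  if (is.null(function_map) || nrow(function_map) == 0) {
    stop("`function_map` is empty but occurrences are present", call. = FALSE)
  }
  hit <- match(occurrences$identifier, function_map$identifier)
  miss <- is.na(hit)
  if (any(miss)) {
    warning(sprintf("%d hub occurrence(s) missing from the function map collected into 'unassigned' (e.g. %s)",
                    sum(miss), occurrences$identifier[miss][1L]), call. = FALSE)
  }
  panel <- ifelse(miss, "unassigned",
                  as.character(function_map$panel_label[hit]))
  category <- ifelse(miss, "unassigned",
                     as.character(function_map$category_label[hit]))

  panels <- list()
  for (lab in sort(unique(panel))) {
    idx <- which(panel == lab)
    by_ds <- split(occurrences$identifier[idx],
                   as.integer(occurrences$dataset_serial[idx]))
    by_ds <- lapply(by_ds, function(v) sort(unique(v)))
    panels[[lab]] <- structure(
      list(panel_label = lab, category_label = category[idx][1L],
           members_by_dataset = by_ds),
      class = "hub_panel")
  }
  panels
}

#' Cross-dataset hub frequency table
#'
#' Counts, for each hub molecule, the number of distinct tumour-group
#' datasets in which it occurs as a hub. Multiple networks or panels within
#' one dataset count once. Only serials in `counted_serials` contribute
#' (default: the six tumour-group datasets, serials 1-6).
#'
#' @param occurrences data.frame with columns `identifier`, `dataset_serial`.
#' @param counted_serials serials that contribute to the frequency.
#' @return data.frame with columns `identifier`, `frequency`,
#'   `dataset_serials` (comma-joined ascending), sorted by frequency
#'   descending then identifier.
#' @export
hub_frequency <- function(occurrences, counted_serials = 1:6) {
  stopifnot(is.data.frame(occurrences))
  if (nrow(occurrences) == 0) {
    return(data.frame(identifier = character(0), frequency = integer(0),
                      dataset_serials = character(0), stringsAsFactors = FALSE))
  }
  ser <- as.integer(occurrences$dataset_serial)
  keep <- ser %in% as.integer(counted_serials)
  sets <- lapply(split(ser[keep], occurrences$identifier[keep]),
                 function(s) sort(unique(s)))
  ids <- sort(unique(occurrences$identifier))
  freq <- vapply(ids, function(id) length(sets[[id]]), integer(1))
  serial_str <- vapply(ids, function(id) {
    paste(sets[[id]], collapse = ",")
  }, character(1))
  out <- data.frame(identifier = ids, frequency = freq,
                    dataset_serials = serial_str, stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$identifier), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep high-frequency hub molecules
#'
#' A high-frequency hub molecule is one observed as a hub in at least
#' `min_freq` distinct datasets (default 3). Input order is preserved.
#'
#' @param records a frequency table from [hub_frequency].
#' @param min_freq minimum frequency (default 3).
#' @return The filtered data.frame.
#' @export
high_frequency_filter <- function(records, min_freq = 3) {
  if (length(min_freq) != 1L || is.na(min_freq) || min_freq < 1) {
    stop("`min_freq` must be >= 1", call. = FALSE)
  }
  out <- records[records$frequency >= min_freq, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-tabulate hub molecules with phosphopeptide quantification
#'
#' Annotates each hub record with whether the molecule was detected in the
#' PTMScan-style phosphoproteomics experiment and, if so, whether its largest
#' absolute signed fold-change reaches `threshold` (default 2.5, i.e. ratio
#' >= 2.5 or <= -2.5). The summary's detection percentage is truncated
#' (toward zero) to one decimal place.
#'
#' @param records a frequency table (typically from [high_frequency_filter]).
#' @param ptm_hits named numeric vector: molecule identifier -> maximum
#'   absolute signed ratio observed for that molecule (all values >= 1).
#' @param threshold large-change threshold on |signed ratio| (default 2.5).
#' @return List with `records` (input plus logical columns `ptm_detected`,
#'   `ptm_large_change`) and `summary` (list: `n_records`, `n_detected`,
#'   `n_large_change`, `percent_detected`).
#' @export
ptm_crosstab <- function(records, ptm_hits, threshold = 2.5) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 1) {
    stop("`threshold` must be >= 1", call. = FALSE)
  }
  ptm_hits <- ptm_hits[!is.na(ptm_hits)]
  if (length(ptm_hits) > 0 && any(abs(ptm_hits) < 1)) {
    stop("ptm_hits ratios must have magnitude >= 1", call. = FALSE)
  }
  detected <- records$identifier %in% names(ptm_hits)
  maxabs <- rep(NA_real_, nrow(records))
  maxabs[detected] <- abs(ptm_hits[records$identifier[detected]])
  large <- detected & !is.na(maxabs) & maxabs >= threshold
  records$ptm_detected <- detected
  records$ptm_large_change <- large
  n <- nrow(records)
  pct <- if (n == 0) 0 else floor(1000 * sum(detected) / n) / 10
  list(records = records,
       summary = list(n_records = n, n_detected = sum(detected),
                      n_large_change = sum(large),
                      percent_detected = pct))
}

#' Reference table of high-frequency hub molecules in NFPA
#'
#' Loads the packaged curated reference table of 57 high-frequency
#' hub-molecules observed across the tumour-group omics datasets of the
#' non-functional pituitary adenoma study design, with their dataset serials
#' and PTMScan detection / fold-change flags (Greek letters romanized).
#'
#' @return List with `records` (data.frame `identifier`, `frequency`,
#'   `dataset_serials`, plus the printed flags `ptm_detected_flag`,
#'   `large_change_flag`), `occurrences` (long form: identifier x serial) and
#'   `ptm_hits` (named ratio-magnitude vector reconstructed from the flags:
#'   2.5 for large-change molecules, 2.0 for detected-only).
#' @export
nfpa_hub_reference <- function() {
  path <- system.file("extdata", "nfpa_high_frequency_hubs.tsv",
                      package = "hubnet", mustWork = TRUE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  serial_sets <- lapply(strsplit(tab$dataset_serials, ","), as.integer)
  occurrences <- data.frame(
    identifier = rep(tab$hub_molecule, lengths(serial_sets)),
    dataset_serial = unlist(serial_sets),
    stringsAsFactors = FALSE
  )
  detected <- tab$ptm_detected %in% "Y"
  large <- tab$fc_large_change %in% "Y"
  ptm_hits <- stats::setNames(ifelse(large[detected], 2.5, 2.0),
                              tab$hub_molecule[detected])
  records <- data.frame(identifier = tab$hub_molecule,
                        frequency = as.integer(tab$frequency),
                        dataset_serials = tab$dataset_serials,
                        ptm_detected_flag = detected,
                        large_change_flag = large,
                        stringsAsFactors = FALSE)
  list(records = records, occurrences = occurrences, ptm_hits = ptm_hits)
}
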