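DATASET_KINDS <- c("quant_transcriptomics", "quant_proteomics",
                   "mapping_protein", "mapping_nitration", "mapping_phospho")
DATASET_GROUPS <- c("nfpa", "invasive_nfpa", "control")
QUANT_KINDS <- c("quant_transcriptomics", "quant_proteomics")

is_quant_kind <- function(kind) kind %in% QUANT_KINDS

#' Construct an omics dataset
#'
#' An omics dataset is one of the molecule collections entering the pipeline:
#' a quantitative transcriptomics/proteomics table of differentially expressed
#' genes or proteins with signed fold-changes, or a presence-only (mapping)
#' inventory of proteins, nitroproteins or phosphoproteins.
#'
#' Signed fold-changes follow the symmetric ratio convention: values \eqn{\ge
#' 1} denote up-regulation by that factor, values \eqn{\le -1} down-regulation
#' by the reciprocal factor; the open interval (-1, 1) is not a valid
#' fold-change and is rejected.
#'
#' @param records data.frame with columns `identifier` (required),
#'   `display_name`, `fold_change`, `direction`, `modification_note`.
#' @param serial integer dataset serial number (1-9 in the default study
#'   layout).
#' @param kind one of `"quant_transcriptomics"`, `"quant_proteomics"`,
#'   `"mapping_protein"`, `"mapping_nitration"`, `"mapping_phospho"`.
#' @param group sample group: `"nfpa"`, `"invasive_nfpa"` or `"control"`.
#' @return An object of class `omics_dataset`.
#' @export
omics_dataset <- function(records, serial, kind, group) {
  kind <- match.arg(kind, DATASET_KINDS)
  group <- match.arg(group, DATASET_GROUPS)
  serial <- as.integer(serial)
  if (length(serial) != 1L || is.na(serial) || serial < 1L) {
    stop("`serial` must be a single positive integer", call. = FALSE)
  }
  records <- validate_records(records, kind)
  structure(
    list(serial = serial, kind = kind, group = group, records = records),
    class = "omics_dataset"
  )
}

validate_records <- function(records, kind) {
  stopifnot(is.data.frame(records))
  if (!"identifier" %in% names(records)) {
    stop("record table lacks an `identifier` column", call. = FALSE)
  }
  n <- nrow(records)
  records$identifier <- toupper(trimws(as.character(records$identifier)))
  if (n > 0 && any(!nzchar(records$identifier) | is.na(records$identifier))) {
    bad <- which(!nzchar(records$identifier) | is.na(records$identifier))[1L]
    stop(sprintf("empty identifier in row %d", bad), call. = FALSE)
  }
  if (is.null(records$display_name)) records$display_name <- records$identifier
  if (is.null(records$fold_change)) records$fold_change <- rep(NA_real_, n)
  records$fold_change <- as.numeric(records$fold_change)
  if (is.null(records$modification_note)) {
    records$modification_note <- rep(NA_character_, n)
  }

  if (is_quant_kind(kind)) {
    fc <- records$fold_change
    bad <- which(!is.na(fc) & abs(fc) < 1)
    if (length(bad) > 0) {
      stop(sprintf(
        "row %d: fold_change %.4g lies in (-1, 1); signed fold-changes must have magnitude >= 1",
        bad[1L], fc[bad[1L]]), call. = FALSE)
    }
    records$direction <- ifelse(is.na(fc), "present",
                                ifelse(fc >= 1, "up", "down"))
  } else {
    if (any(!is.na(records$fold_change))) {
      stop("mapping datasets are presence-only; fold_change must be absent",
           call. = FALSE)
    }
    records$direction <- rep("present", n)
  }
  rownames(records) <- NULL
  records[, c("identifier", "display_name", "fold_change",
              "direction", "modification_note")]
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("<omics_dataset> serial %d  kind %s  group %s  %d records\n",
              x$serial, x$kind, x$group, nrow(x$records)))
  invisible(x)
}

#' Load a molecule table from TSV
#'
#' Reads a tab-separated molecule table (UTF-8, header row required) into an
#' [omics_dataset]. Required column: `identifier`; optional: `fold_change`
#' (decimal, optional leading minus), `direction`, `modification_note`.
#' Identifiers are canonicalized to uppercase; row order is preserved.
#'
#' @inheritParams omics_dataset
#' @param path path to the TSV file.
#' @return An [omics_dataset].
#' @export
load_dataset <- function(path, serial, kind, group) {
  if (!file.exists(path)) stop(sprintf("dataset file not found: %s", path), call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""))
  if (!"identifier" %in% names(tab)) {
    stop(sprintf("%s: missing required `identifier` column", path), call. = FALSE)
  }
  if ("fold_change" %in% names(tab)) {
    tab$fold_change <- suppressWarnings(as.numeric(tab$fold_change))
  }
  omics_dataset(tab, serial = serial, kind = kind, group = group)
}

#' Collapse duplicated identifiers
#'
#' One record per identifier. For quantitative datasets the surviving record
#' is the one with the largest absolute fold-change (sign retained; ties go to
#' the earlier row); for mapping datasets the first occurrence survives. The
#' output keeps first-occurrence order, and the operation is idempotent.
#'
#' @param dataset an [omics_dataset].
#' @return An [omics_dataset] with unique identifiers.
#' @export
deduplicate <- function(dataset) {
  stopifnot(inherits(dataset, "omics_dataset"))
  rec <- dataset$records
  if (nrow(rec) <= 1L || !anyDuplicated(rec$identifier)) return(dataset)

  if (is_quant_kind(dataset$kind)) {
    keep <- vapply(split(seq_len(nrow(rec)), rec$identifier), function(idx) {
      mag <- abs(rec$fold_change[idx])
      mag[is.na(mag)] <- -Inf
      idx[which.max(mag)]
    }, integer(1))
  } else {
    keep <- vapply(split(seq_len(nrow(rec)), rec$identifier),
                   function(idx) idx[1L], integer(1))
  }
  first_seen <- match(unique(rec$identifier), rec$identifier)
  ord <- keep[match(rec$identifier[sort(first_seen)], names(keep))]
  dataset$records <- rec[ord, , drop = FALSE]
  rownames(dataset$records) <- NULL
  dataset
}

#' Classify dataset identifiers against a knowledge base
#'
#' Partitions a dataset's identifiers into mapped (present in the knowledge
#' base's interaction graph or pathway membership) and unmapped subsets, and
#' derives the network-eligible set: mapped identifiers after de-duplication.
#' De-duplication is applied internally, so raw datasets are accepted.
#'
#' @param dataset an [omics_dataset].
#' @param kb a [knowledge_base].
#' @return An object of class `id_classification` with character-vector fields
#'   `all_ids`, `mapped_ids`, `unmapped_ids`, `network_eligible_ids`.
#' @export
classify_ids <- function(dataset, kb) {
  stopifnot(inherits(dataset, "omics_dataset"), inherits(kb, "knowledge_base"))
  known <- kb_known_ids(kb)
  if (length(known) == 0) {
    stop("knowledge base is empty: no graph nodes and no pathway members",
         call. = FALSE)
  }
  all_ids <- unique(dataset$records$identifier)
  mapped <- all_ids[all_ids %in% known]
  unmapped <- setdiff(all_ids, mapped)
  eligible <- unique(deduplicate(dataset)$records$identifier)
  eligible <- eligible[eligible %in% known]
  structure(
    list(all_ids = all_ids, mapped_ids = mapped, unmapped_ids = unmapped,
         network_eligible_ids = eligible),
    class = "id_classification"
  )
}

#' @export
print.id_classification <- function(x, ...) {
  cat(sprintf("<id_classification> %d ids: %d mapped, %d unmapped, %d network-eligible\n",
              length(x$all_ids), length(x$mapped_ids), length(x$unmapped_ids),
              length(x$network_eligible_ids)))
  invisible(x)
}
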