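#' Parse a modified-peptide string
#'
#' Peptide strings use uppercase residue letters, each optionally suffixed by
#' `#` marking methionine oxidation (e.g. `NLLHVTDTGVGM#TR`). Positions in
#' the returned modification table are 1-based on the plain sequence.
#'
#' @param text a modified-peptide string.
#' @return List with `sequence` (plain string) and `modifications`
#'   (data.frame `position`, `type`).
#' @export
parse_modified_peptide <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("empty peptide string", call. = FALSE)
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  seq_chars <- character(0)
  mods <- integer(0)
  for (ch in chars) {
    if (ch == "#") {
      if (length(seq_chars) == 0 || seq_chars[length(seq_chars)] != "M") {
        stop(sprintf("'#' oxidation mark must follow an M residue in '%s'", text),
             call. = FALSE)
      }
      mods <- c(mods, length(seq_chars))
    } else if (grepl("^[A-Z]$", ch)) {
      seq_chars <- c(seq_chars, ch)
    } else {
      stop(sprintf("invalid character '%s' in peptide '%s'", ch, text),
           call. = FALSE)
    }
  }
  list(sequence = paste(seq_chars, collapse = ""),
       modifications = data.frame(position = mods,
                                  type = rep("oxidation", length(mods)),
                                  stringsAsFactors = FALSE))
}

#' Signed tumour:control fold-change
#'
#' Symmetric ratio convention: returns `t/c` when the quotient is at least 1
#' and `-(c/t)` otherwise, so that magnitudes are comparable about +/-1 and
#' values in (-1, 1) never occur.
#'
#' @param area_tumor,area_control positive summed peak areas.
#' @return Signed ratio with `|value| >= 1`.
#' @export
signed_ratio <- function(area_tumor, area_control) {
  if (any(c(length(area_tumor), length(area_control)) != 1L) ||
      is.na(area_tumor) || is.na(area_control) ||
      area_tumor <= 0 || area_control <= 0) {
    stop("peak areas must be single positive numbers", call. = FALSE)
  }
  r <- area_tumor / area_control
  if (r >= 1) r else -(area_control / area_tumor)
}

#' Large-change classification of a signed ratio
#'
#' TRUE when the signed ratio is at least `threshold` or at most
#' `-threshold` (default 2.5), i.e. at least a 2.5-fold change in either
#' direction.
#'
#' @param ratio signed ratio with `|ratio| >= 1`.
#' @param threshold fold-change threshold (>= 1; default 2.5).
#' @return Logical.
#' @export
classify_magnitude <- function(ratio, threshold = 2.5) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 1) {
    stop("`threshold` must be >= 1", call. = FALSE)
  }
  if (any(is.na(ratio)) || any(abs(ratio) < 1)) {
    stop("signed ratios must have magnitude >= 1", call. = FALSE)
  }
  ratio >= threshold | ratio <= -threshold
}

#' Target-decoy FDR score cutoff
#'
#' Scans candidate score cutoffs from the highest observed score downward.
#' At each cutoff the FDR estimate is `#decoys >= cutoff / #targets >=
#' cutoff` (undefined while no target is accepted; such cutoffs are
#' skipped). Returns the lowest cutoff whose FDR is at most `alpha`, i.e.
#' the qualifying cutoff accepting the most targets; ties at the cutoff
#' score are all included. Returns `NULL` when no cutoff qualifies.
#'
#' @param psms data.frame with columns `score` (numeric) and `is_decoy`
#'   (logical).
#' @param alpha FDR level in (0, 1), default 0.05.
#' @return The score cutoff, or `NULL`.
#' @export
decoy_fdr_threshold <- function(psms, alpha = 0.05) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  if (is.null(psms) || nrow(psms) == 0) return(NULL)
  stopifnot(all(c("score", "is_decoy") %in% names(psms)))
  cutoffs <- sort(unique(psms$score), decreasing = TRUE)
  best <- NULL
  for (cut in cutoffs) {
    acc <- psms$score >= cut
    n_target <- sum(acc & !psms$is_decoy)
    if (n_target == 0) next
    fdr <- sum(acc & psms$is_decoy) / n_target
    if (fdr <= alpha) best <- cut
  }
  best
}

#' Quantify a phosphopeptide table
#'
#' Post-search label-free quantification: per-group peak areas are summed
#' over the (duplicate-injection) area columns, the signed tumour:control
#' ratio is computed, and site annotations are parsed. Site tokens look like
#' `S236` (confident) or `S236?` (ambiguous; kept with `confident = FALSE`).
#' Rows without a positive area in each group are dropped with a warning;
#' rows with malformed site or peptide annotations are collected into a
#' rejects table rather than failing the run.
#'
#' @param rows data.frame with columns `protein`, `gene`, `peptide`, `sites`
#'   (semicolon-joined tokens) and one or more `tumor_*` / `control_*` area
#'   columns.
#' @param fc_threshold large-change threshold passed to
#'   [classify_magnitude] (default 2.5).
#' @return List with `measurements` (data.frame: `protein`, `gene`,
#'   `peptide`, `sequence`, `sites`, `area_tumor`, `area_control`,
#'   `signed_ratio`, `large_change`) and `rejects` (data.frame: `row`,
#'   `reason`).
#' @export
quantify_table <- function(rows, fc_threshold = 2.5) {
  stopifnot(is.data.frame(rows))
  tumor_cols <- grep("^tumor_", names(rows), value = TRUE)
  control_cols <- grep("^control_", names(rows), value = TRUE)
  if (length(tumor_cols) == 0 || length(control_cols) == 0) {
    stop("table needs tumor_* and control_* area columns", call. = FALSE)
  }
  meas <- list(); rejects <- list()
  dropped <- 0L
  for (i in seq_len(nrow(rows))) {
    at <- sum_areas(rows[i, tumor_cols])
    ac <- sum_areas(rows[i, control_cols])
    if (at <= 0 || ac <= 0) {
      dropped <- dropped + 1L
      next
    }
    parsed <- tryCatch(parse_modified_peptide(rows$peptide[i]), error = identity)
    if (inherits(parsed, "error")) {
      rejects[[length(rejects) + 1L]] <-
        data.frame(row = i, reason = conditionMessage(parsed))
      next
    }
    sites <- tryCatch(parse_sites(rows$sites[i]), error = identity)
    if (inherits(sites, "error")) {
      rejects[[length(rejects) + 1L]] <-
        data.frame(row = i, reason = conditionMessage(sites))
      next
    }
    r <- signed_ratio(at, ac)
    meas[[length(meas) + 1L]] <- data.frame(
      protein = rows$protein[i], gene = toupper(rows$gene[i]),
      peptide = rows$peptide[i], sequence = parsed$sequence,
      sites = site_string(sites), area_tumor = at, area_control = ac,
      signed_ratio = r, large_change = classify_magnitude(r, fc_threshold),
      stringsAsFactors = FALSE)
  }
  if (dropped > 0) {
    warning(sprintf("%d row(s) without a positive area in each group dropped",
                    dropped), call. = FALSE)
  }
  list(
    measurements = if (length(meas)) do.call(rbind, meas) else
      data.frame(protein = character(0), gene = character(0),
                 peptide = character(0), sequence = character(0),
                 sites = character(0), area_tumor = numeric(0),
                 area_control = numeric(0), signed_ratio = numeric(0),
                 large_change = logical(0), stringsAsFactors = FALSE),
    rejects = if (length(rejects)) do.call(rbind, rejects) else
      data.frame(row = integer(0), reason = character(0),
                 stringsAsFactors = FALSE)
  )
}

sum_areas <- function(vals) {
  x <- suppressWarnings(as.numeric(unlist(vals)))
  x <- x[!is.na(x) & x > 0]
  if (length(x) == 0) 0 else sum(x)
}

parse_sites <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(residue = character(0), position = integer(0),
                      confident = logical(0), stringsAsFactors = FALSE))
  }
  toks <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  m <- regmatches(toks, regexec("^([A-Z])([0-9]+)(\\??)$", toks))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) {
    stop(sprintf("malformed site token '%s'", toks[bad][1L]), call. = FALSE)
  }
  out <- data.frame(
    residue = vapply(m, `[[`, character(1), 2L),
    position = as.integer(vapply(m, `[[`, character(1), 3L)),
    confident = vapply(m, `[[`, character(1), 4L) == "",
    stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}

site_string <- function(sites) {
  if (nrow(sites) == 0) return("")
  paste0(sites$residue, sites$position, ifelse(sites$confident, "", "?"),
         collapse = ";")
}
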