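SITE_SOURCES <- c("experimental", "by_similarity", "imported")

.check_records_residue <- function(df, records, what) {
  if (is.null(records)) return(invisible(TRUE))
  if (inherits(records, "protein_record")) records <- list(records)
  byid <- setNames(records, vapply(records, `[[`, "", "id"))
  for (i in seq_len(nrow(df))) {
    rec <- byid[[df$seq_id[i]]]
    if (is.null(rec)) next
    got <- residue_at(rec, df$position[i])
    if (got != df$residue[i])
      stop(sprintf("%s: residue mismatch for %s position %d (table says %s, sequence has %s)",
                   what, df$seq_id[i], df$position[i], df$residue[i], got),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a site-evidence table (TSV)
#'
#' Columns: `seq_id`, `position` (reported numbering), `residue` (S/T/Y),
#' `source` (experimental / by_similarity / imported), `provenance`.
#' The shape of a Phospho.ELM-style export.
#'
#' @param path TSV path (with header).
#' @param records Optional list of [protein_record()]s; when given, each row's
#'   residue is cross-checked against the referenced sequence.
#' @return data.frame of typed evidence rows (possibly empty).
#' @export
read_site_table <- function(path, records = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("seq_id", "position", "residue", "source", "provenance")
  if (!all(need %in% names(df)))
    stop(sprintf("site table %s must have columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  df <- df[, need, drop = FALSE]
  df$position <- as.integer(df$position)
  if (nrow(df)) {
    if (!all(df$residue %in% c("S", "T", "Y")))
      stop("site table residue must be S, T or Y", call. = FALSE)
    if (!all(df$source %in% SITE_SOURCES))
      stop(sprintf("site table source must be one of: %s",
                   paste(SITE_SOURCES, collapse = ", ")), call. = FALSE)
    .check_records_residue(df, records, sprintf("site table %s", path))
  }
  df
}

#' Write a site-evidence table (TSV)
#' @param evidence data.frame as returned by [read_site_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(evidence, path) {
  write.table(evidence, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a predictor-score table (TSV)
#'
#' Columns: `seq_id`, `position`, `residue` (S/T/Y), `predictor` (phospho,
#' glyco, or a kinase name), `score` in \[0,1\], `threshold` in (0,1).  The
#' shape of NetPhos/NetPhosK/YinOYang-style exports; a score is positive iff
#' `score >= threshold`.
#'
#' @inheritParams read_site_table
#' @return data.frame of typed score rows.
#' @export
read_score_table <- function(path, records = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("seq_id", "position", "residue", "predictor", "score", "threshold")
  if (!all(need %in% names(df)))
    stop(sprintf("score table %s must have columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  df <- df[, need, drop = FALSE]
  df$position <- as.integer(df$position)
  df$score <- as.numeric(df$score)
  df$threshold <- as.numeric(df$threshold)
  if (nrow(df)) {
    if (!all(df$residue %in% c("S", "T", "Y")))
      stop("score table residue must be S, T or Y", call. = FALSE)
    bad <- which(is.na(df$score) | df$score < 0 | df$score > 1)
    if (length(bad))
      stop(sprintf("score outside [0,1] for %s position %d",
                   df$seq_id[bad[1]], df$position[bad[1]]), call. = FALSE)
    bad <- which(is.na(df$threshold) | df$threshold <= 0 | df$threshold >= 1)
    if (length(bad))
      stop(sprintf("threshold outside (0,1) for %s position %d",
                   df$seq_id[bad[1]], df$position[bad[1]]), call. = FALSE)
    .check_records_residue(df, records, sprintf("score table %s", path))
  }
  df
}

#' Write a predictor-score table (TSV)
#' @param scores data.frame as returned by [read_score_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
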