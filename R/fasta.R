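#' Read protein sequences from FASTA
#'
#' Parsing is delegated to Biostrings; sequences are uppercased, validated
#' against the 21-letter alphabet (20 amino acids + X) and returned as
#' [protein_record()]s with `numbering_offset = 0` (raw numbering).
#'
#' @param path Path to a FASTA file.
#' @return List of [protein_record()]s, one per entry, named by id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  recs <- lapply(seq_along(set), function(i) {
    protein_record(ids[i], as.character(set[[i]]), name = descs[i])
  })
  names(recs) <- ids
  recs
}

#' Write protein records to FASTA
#'
#' @param records List of [protein_record()]s.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "protein_record")) records <- list(records)
  set <- Biostrings::AAStringSet(vapply(records, function(r) r$sequence, ""))
  names(set) <- vapply(records, function(r) {
    if (nzchar(r$name)) paste(r$id, r$name) else r$id
  }, "")
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}
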