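#' Multiple protein alignment container
#'
#' Rows are gapped sequences of equal length; ungapping a row recovers the
#' underlying protein sequence.  Alignments are consumed, never computed:
#' any aligner emitting Clustal or aligned-FASTA output can feed this type.
#'
#' @param ids Character vector of row ids (unique).
#' @param seqs Character vector of gapped sequences (equal length, >= 2 rows).
#' @return Object of class `multiple_alignment` with fields `ids`, `seqs`,
#'   `length` (number of columns).
#' @export
multiple_alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  stopifnot(length(ids) == length(seqs))
  if (length(ids) < 2L) stop("alignment needs >= 2 rows", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate alignment row ids", call. = FALSE)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("alignment rows differ in length", call. = FALSE)
  for (i in seq_along(seqs))
    .validate_residues(.seq_chars(seqs[i]),
                       what = sprintf("alignment row '%s'", ids[i]),
                       allow_gap = TRUE)
  structure(list(ids = ids, seqs = setNames(seqs, ids), length = widths[1]),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("multiple_alignment: %d rows x %d columns (%s)\n",
              length(x$ids), x$length,
              paste(utils::head(x$ids, 5), collapse = ", ")))
  invisible(x)
}

#' Read a multiple alignment (Clustal or aligned FASTA)
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` (aligned FASTA) or `"clustal"`.
#' @return A [multiple_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  m <- as.character(aln)
  multiple_alignment(names(m), unname(m))
}

#' Write a multiple alignment as aligned FASTA
#'
#' @param msa A [multiple_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path) {
  stopifnot(inherits(msa, "multiple_alignment"))
  set <- Biostrings::AAStringSet(msa$seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Ungapped sequence of one alignment row
#' @param msa A [multiple_alignment()].
#' @param id Row id.
#' @return Character scalar (residues only).
#' @export
ungapped_row <- function(msa, id) {
  stopifnot(inherits(msa, "multiple_alignment"))
  if (!id %in% msa$ids) stop(sprintf("row '%s' not in alignment", id), call. = FALSE)
  gsub(GAP, "", msa$seqs[[id]], fixed = TRUE)
}

# column index for each raw residue position of a row (gaps skipped)
.row_pos_to_col <- function(msa, id) {
  chars <- .seq_chars(msa$seqs[[id]])
  which(chars != GAP)
}

# raw residue position for each column of a row (NA at gap columns)
.row_col_to_pos <- function(msa, id) {
  chars <- .seq_chars(msa$seqs[[id]])
  pos <- cumsum(chars != GAP)
  pos[chars == GAP] <- NA_integer_
  pos
}
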