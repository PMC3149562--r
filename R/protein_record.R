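#' Protein sequence record with an explicit residue-numbering convention
#'
#' A `protein_record` holds one amino-acid sequence together with the offset
#' that converts its 1-based raw index into the position reported in site
#' tables.  Linker histone positions in the literature are usually counted
#' after cleavage of the initiator methionine, one below the database
#' canonical position; [apply_numbering()] switches a record to that
#' convention.
#'
#' @param id Accession or label (single string).
#' @param sequence Amino-acid sequence over the 20-letter alphabet plus `X`
#'   (unknown).  Lower case is accepted and uppercased.
#' @param name Optional free-text description.
#' @param numbering_offset Integer added to the 1-based raw index to yield the
#'   reported position.  All reported positions must stay >= 1.
#' @return An object of class `protein_record` with fields `id`, `name`,
#'   `sequence`, `numbering_offset`.
#' @examples
#' r <- protein_record("x", "MSETA")
#' residue_at(r, 2)   # "S"
#' @export
protein_record <- function(id, sequence, name = "", numbering_offset = 0L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("sequence must be non-empty", call. = FALSE)
  .validate_residues(.seq_chars(sequence), what = sprintf("sequence '%s'", id))
  numbering_offset <- as.integer(numbering_offset)
  if (1L + numbering_offset < 1L)
    stop("numbering_offset would give a reported position < 1", call. = FALSE)
  structure(list(id = id, name = name, sequence = sequence,
                 numbering_offset = numbering_offset),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("protein_record %s (%d aa, offset %+d)%s\n", x$id,
              nchar(x$sequence), x$numbering_offset,
              if (nzchar(x$name)) paste0(": ", x$name) else ""))
  invisible(x)
}

#' @export
length.protein_record <- function(x) nchar(x$sequence)

#' Residue at a reported position
#'
#' @param record A [protein_record()].
#' @param position Reported position(s) (raw index + numbering offset).
#' @return Character vector of single residues.
#' @export
residue_at <- function(record, position) {
  stopifnot(inherits(record, "protein_record"))
  raw <- as.integer(position) - record$numbering_offset
  n <- nchar(record$sequence)
  if (any(raw < 1L | raw > n))
    stop(sprintf("position out of range for %s (reported %s)", record$id,
                 paste(position[raw < 1L | raw > n], collapse = ",")),
         call. = FALSE)
  substring(record$sequence, raw, raw)
}

#' Switch a record between raw and initiator-Met-removed numbering
#'
#' Under `met_cleaved` the leading methionine is removed and the first
#' retained residue is reported as position 1, reproducing the numbering used
#' for mature linker histones (one below the database canonical position).
#' `raw` is the identity.
#'
#' @param record A [protein_record()].
#' @param convention `"raw"` or `"met_cleaved"`.
#' @return A [protein_record()].
#' @examples
#' apply_numbering(protein_record("x", "MSETA"), "met_cleaved")$sequence  # "SETA"
#' @export
apply_numbering <- function(record, convention = c("met_cleaved", "raw")) {
  stopifnot(inherits(record, "protein_record"))
  convention <- match.arg(convention)
  if (convention == "raw") return(record)
  if (substring(record$sequence, 1L, 1L) != "M")
    stop(sprintf("met_cleaved numbering requires %s to start with M",
                 record$id), call. = FALSE)
  protein_record(record$id, substring(record$sequence, 2L),
                 name = record$name,
                 numbering_offset = record$numbering_offset)
}
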