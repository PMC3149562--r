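#' Scan a sequence for proline-directed kinase consensus motifs
#'
#' Finds every Ser/Thr residue opening an `(S/T)PXK` or `(S/T)PXZ` tetramer
#' (X any residue, Z a basic residue), the consensus required by the
#' CDK-type kinases that phosphorylate linker histone H1 tails.  The hit
#' position is the S/T residue itself, on the record's reported numbering.
#' Overlapping motifs are all reported; a tetramer ending in K matches both
#' classes when K is in `basic_set` and is then reported once per class
#' unless `dedupe` is set.
#'
#' @param record A [protein_record()].
#' @param classes Motif classes to scan: subset of `"STPXK"`, `"STPXZ"`.
#' @param basic_set Residues accepted as Z; subset of K, R, H.
#' @param dedupe If `TRUE`, collapse to one hit per position (class order
#'   STPXK before STPXZ decides which row is kept).
#' @return data.frame with columns `seq_id`, `position`, `residue`,
#'   `motif_class`, `tetramer`, sorted by position then class.
#' @examples
#' scan_motifs(protein_record("x", "AKSPKKA"))
#' @export
scan_motifs <- function(record, classes = MOTIF_CLASSES,
                        basic_set = BASIC_DEFAULT, dedupe = FALSE) {
  stopifnot(inherits(record, "protein_record"))
  classes <- match.arg(classes, MOTIF_CLASSES, several.ok = TRUE)
  if (!all(basic_set %in% c("K", "R", "H")))
    stop("basic_set must be a subset of {K,R,H}", call. = FALSE)
  chars <- .seq_chars(record$sequence)
  n <- length(chars)
  hits <- data.frame(seq_id = character(), position = integer(),
                     residue = character(), motif_class = character(),
                     tetramer = character(), stringsAsFactors = FALSE)
  if (n >= 4L) {
    i <- seq_len(n - 3L)
    open <- chars[i] %in% c("S", "T") & chars[i + 1L] == "P"
    for (cls in MOTIF_CLASSES[MOTIF_CLASSES %in% classes]) {
      last_ok <- if (cls == "STPXK") chars[i + 3L] == "K"
                 else chars[i + 3L] %in% basic_set
      at <- i[open & last_ok]
      if (length(at)) {
        hits <- rbind(hits, data.frame(
          seq_id = record$id,
          position = at + record$numbering_offset,
          residue = chars[at],
          motif_class = cls,
          tetramer = vapply(at, function(p)
            paste(chars[p:(p + 3L)], collapse = ""), ""),
          stringsAsFactors = FALSE))
      }
    }
  }
  hits <- hits[order(hits$position, match(hits$motif_class, MOTIF_CLASSES)), ,
               drop = FALSE]
  if (dedupe && nrow(hits))
    hits <- hits[!duplicated(hits$position), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Partition motif-hit positions by residue
#'
#' Collapses the hit list of one sequence into the map S -> positions,
#' T -> positions (sorted, de-duplicated) used to print per-subtype motif
#' columns in a site map.
#'
#' @param hits data.frame from [scan_motifs()] (single sequence).
#' @return Named list with sorted integer vectors `S` and `T`.
#' @export
motif_positions_by_residue <- function(hits) {
  if (nrow(hits) && length(unique(hits$seq_id)) > 1L)
    stop("hits come from more than one sequence", call. = FALSE)
  out <- list(S = integer(), T = integer())
  for (res in names(out))
    out[[res]] <- sort(unique(hits$position[hits$residue == res]))
  out
}
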