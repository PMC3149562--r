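CONS_CLASSES <- c("conserved", "conserved_substituted", "not_conserved")

#' Classify one alignment column against a reference Ser/Thr residue
#'
#' A column is `conserved` when every counted non-reference cell equals the
#' reference residue, `conserved_substituted` when every counted cell stays
#' within the substitution group (default the functionally interchangeable
#' pair S/T) with at least one differing, and `not_conserved` otherwise.
#' Under the default gap policy (`"break"`) a gap in any row breaks
#' conservation; with `"ignore"` gapped cells are dropped from the count.
#'
#' @param column Character vector of non-reference cells (residues, possibly
#'   gaps `-`).
#' @param ref_residue Reference residue, S or T.
#' @param group Substitution group (default `c("S","T")`).
#' @param gap_policy `"break"` or `"ignore"`.
#' @param min_support Fraction of counted cells that must satisfy the class
#'   rule; 1 is the strict all-rows rule.
#' @return List with `class` and `support` (fraction of counted cells equal
#'   to the reference residue).
#' @export
classify_column <- function(column, ref_residue, group = c("S", "T"),
                            gap_policy = c("break", "ignore"),
                            min_support = 1) {
  gap_policy <- match.arg(gap_policy)
  if (length(column) == 0L) stop("empty column", call. = FALSE)
  if (!ref_residue %in% c("S", "T"))
    stop("ref_residue must be S or T", call. = FALSE)
  stopifnot(min_support > 0, min_support <= 1)
  counted <- column
  if (gap_policy == "ignore") counted <- counted[counted != GAP]
  if (length(counted) == 0L)
    return(list(class = "not_conserved", support = 0))
  # under "break" a gap cell counts and never matches anything
  eq <- counted == ref_residue
  in_group <- counted %in% group
  support <- mean(eq)
  cls <- if (mean(eq) >= min_support) "conserved"
         else if (mean(in_group) >= min_support && any(!eq)) "conserved_substituted"
         else "not_conserved"
  list(class = cls, support = support)
}

#' Conservation calls for every Ser/Thr of a reference row in an MSA
#'
#' Walks the ungapped reference sequence, maps each S/T residue to its
#' alignment column, classifies the column with [classify_column()] and
#' reports the call at the reference's reported numbering.
#'
#' @param msa A [multiple_alignment()].
#' @param ref_id Reference row id.
#' @param numbering_offset Offset added to the reference raw position to give
#'   reported positions (0 when alignment rows already use the reported
#'   convention).
#' @inheritParams classify_column
#' @return data.frame with columns `seq_id`, `position`, `residue`, `class`,
#'   `support`.
#' @export
conserved_sites <- function(msa, ref_id, numbering_offset = 0L,
                            group = c("S", "T"),
                            gap_policy = c("break", "ignore"),
                            min_support = 1) {
  stopifnot(inherits(msa, "multiple_alignment"))
  gap_policy <- match.arg(gap_policy)
  if (!ref_id %in% msa$ids)
    stop(sprintf("reference '%s' not in alignment", ref_id), call. = FALSE)
  cols <- .row_pos_to_col(msa, ref_id)
  ref_chars <- .seq_chars(ungapped_row(msa, ref_id))
  other_ids <- setdiff(msa$ids, ref_id)
  mat <- do.call(rbind, lapply(msa$seqs[other_ids], .seq_chars))
  st <- which(ref_chars %in% c("S", "T"))
  calls <- lapply(st, function(p) {
    cc <- classify_column(mat[, cols[p]], ref_chars[p], group = group,
                          gap_policy = gap_policy, min_support = min_support)
    data.frame(seq_id = ref_id, position = p + as.integer(numbering_offset),
               residue = ref_chars[p], class = cc$class,
               support = cc$support, stringsAsFactors = FALSE)
  })
  out <- if (length(calls)) do.call(rbind, calls)
         else data.frame(seq_id = character(), position = integer(),
                         residue = character(), class = character(),
                         support = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Transfer experimental sites from orthologs to a reference ("by similarity")
#'
#' A site experimentally known in another species is proposed on the
#' reference when its alignment column maps onto a reference S/T whose column
#' is conserved or conserved-substituted.  Sites already experimentally known
#' on the reference are never duplicated.
#'
#' @param msa A [multiple_alignment()].
#' @param evidence Site-evidence data.frame ([read_site_table()] shape);
#'   positions are reported numbering of their own sequences.
#' @param ref_id Reference row id.
#' @param offsets Named integer vector of numbering offsets per sequence id
#'   (missing ids default to 0).
#' @inheritParams classify_column
#' @return data.frame of new `by_similarity` evidence rows on the reference.
#' @export
propagate_by_similarity <- function(msa, evidence, ref_id,
                                    offsets = integer(),
                                    group = c("S", "T"),
                                    gap_policy = c("break", "ignore"),
                                    min_support = 1) {
  stopifnot(inherits(msa, "multiple_alignment"))
  gap_policy <- match.arg(gap_policy)
  if (!ref_id %in% msa$ids)
    stop(sprintf("reference '%s' not in alignment", ref_id), call. = FALSE)
  off <- function(id) if (id %in% names(offsets)) as.integer(offsets[[id]]) else 0L
  src <- evidence[evidence$seq_id != ref_id, , drop = FALSE]
  if (nrow(src) && !all(src$seq_id %in% msa$ids))
    stop(sprintf("evidence on sequence absent from alignment: %s",
                 paste(setdiff(unique(src$seq_id), msa$ids), collapse = ",")),
         call. = FALSE)
  ref_cols <- .row_pos_to_col(msa, ref_id)
  ref_chars <- .seq_chars(ungapped_row(msa, ref_id))
  col_to_ref <- .row_col_to_pos(msa, ref_id)
  other_ids <- setdiff(msa$ids, ref_id)
  mat <- do.call(rbind, lapply(msa$seqs[other_ids], .seq_chars))
  known <- evidence[evidence$seq_id == ref_id &
                      evidence$source == "experimental", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(src))) {
    sid <- src$seq_id[i]
    raw <- src$position[i] - off(sid)
    cols <- .row_pos_to_col(msa, sid)
    if (raw < 1L || raw > length(cols)) next
    col <- cols[raw]
    ref_raw <- col_to_ref[col]
    if (is.na(ref_raw)) next
    ref_res <- ref_chars[ref_raw]
    if (!ref_res %in% c("S", "T")) next
    cc <- classify_column(mat[, col], ref_res, group = group,
                          gap_policy = gap_policy, min_support = min_support)
    if (cc$class == "not_conserved") next
    ref_pos <- ref_raw + off(ref_id)
    if (ref_pos %in% known$position) next
    out[[length(out) + 1L]] <- data.frame(
      seq_id = ref_id, position = ref_pos, residue = ref_res,
      source = "by_similarity",
      provenance = sprintf("%s:%d", sid, src$position[i]),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) unique(do.call(rbind, out))
         else data.frame(seq_id = character(), position = integer(),
                         residue = character(), source = character(),
                         provenance = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Read / write a conservation-call table (TSV)
#'
#' Columns: `seq_id`, `position`, `residue`, `class` (conserved /
#' conserved_substituted / not_conserved), `support`.
#'
#' @param path TSV path.
#' @return data.frame of conservation calls.
#' @export
read_conservation_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_id", "position", "residue", "class", "support")
  if (!all(need %in% names(df)))
    stop(sprintf("conservation table %s must have columns: %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  df <- df[, need, drop = FALSE]
  df$position <- as.integer(df$position)
  df$support <- as.numeric(df$support)
  if (nrow(df) && !all(df$class %in% CONS_CLASSES))
    stop("unknown conservation class in table", call. = FALSE)
  df
}

#' @rdname read_conservation_table
#' @param calls data.frame of conservation calls.
#' @export
write_conservation_table <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
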