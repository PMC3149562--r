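YY_CLASSES <- c("yin_yang", "fn_yin_yang", "phospho_only", "glyco_only",
                "negative")

#' Parameters of the Yin-Yang interplay caller
#'
#' @param phospho_threshold Phospho score positive-call threshold in (0,1).
#' @param glyco_threshold O-GlcNAc score positive-call threshold in (0,1).
#' @param fn_margin Width of the false-negative band below the glyco
#'   threshold: a site scoring in `[glyco_threshold - fn_margin,
#'   glyco_threshold)` is still eligible as an FN-Yin-Yang site.  Must
#'   satisfy `0 < fn_margin < glyco_threshold`.
#' @param require_conservation_for_proposed If `TRUE` (default), only
#'   conserved or conserved-substituted sites enter the proposed-site report.
#' @return List of class `interplay_params`.
#' @export
interplay_params <- function(phospho_threshold = 0.5, glyco_threshold = 0.5,
                             fn_margin = 0.1,
                             require_conservation_for_proposed = TRUE) {
  stopifnot(phospho_threshold > 0, phospho_threshold < 1,
            glyco_threshold > 0, glyco_threshold < 1)
  if (!(fn_margin > 0 && fn_margin < glyco_threshold))
    stop("fn_margin must satisfy 0 < fn_margin < glyco_threshold", call. = FALSE)
  structure(list(phospho_threshold = phospho_threshold,
                 glyco_threshold = glyco_threshold,
                 fn_margin = fn_margin,
                 require_conservation_for_proposed =
                   isTRUE(require_conservation_for_proposed)),
            class = "interplay_params")
}

.dedupe_check <- function(scores, what) {
  if (!nrow(scores)) return(invisible(TRUE))
  key <- paste(scores$seq_id, scores$position)
  if (anyDuplicated(key))
    stop(sprintf("duplicate %s score rows for %s", what,
                 key[duplicated(key)][1]), call. = FALSE)
  invisible(TRUE)
}

#' Call phosphorylation/O-GlcNAc interplay classes per Ser/Thr site
#'
#' Combines phospho and glyco score tables with experimental evidence,
#' conservation calls and motif hits into one mutually exclusive class per
#' scored S/T position:
#' \describe{
#'   \item{yin_yang}{glyco positive and phospho-competent (score above the
#'     phospho threshold or experimentally known phosphosite).}
#'   \item{fn_yin_yang}{phospho-competent but glyco score falling just below
#'     threshold, within `fn_margin` (the false-negative band).}
#'   \item{phospho_only / glyco_only}{one arm positive, the other cold.}
#'   \item{negative}{neither arm positive.}
#' }
#' Tyrosine score rows are carried in inputs but excluded from interplay
#' classes.  Classification thresholds are taken from `params`.
#'
#' @param scores_phospho,scores_glyco Score data.frames
#'   ([read_score_table()] shape); at most one row per (seq_id, position)
#'   each.
#' @param evidence Optional site-evidence data.frame.
#' @param conservation_calls Optional data.frame from [conserved_sites()]
#'   (or the same TSV shape).
#' @param motif_hits Optional data.frame from [scan_motifs()].
#' @param params An [interplay_params()].
#' @return data.frame sorted by (seq_id, position) with columns `seq_id`,
#'   `position`, `residue`, `class`, `phospho_score`, `glyco_score`,
#'   `motif_hit`, `conservation`, `experimental`, `by_similarity`.
#' @export
call_sites <- function(scores_phospho, scores_glyco, evidence = NULL,
                       conservation_calls = NULL, motif_hits = NULL,
                       params = interplay_params()) {
  stopifnot(inherits(params, "interplay_params"))
  sp <- scores_phospho[scores_phospho$residue %in% c("S", "T"), , drop = FALSE]
  sg <- scores_glyco[scores_glyco$residue %in% c("S", "T"), , drop = FALSE]
  .dedupe_check(sp, "phospho")
  .dedupe_check(sg, "glyco")

  key <- function(df) paste(df$seq_id, df$position)
  all_keys <- union(key(sp), key(sg))
  if (!length(all_keys))
    return(data.frame(seq_id = character(), position = integer(),
                      residue = character(), class = character(),
                      phospho_score = numeric(), glyco_score = numeric(),
                      motif_hit = logical(), conservation = character(),
                      experimental = logical(), by_similarity = logical(),
                      stringsAsFactors = FALSE))
  take <- function(df, col, keys, default = NA) {
    out <- rep(default, length(keys))
    m <- match(keys, key(df))
    out[!is.na(m)] <- df[[col]][m[!is.na(m)]]
    out
  }
  seq_id <- sub(" [^ ]+$", "", all_keys)
  position <- as.integer(sub("^.* ", "", all_keys))
  res_p <- take(sp, "residue", all_keys, NA_character_)
  res_g <- take(sg, "residue", all_keys, NA_character_)
  both <- !is.na(res_p) & !is.na(res_g)
  if (any(both & res_p != res_g)) {
    i <- which(both & res_p != res_g)[1]
    stop(sprintf("conflicting residue letters for %s position %d (%s vs %s)",
                 seq_id[i], position[i], res_p[i], res_g[i]), call. = FALSE)
  }
  residue <- ifelse(is.na(res_p), res_g, res_p)
  p_score <- take(sp, "score", all_keys, NA_real_)
  g_score <- take(sg, "score", all_keys, NA_real_)

  flag_at <- function(df, keep = TRUE) {
    if (is.null(df) || !nrow(df)) return(rep(FALSE, length(all_keys)))
    df <- df[keep, , drop = FALSE]
    all_keys %in% paste(df$seq_id, df$position)
  }
  experimental <- flag_at(evidence,
                          if (is.null(evidence)) TRUE
                          else evidence$source == "experimental")
  by_similarity <- flag_at(evidence,
                           if (is.null(evidence)) TRUE
                           else evidence$source == "by_similarity")
  motif_hit <- flag_at(motif_hits)
  conservation <- if (is.null(conservation_calls)) rep(NA_character_, length(all_keys))
                  else take(conservation_calls, "class", all_keys, NA_character_)

  # residue letter consistency against annotation inputs
  for (ann in list(evidence, conservation_calls, motif_hits)) {
    if (is.null(ann) || !nrow(ann)) next
    m <- match(paste(ann$seq_id, ann$position), all_keys)
    hit <- which(!is.na(m))
    bad <- hit[ann$residue[hit] != residue[m[hit]]]
    if (length(bad))
      stop(sprintf("conflicting residue letters for %s position %d",
                   ann$seq_id[bad[1]], ann$position[bad[1]]), call. = FALSE)
  }

  p_pos <- !is.na(p_score) & p_score >= params$phospho_threshold
  phospho_arm <- p_pos | experimental
  g_pos <- !is.na(g_score) & g_score >= params$glyco_threshold
  g_fn <- !is.na(g_score) & !g_pos &
    g_score >= params$glyco_threshold - params$fn_margin
  cls <- ifelse(phospho_arm & g_pos, "yin_yang",
         ifelse(phospho_arm & g_fn, "fn_yin_yang",
         ifelse(phospho_arm, "phospho_only",
         ifelse(g_pos, "glyco_only", "negative"))))

  out <- data.frame(seq_id = seq_id, position = position, residue = residue,
                    class = cls, phospho_score = p_score,
                    glyco_score = g_score, motif_hit = motif_hit,
                    conservation = conservation, experimental = experimental,
                    by_similarity = by_similarity, stringsAsFactors = FALSE)
  out <- out[order(out$seq_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Proposed interplay-site report (Yin-Yang and FN-Yin-Yang lists)
#'
#' Filters the calls down to the two proposed-site lists, optionally
#' restricted to conserved / conserved-substituted residues, keeping the
#' residue column so each list can be partitioned into its Ser and Thr rows.
#'
#' @param calls data.frame from [call_sites()].
#' @param params An [interplay_params()].
#' @return List with data.frames `yin_yang` and `fn_yin_yang`.
#' @export
proposed_site_report <- function(calls, params = interplay_params()) {
  stopifnot(inherits(params, "interplay_params"))
  keep <- if (params$require_conservation_for_proposed)
    !is.na(calls$conservation) &
      calls$conservation %in% c("conserved", "conserved_substituted")
  else rep(TRUE, nrow(calls))
  pick <- function(cl) {
    df <- calls[keep & calls$class == cl, , drop = FALSE]
    df <- df[order(df$seq_id, match(df$residue, c("S", "T")), df$position), ,
             drop = FALSE]
    rownames(df) <- NULL
    df
  }
  list(yin_yang = pick("yin_yang"), fn_yin_yang = pick("fn_yin_yang"))
}
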