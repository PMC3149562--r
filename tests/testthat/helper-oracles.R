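# Independent oracles and small generators shared across tests.  Each oracle
# deliberately uses a different mechanism than the implementation it checks.

# regex-based motif oracle: lookahead so overlapping hits are all found
regex_motif_positions <- function(sequence, class, basic = c("K", "R", "H")) {
  pat <- if (class == "STPXK") "(?=[ST]P.K)"
         else sprintf("(?=[ST]P.[%s])", paste(basic, collapse = ""))
  m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

random_sequence <- function(n, alphabet = c("A", "S", "T", "P", "K", "R",
                                            "H", "G", "L", "E")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# plain-loop conservation recount, independent of the vectorised path
brute_force_conservation <- function(msa, ref_id) {
  ref_g <- strsplit(msa$seqs[[ref_id]], "")[[1]]
  others <- lapply(msa$seqs[setdiff(msa$ids, ref_id)],
                   function(s) strsplit(s, "")[[1]])
  out <- list()
  pos <- 0L
  for (col in seq_len(msa$length)) {
    if (ref_g[col] == "-") next
    pos <- pos + 1L
    r <- ref_g[col]
    if (!r %in% c("S", "T")) next
    cells <- vapply(others, `[[`, "", col)
    cls <- if (all(cells == r)) "conserved"
           else if (all(cells %in% c("S", "T"))) "conserved_substituted"
           else "not_conserved"
    out[[length(out) + 1L]] <- data.frame(
      seq_id = ref_id, position = pos, residue = r, class = cls,
      support = mean(cells == r), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# row-by-row re-derivation of the interplay class rules
rule_based_class <- function(p_score, g_score, experimental,
                             p_thr = 0.5, g_thr = 0.5, margin = 0.1) {
  p_arm <- (!is.na(p_score) && p_score >= p_thr) || experimental
  g_pos <- !is.na(g_score) && g_score >= g_thr
  g_fn <- !is.na(g_score) && !g_pos && g_score >= g_thr - margin
  if (p_arm && g_pos) "yin_yang"
  else if (p_arm && g_fn) "fn_yin_yang"
  else if (p_arm) "phospho_only"
  else if (g_pos) "glyco_only"
  else "negative"
}

# score all window-example records with a model, returning the centre score
score_window_examples <- function(model, we) {
  vapply(seq_len(nrow(we$examples)), function(i) {
    sc <- predict_sites(model, we$records[[we$examples$seq_id[i]]])
    sc$score[sc$position == we$examples$position[i]][1]
  }, numeric(1))
}

rank_auc <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

tiny_msa <- function() {
  multiple_alignment(
    c("human", "mouse", "rat"),
    c("MS-TAKSA", "MSATAKSA", "MSATAKTA"))
}
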