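# Curated site-map annotation for the nine human linker histone H1 subtypes
# (met-cleaved numbering): per subtype the published positions of
# NetPhos-positive, experimentally known, consensus-motif, Yin-Yang,
# conserved and conserved-substituted Ser/Thr residues, the proposed
# Yin-Yang / FN-Yin-Yang partitions, and the mitotic phosphosites.  Used to
# build the bundled SYNTHETIC benchmark fixture: real subtype sequences are
# not shipped, so H1-like sequences are generated under the constraint that
# every annotated position carries the stated residue (and motif positions a
# planted (S/T)PXK tetramer).

.h1_ann <- function() {
  list(
    `Q02539` = list(subtype = "H1.1", length = 214L,
      S = list(netphos = c(33,41,51,52,53,91,106,114,115,123,135,145,148,164,165),
               experimental = c(1,35,103,183), motif = 183,
               yinyang = c(33,52,53,114,164,165),
               conserved = c(41,43,51,53,60,106,183),
               conserved_sub = c(1,48,52,91,103),
               proposed_yy = c(103,183), proposed_fn = c(41,51,91,104,106,182),
               mitotic = 182, exemplar = numeric()),
      T = list(netphos = c(94,151,161,173,199,203), experimental = 151,
               motif = 151, yinyang = c(161,173,199,203), conserved = 94,
               conserved_sub = c(101,151,11,164,203),
               proposed_yy = 203, proposed_fn = c(94,203),
               mitotic = 152, exemplar = numeric())),
    `P16403` = list(subtype = "H1.2", length = 212L,
      S = list(netphos = c(35,50,54,104,112,149,172,187),
               experimental = c(1,172), motif = 172, yinyang = c(30,50,187),
               conserved = c(1,40,58,77,102,104,172,187),
               conserved_sub = c(35,85,88,112),
               proposed_yy = 187, proposed_fn = numeric(),
               mitotic = 172, exemplar = numeric()),
      T = list(netphos = c(30,91,145,153,166), experimental = 30,
               motif = c(30,145,153), yinyang = c(145,166),
               conserved = c(44,91,95,98), conserved_sub = c(3,153),
               proposed_yy = numeric(), proposed_fn = numeric(),
               mitotic = numeric(), exemplar = numeric())),
    `P16402` = list(subtype = "H1.3", length = 220L,
      S = list(netphos = c(36,51,55,104,113,150,173,188,204),
               experimental = 188, motif = c(173,188),
               yinyang = c(35,51,188,204),
               conserved = c(36,41,51,58,79,89,102,104,188),
               conserved_sub = c(1,86),
               proposed_yy = 188, proposed_fn = 104,
               mitotic = 188, exemplar = 188),
      T = list(netphos = c(18,92,146,154,167,179), experimental = 18,
               motif = c(18,146,154), yinyang = 146,
               conserved = c(3,45,92,96,99), conserved_sub = 154,
               proposed_yy = 146, proposed_fn = c(92,154),
               mitotic = numeric(), exemplar = numeric())),
    `P10412` = list(subtype = "H1.4", length = 218L,
      S = list(netphos = c(26,35,50,54,103,112,150,171,186),
               experimental = c(35,171,186), motif = c(171,186),
               yinyang = c(35,50,186),
               conserved = c(1,35,40,50,54,57,78,85,88,101,103,112,150,171,186),
               conserved_sub = c(172,188),
               proposed_yy = c(35,186), proposed_fn = c(54,103,112,171),
               mitotic = c(171,186), exemplar = 186),
      T = list(netphos = c(17,91,145,153,202), experimental = 17,
               motif = c(17,145,153), yinyang = c(17,145,202),
               conserved = c(3,17,91,95,98,145), conserved_sub = c(141,153,202),
               proposed_yy = c(17,45,202), proposed_fn = c(91,153),
               mitotic = 145, exemplar = 145)),
    `P16401` = list(subtype = "H1.5", length = 225L,
      S = list(netphos = c(17,43,53,106,115,172,188),
               experimental = c(17,172,188), motif = c(17,172),
               yinyang = c(17,43,53), conserved = c(1,43,60,80,104,106,115),
               conserved_sub = c(17,53,88,91,172),
               proposed_yy = 17, proposed_fn = c(106,115,172),
               mitotic = c(17,172), exemplar = 17),
      T = list(netphos = c(10,24,38,94,137,154), experimental = c(137,154),
               motif = c(10,137,154), yinyang = c(10,38), conserved = 38,
               conserved_sub = c(3,8,47,98,101,154),
               proposed_yy = numeric(), proposed_fn = numeric(),
               mitotic = c(137,154), exemplar = numeric())),
    `P07305` = list(subtype = "H1.0", length = 193L,
      S = list(netphos = c(6,18,21,44,48,65,70,97,103,123,130,185),
               experimental = 123, motif = numeric(),
               yinyang = c(6,21,44,97,103,123,130),
               conserved = c(4,6,21,28,44,45,55,65,70,89,91,103,130,170,184,185),
               conserved_sub = c(18,97,115),
               proposed_yy = c(21,44,97,103,123,130), proposed_fn = numeric(),
               mitotic = numeric(), exemplar = numeric()),
      T = list(netphos = c(109,118,134,140,152,161), experimental = numeric(),
               motif = c(118,140,152), yinyang = c(134,161),
               conserved = c(1,5,22,76,77,83,109,118,123,134,140,152),
               conserved_sub = 161,
               proposed_yy = c(134,161), proposed_fn = numeric(),
               mitotic = numeric(), exemplar = numeric())),
    `P22492` = list(subtype = "H1.T", length = 206L,
      S = list(netphos = c(8,42,52,54,86,107,111,118,126,128,137,140,142,165,180,187,204),
               experimental = 177, motif = c(142,180),
               yinyang = c(8,54,118,180,204),
               conserved = c(1,42,44,52,54,61,81,105,107,140,142,165,180),
               conserved_sub = c(8,35,126,128,137,187,189,204),
               proposed_yy = c(54,180,204),
               proposed_fn = c(42,52,107,126,128,137,140,165,187),
               mitotic = 177, exemplar = 177),
      T = list(netphos = c(131,148,158,159,162,203), experimental = c(158,159),
               motif = numeric(), yinyang = c(148,158,159,162,203),
               conserved = c(3,21,99,102,148,158),
               conserved_sub = c(10,48,131,145,203),
               proposed_yy = c(148,158,203), proposed_fn = 31,
               mitotic = c(158,159), exemplar = numeric())),
    `Q81ZA3` = list(subtype = "H1oo", length = 345L,
      S = list(netphos = c(8,11,13,14,16,20,21,23,26,32,42,73,161,211,229,230,235,243,245,246,260,262,263,276,336,337,340,341),
               experimental = numeric(), motif = 276,
               yinyang = c(8,13,14,16,26,73,229,262,336,337,340,341),
               conserved = c(5,8,12,13,20,67,110,118,221,236),
               conserved_sub = c(7,122,219,231,241,249),
               proposed_yy = c(8,13), proposed_fn = numeric(),
               mitotic = numeric(), exemplar = numeric()),
      T = list(netphos = c(72,194,256,278,319), experimental = numeric(),
               motif = numeric(), yinyang = c(256,319),
               conserved = c(66,81,97,116,231), conserved_sub = c(19,209),
               proposed_yy = numeric(), proposed_fn = numeric(),
               mitotic = numeric(), exemplar = numeric())),
    `Q92522` = list(subtype = "H1.X", length = 212L,
      S = list(netphos = c(31,33,39,92,113,154,171), experimental = c(31,33),
               motif = numeric(), yinyang = 33,
               conserved = c(49,65,66,92,113), conserved_sub = c(27,31,133),
               proposed_yy = numeric(), proposed_fn = numeric(),
               mitotic = c(2,31,33), exemplar = numeric()),
      T = list(netphos = 55, experimental = numeric(), motif = numeric(),
               yinyang = numeric(), conserved = 101,
               conserved_sub = c(12,13,55,87),
               proposed_yy = numeric(), proposed_fn = numeric(),
               mitotic = numeric(), exemplar = numeric())))
}

#' Published H1 subtype site-map annotation
#'
#' Positions (met-cleaved numbering) of annotated Ser/Thr residues per human
#' linker histone H1 subtype: external-predictor-positive (`netphos`),
#' experimentally known, consensus-motif, Yin-Yang, conserved and
#' conserved-substituted columns, proposed Yin-Yang / FN-Yin-Yang
#' partitions, and mitotic phosphosites.  This annotation (not any real
#' sequence) is what the bundled synthetic fixture is built from.
#'
#' @return Named list (by accession-style id) of per-subtype annotations.
#' @export
h1_site_annotations <- function() .h1_ann()

#' Mitotic phosphosites of the H1 subtypes
#'
#' The cell-cycle (mitotic) phosphosites reported for human H1 subtypes, on
#' met-cleaved numbering.  For H1.2-H1.5 each of these positions also sits
#' in the subtype's consensus-motif column, which is what the motif-recovery
#' check exercises.
#'
#' @return data.frame with columns `seq_id`, `subtype`, `residue`, `position`.
#' @export
h1_mitotic_sites <- function() {
  ann <- .h1_ann()
  rows <- list()
  for (id in names(ann)) for (res in c("S", "T")) {
    ps <- ann[[id]][[res]]$mitotic
    if (length(ps))
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = id, subtype = ann[[id]]$subtype, residue = res,
        position = as.integer(ps), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# background composition without S/T/P so that, by construction, every
# Ser/Thr of a fixture sequence is an annotated position and every motif hit
# a planted tetramer
.h1_background <- function() {
  c(K = 0.30, A = 0.27, G = 0.08, V = 0.07, E = 0.06, R = 0.05, L = 0.05,
    N = 0.04, D = 0.04, Q = 0.02, I = 0.02)
}

.plant_subtype <- function(id, ann, seed) {
  L <- ann$length
  res <- rep(NA_character_, L)
  dropped <- character()
  claim <- function(pos, ch, tag) {
    if (pos < 1L || pos > L) { dropped <<- c(dropped, sprintf("%s:%s%d[%s] out of range", id, ch, pos, tag)); return(FALSE) }
    if (!is.na(res[pos]) && res[pos] != ch) {
      dropped <<- c(dropped, sprintf("%s:%s%d[%s] collides with %s", id, ch, pos, tag, res[pos]))
      return(FALSE)
    }
    res[pos] <<- ch
    TRUE
  }
  # motif tetramers first: (S/T) P X K
  for (r in c("S", "T")) for (p in ann[[r]]$motif) {
    p <- as.integer(p)
    if (p + 3L > L) { dropped <- c(dropped, sprintf("%s:%s%d[motif] truncated", id, r, p)); next }
    ok <- claim(p, r, "motif") && claim(p + 1L, "P", "motif") &&
      claim(p + 3L, "K", "motif")
    if (!ok) next
  }
  cols <- c("netphos", "experimental", "mitotic", "yinyang", "conserved",
            "conserved_sub", "proposed_yy", "proposed_fn", "exemplar")
  for (tag in cols) for (r in c("S", "T")) for (p in ann[[r]][[tag]])
    claim(as.integer(p), r, tag)
  # block accidental motifs: a planted non-motif S/T never gets P at +1
  motif_pos <- as.integer(c(ann$S$motif, ann$T$motif))
  st <- which(res %in% c("S", "T"))
  for (p in setdiff(st, motif_pos))
    if (p + 1L <= L && is.na(res[p + 1L])) res[p + 1L] <- "A"
  # H1-like background (no S/T/P) elsewhere
  bg <- .h1_background()
  free <- which(is.na(res))
  set.seed(seed)
  res[free] <- sample(names(bg), length(free), replace = TRUE, prob = bg)
  list(residues = res, dropped = dropped)
}

.membership <- function(ann, res_final, tag) {
  # surviving annotated positions for a column: claimed residue must match
  out <- list(S = integer(), T = integer())
  for (r in c("S", "T")) {
    ps <- as.integer(ann[[r]][[tag]])
    out[[r]] <- ps[ps >= 1L & ps <= length(res_final) & res_final[ps] == r]
  }
  out
}

#' Build the bundled synthetic H1 benchmark fixture
#'
#' Generates, deterministically, nine SYNTHETIC H1-subtype stand-in
#' sequences plus the companion evidence, phospho/glyco score and
#' conservation tables.  Each sequence is an H1-like background (Lys/Ala
#' rich, no stray Ser/Thr/Pro) constrained so that every position in the
#' published site-map annotation carries its stated residue and every
#' motif-column position a planted (S/T)PXK tetramer; annotation claims that
#' collide (the published tables are not perfectly self-consistent) are
#' resolved motif-first and reported in `dropped_claims`.  Sequences are
#' written with an initiator Met so that files round-trip through
#' [apply_numbering()] like database entries.  Score values encode the
#' annotation: phospho 0.8 at predictor-positive positions, glyco 0.7 at
#' Yin-Yang (plus literature exemplar) positions, 0.45 inside the
#' FN band, 0.2 elsewhere (thresholds 0.5).
#'
#' @param dir Optional directory; when given, writes
#'   `h1_subtypes_synthetic.fasta`, `h1_evidence_synthetic.tsv`,
#'   `h1_scores_phospho_synthetic.tsv`, `h1_scores_glyco_synthetic.tsv`,
#'   `h1_conservation_synthetic.tsv`.
#' @param seed Seed for the background fill (fixed default keeps the bundled
#'   files reproducible).
#' @return List: `records` (met-cleaved), `raw_records` (with initiator M),
#'   `evidence`, `scores_phospho`, `scores_glyco`, `conservation`,
#'   `dropped_claims`, and `paths` when `dir` was given.
#' @export
build_h1_synthetic_fixture <- function(dir = NULL, seed = 20110712L) {
  ann_all <- .h1_ann()
  records <- list(); raw_records <- list(); dropped <- character()
  ev <- list(); sp <- list(); sg <- list(); cons <- list()
  for (i in seq_along(ann_all)) {
    id <- names(ann_all)[i]
    ann <- ann_all[[id]]
    planted <- .plant_subtype(id, ann, seed + i)
    res <- planted$residues
    dropped <- c(dropped, planted$dropped)
    seq_cleaved <- paste(res, collapse = "")
    raw_records[[id]] <- protein_record(id, paste0("M", seq_cleaved),
                                        name = paste(ann$subtype, "synthetic"))
    records[[id]] <- apply_numbering(raw_records[[id]], "met_cleaved")

    m <- lapply(c(netphos = "netphos", experimental = "experimental",
                  mitotic = "mitotic", yinyang = "yinyang",
                  conserved = "conserved", conserved_sub = "conserved_sub",
                  proposed_fn = "proposed_fn", exemplar = "exemplar"),
                function(tag) .membership(ann, res, tag))
    st <- which(res %in% c("S", "T"))
    resv <- res[st]
    in_col <- function(col) mapply(function(p, r) p %in% m[[col]][[r]], st, resv)
    ev_pos <- sort(unique(c(m$experimental$S, m$experimental$T,
                            m$mitotic$S, m$mitotic$T)))
    if (length(ev_pos))
      ev[[id]] <- data.frame(seq_id = id, position = ev_pos,
                             residue = res[ev_pos], source = "experimental",
                             provenance = "synthetic_curated",
                             stringsAsFactors = FALSE)
    sp[[id]] <- data.frame(seq_id = id, position = st, residue = resv,
                           predictor = "phospho",
                           score = ifelse(in_col("netphos"), 0.8, 0.2),
                           threshold = 0.5, stringsAsFactors = FALSE)
    g <- ifelse(in_col("yinyang") | in_col("exemplar"), 0.7,
                ifelse(in_col("proposed_fn"), 0.45, 0.2))
    sg[[id]] <- data.frame(seq_id = id, position = st, residue = resv,
                           predictor = "glyco", score = g, threshold = 0.5,
                           stringsAsFactors = FALSE)
    cl <- ifelse(in_col("conserved"), "conserved",
                 ifelse(in_col("conserved_sub"), "conserved_substituted",
                        "not_conserved"))
    cons[[id]] <- data.frame(seq_id = id, position = st, residue = resv,
                             class = cl,
                             support = ifelse(cl == "conserved", 1,
                                              ifelse(cl == "conserved_substituted", 0.75, 0.25)),
                             stringsAsFactors = FALSE)
  }
  out <- list(records = records, raw_records = raw_records,
              evidence = do.call(rbind, ev),
              scores_phospho = do.call(rbind, sp),
              scores_glyco = do.call(rbind, sg),
              conservation = do.call(rbind, cons),
              dropped_claims = dropped)
  rownames(out$evidence) <- rownames(out$scores_phospho) <-
    rownames(out$scores_glyco) <- rownames(out$conservation) <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stop(sprintf("cannot create directory %s", dir), call. = FALSE)
    paths <- list(
      fasta = file.path(dir, "h1_subtypes_synthetic.fasta"),
      evidence = file.path(dir, "h1_evidence_synthetic.tsv"),
      scores_phospho = file.path(dir, "h1_scores_phospho_synthetic.tsv"),
      scores_glyco = file.path(dir, "h1_scores_glyco_synthetic.tsv"),
      conservation = file.path(dir, "h1_conservation_synthetic.tsv"))
    write_fasta(out$raw_records, paths$fasta)
    write_site_table(out$evidence, paths$evidence)
    write_score_table(out$scores_phospho, paths$scores_phospho)
    write_score_table(out$scores_glyco, paths$scores_glyco)
    write_conservation_table(out$conservation, paths$conservation)
    out$paths <- paths
  }
  out
}

#' Path to a bundled synthetic H1 fixture file
#' @param file File name under the package's `extdata` (default the FASTA).
#' @return Absolute path.
#' @export
h1_fixture_path <- function(file = "h1_subtypes_synthetic.fasta") {
  p <- system.file("extdata", file, package = "yinyang")
  if (!nzchar(p)) stop(sprintf("no bundled fixture file '%s'", file), call. = FALSE)
  p
}
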