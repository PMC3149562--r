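#' H1-like background residue composition
#'
#' Lysine/alanine/proline-rich frequencies emulating the strongly basic,
#' low-complexity tails of linker histones, with moderate Ser/Thr content so
#' acceptor sites occur at realistic density.
#'
#' @return Named numeric vector of residue frequencies summing to 1.
#' @export
h1_composition <- function() {
  c(K = 0.24, A = 0.22, P = 0.09, S = 0.08, T = 0.06, G = 0.05, V = 0.05,
    E = 0.04, R = 0.03, L = 0.03, N = 0.03, D = 0.03, I = 0.02, Q = 0.02,
    F = 0.01)
}

#' Sparse logistic label model over window cells
#'
#' Ground-truth modification labels are drawn from a logistic model on the
#' residue window around each acceptor: `logit(p) = intercept + sum of
#' weights of matching (offset, residue) cells`.  The default rewards the
#' proline-directed context (P at +1, K at +3), mirroring the consensus the
#' motif scanner targets, so planted motifs are strongly label-enriched over
#' background.
#'
#' @param intercept Baseline log-odds.
#' @param offsets,residues,weights Parallel vectors defining the non-zero
#'   window-cell weights.
#' @return List of class `yy_label_model`.
#' @export
label_model <- function(intercept = -4,
                        offsets = c(1L, 3L),
                        residues = c("P", "K"),
                        weights = c(8, 1)) {
  stopifnot(length(offsets) == length(residues),
            length(residues) == length(weights))
  structure(list(intercept = intercept,
                 terms = data.frame(offset = as.integer(offsets),
                                    residue = as.character(residues),
                                    weight = as.numeric(weights),
                                    stringsAsFactors = FALSE)),
            class = "yy_label_model")
}

.label_prob <- function(model, chars, positions) {
  vapply(positions, function(i) {
    eta <- model$intercept
    for (j in seq_len(nrow(model$terms))) {
      at <- i + model$terms$offset[j]
      if (at >= 1L && at <= length(chars) &&
          chars[at] == model$terms$residue[j])
        eta <- eta + model$terms$weight[j]
    }
    plogis(eta)
  }, numeric(1))
}

#' Configuration of a synthetic ortholog family
#'
#' Defines the study conditions every pipeline stage is validated under: an
#' H1-like reference sequence, a small ortholog family (the real analysis
#' used 4-5 orthologs per subtype) with per-column frozen conservation,
#' planted (S/T)PXK consensus motifs, and correlated phospho/glyco ground
#' truth drawn from logistic label models.
#'
#' @param n_orthologs Number of non-reference family members (default 5).
#' @param length Reference length in residues (default 400).
#' @param composition Residue frequency table (default [h1_composition()]).
#' @param conservation_p Probability a column is frozen across the family
#'   (default 0.7); motif columns are always frozen.
#' @param subst_p Per-column substitution probability in non-frozen columns
#'   of each ortholog (default 0.3).
#' @param n_motifs Planted non-overlapping (S/T)PXK tetramers (default 12).
#' @param phospho_model,glyco_model [label_model()]s for the two arms.
#' @param dual_site_corr Probability the glyco truth of a site is overwritten
#'   by a copy of its phospho truth (1 = fully coupled dual sites).
#' @param noise_rate Independent label-flip probability (default 0).
#' @param evidence_fraction Fraction of true phospho sites exported as
#'   "experimental" evidence (default 0.5).
#' @param n_cross_species Planted ortholog-side experimental sites used to
#'   exercise by-similarity transfer (default 5).
#' @param window Window width assumed by downstream encoders (default 9).
#' @param seed Single seed governing every draw.
#' @return List of class `synthetic_family_config`.
#' @export
synthetic_family_config <- function(n_orthologs = 5L, length = 400L,
                                    composition = h1_composition(),
                                    conservation_p = 0.7, subst_p = 0.3,
                                    n_motifs = 12L,
                                    phospho_model = label_model(),
                                    glyco_model = label_model(),
                                    dual_site_corr = 1, noise_rate = 0,
                                    evidence_fraction = 0.5,
                                    n_cross_species = 5L,
                                    window = 9L, seed = 1L) {
  stopifnot(n_orthologs >= 1L, length >= window,
            conservation_p >= 0, conservation_p <= 1,
            subst_p >= 0, subst_p <= 1,
            dual_site_corr >= 0, dual_site_corr <= 1,
            noise_rate >= 0, noise_rate <= 1,
            evidence_fraction >= 0, evidence_fraction <= 1)
  composition <- composition / sum(composition)
  if (!all(names(composition) %in% AA20))
    stop("composition names must be standard amino acids", call. = FALSE)
  if (n_motifs * 4L > length)
    stop("n_motifs * 4 exceeds sequence length", call. = FALSE)
  structure(list(n_orthologs = as.integer(n_orthologs),
                 length = as.integer(length), composition = composition,
                 conservation_p = conservation_p, subst_p = subst_p,
                 n_motifs = as.integer(n_motifs),
                 phospho_model = phospho_model, glyco_model = glyco_model,
                 dual_site_corr = dual_site_corr, noise_rate = noise_rate,
                 evidence_fraction = evidence_fraction,
                 n_cross_species = as.integer(n_cross_species),
                 window = as.integer(window), seed = as.integer(seed)),
            class = "synthetic_family_config")
}

.sample_comp <- function(comp, n) {
  sample(names(comp), n, replace = TRUE, prob = comp)
}

#' Generate a synthetic ortholog family with planted ground truth
#'
#' Deterministic given `config$seed`.  The reference is drawn from the
#' composition, motif tetramers overwrite random non-overlapping positions,
#' frozen columns are copied verbatim into every ortholog while the rest
#' mutate by point substitution, and phospho/glyco truth labels are drawn
#' from the logistic label models, coupled with probability
#' `dual_site_corr` and flipped with probability `noise_rate`.  The family
#' is gap-free, so alignment columns and reference positions coincide.
#'
#' @param config A [synthetic_family_config()].
#' @return List of class `synthetic_family`: `records` (reference first),
#'   `alignment`, `truth` (per reference S/T position: residue, labels,
#'   model probabilities), `planted_motifs`, `frozen`, `evidence`
#'   (ready-made experimental + cross-species rows),
#'   `planted_cross_species`, and the `config`.
#' @export
generate_family <- function(config) {
  stopifnot(inherits(config, "synthetic_family_config"))
  set.seed(config$seed)
  L <- config$length
  comp <- config$composition
  ref <- .sample_comp(comp, L)

  # plant non-overlapping motif tetramers (bounded retries)
  occupied <- rep(FALSE, L)
  planted <- integer()
  tries <- 0L
  while (length(planted) < config$n_motifs) {
    tries <- tries + 1L
    if (tries > 200L * config$n_motifs)
      stop("could not place motifs without overlap; sequence too short",
           call. = FALSE)
    p <- sample.int(L - 3L, 1L)
    if (any(occupied[p:(p + 3L)])) next
    ref[p] <- sample(c("S", "T"), 1L)
    ref[p + 1L] <- "P"
    ref[p + 2L] <- .sample_comp(comp, 1L)
    ref[p + 3L] <- "K"
    occupied[p:(p + 3L)] <- TRUE
    planted <- c(planted, p)
  }
  planted <- sort(planted)

  frozen <- runif(L) < config$conservation_p
  for (p in planted) frozen[p:(p + 3L)] <- TRUE

  orth <- lapply(seq_len(config$n_orthologs), function(k) {
    s <- ref
    sub <- !frozen & runif(L) < config$subst_p
    s[sub] <- .sample_comp(comp, sum(sub))
    s
  })
  ids <- c("ref", sprintf("ortho%02d", seq_len(config$n_orthologs)))
  seqs <- c(paste(ref, collapse = ""),
            vapply(orth, paste, "", collapse = ""))
  records <- lapply(seq_along(ids), function(i) protein_record(ids[i], seqs[i]))
  names(records) <- ids
  alignment <- multiple_alignment(ids, seqs)

  st <- which(ref %in% c("S", "T"))
  p_ph <- .label_prob(config$phospho_model, ref, st)
  p_gl <- .label_prob(config$glyco_model, ref, st)
  lab_ph <- rbinom(length(st), 1L, p_ph) == 1L
  lab_gl <- rbinom(length(st), 1L, p_gl) == 1L
  copy <- runif(length(st)) < config$dual_site_corr
  lab_gl[copy] <- lab_ph[copy]
  if (config$noise_rate > 0) {
    lab_ph <- xor(lab_ph, runif(length(st)) < config$noise_rate)
    lab_gl <- xor(lab_gl, runif(length(st)) < config$noise_rate)
  }
  truth <- data.frame(position = st, residue = ref[st],
                      phospho = lab_ph, glyco = lab_gl,
                      p_phospho = p_ph, p_glyco = p_gl,
                      stringsAsFactors = FALSE)

  # reference experimental evidence: subsample of true phospho sites
  pos_true <- truth$position[truth$phospho]
  n_ev <- round(config$evidence_fraction * length(pos_true))
  ev_pos <- sort(pos_true[sample.int(length(pos_true), n_ev)])
  evidence <- data.frame(seq_id = "ref", position = ev_pos,
                         residue = ref[ev_pos], source = "experimental",
                         provenance = "synthetic_truth",
                         stringsAsFactors = FALSE)

  # ortholog-side experimental sites on frozen S/T columns (by-similarity
  # transfer targets); gap-free family, so ortholog position == column
  frozen_st <- st[frozen[st]]
  ncs <- min(config$n_cross_species, length(frozen_st))
  cs_pos <- sort(frozen_st[sample.int(length(frozen_st), ncs)])
  cs_org <- ids[-1][sample.int(length(ids) - 1L, ncs, replace = TRUE)]
  planted_cross_species <- data.frame(seq_id = cs_org, position = cs_pos,
                                      ref_position = cs_pos,
                                      stringsAsFactors = FALSE)
  if (ncs > 0L) {
    cs_ev <- data.frame(seq_id = cs_org, position = cs_pos,
                        residue = ref[cs_pos], source = "experimental",
                        provenance = "synthetic_cross_species",
                        stringsAsFactors = FALSE)
    evidence <- rbind(evidence, cs_ev)
  }

  structure(list(records = records, alignment = alignment, truth = truth,
                 planted_motifs = planted, frozen = frozen,
                 evidence = evidence,
                 planted_cross_species = planted_cross_species,
                 config = config),
            class = "synthetic_family")
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf("synthetic_family: %d x %d aa, %d motifs, %d S/T truth sites (%d phospho+, %d dual)\n",
              length(x$records), x$config$length, length(x$planted_motifs),
              nrow(x$truth), sum(x$truth$phospho),
              sum(x$truth$phospho & x$truth$glyco)))
  invisible(x)
}

#' Write a synthetic family as standard pipeline inputs
#'
#' Emits the files every pipeline stage consumes: a FASTA of all family
#' members, the (gap-free) aligned FASTA, the evidence TSV (reference
#' experimental sites plus planted cross-species sites), and phospho/glyco
#' score TSVs whose scores are the label-model probabilities, standing in
#' for external predictor exports.
#'
#' @param family A [generate_family()] result.
#' @param outdir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
emit_pipeline_inputs <- function(family, outdir) {
  stopifnot(inherits(family, "synthetic_family"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory: %s", outdir), call. = FALSE)
  paths <- list(fasta = file.path(outdir, "family.fasta"),
                alignment = file.path(outdir, "family_aln.fasta"),
                evidence = file.path(outdir, "evidence.tsv"),
                scores_phospho = file.path(outdir, "scores_phospho.tsv"),
                scores_glyco = file.path(outdir, "scores_glyco.tsv"))
  write_fasta(family$records, paths$fasta)
  write_alignment(family$alignment, paths$alignment)
  write_site_table(family$evidence, paths$evidence)
  tr <- family$truth
  mk <- function(pred, p) data.frame(seq_id = "ref", position = tr$position,
                                     residue = tr$residue, predictor = pred,
                                     score = p, threshold = 0.5,
                                     stringsAsFactors = FALSE)
  write_score_table(mk("phospho", tr$p_phospho), paths$scores_phospho)
  write_score_table(mk("glyco", tr$p_glyco), paths$scores_glyco)
  paths
}

#' Generate stand-alone window examples for scorer benchmarking
#'
#' Emits `n` window-sized records with an S/T acceptor at the centre plus a
#' labelled example table.  Two tasks:
#' \describe{
#'   \item{`p_plus_one`}{class-balanced and linearly separable: positives
#'     carry P at centre+1, negatives anything else there.}
#'   \item{`label_model`}{windows drawn from the composition, labels drawn
#'     from the logistic [label_model()] -- the noisy recovery benchmark.}
#' }
#'
#' @param n Number of windows.
#' @param window Odd window width (default 9).
#' @param task `"p_plus_one"` or `"label_model"`.
#' @param model [label_model()] used by the `label_model` task.
#' @param composition Residue frequencies (default [h1_composition()]).
#' @param balance Positive fraction for the separable task (default 0.5).
#' @param seed Seed.
#' @return List with `records` (one per window) and `examples`
#'   (`seq_id`, `position`, `label`).
#' @export
generate_window_examples <- function(n = 2000L, window = 9L,
                                     task = c("p_plus_one", "label_model"),
                                     model = label_model(),
                                     composition = h1_composition(),
                                     balance = 0.5, seed = 1L) {
  task <- match.arg(task)
  stopifnot(window %% 2L == 1L, window >= 3L)
  set.seed(as.integer(seed))
  comp <- composition / sum(composition)
  centre <- (window + 1L) %/% 2L
  non_p <- comp[names(comp) != "P"]
  mk <- function(i, force_p) {
    ch <- .sample_comp(comp, window)
    ch[centre] <- sample(c("S", "T"), 1L)
    if (!is.na(force_p))
      ch[centre + 1L] <- if (force_p) "P" else .sample_comp(non_p, 1L)
    ch
  }
  labels <- integer(n)
  records <- vector("list", n)
  ids <- sprintf("w%05d", seq_len(n))
  for (i in seq_len(n)) {
    if (task == "p_plus_one") {
      lab <- as.integer(i <= round(balance * n))
      ch <- mk(i, force_p = lab == 1L)
    } else {
      ch <- mk(i, force_p = NA)
      lab <- rbinom(1L, 1L, .label_prob(model, ch, centre))
    }
    labels[i] <- lab
    records[[i]] <- protein_record(ids[i], paste(ch, collapse = ""))
  }
  names(records) <- ids
  list(records = records,
       examples = data.frame(seq_id = ids, position = centre, label = labels,
                             stringsAsFactors = FALSE))
}
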