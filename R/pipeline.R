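#' Pipeline configuration
#'
#' Collects every input path and option of an end-to-end run.  Per predictor
#' arm exactly one source must be active: an imported score table
#' (`scores_*`) or a trained model file (`model_*`).  Conservation comes
#' either from an alignment (classified here, for the `ref_id` row) or from
#' a pre-computed conservation TSV.
#'
#' @param fasta FASTA of the sequences to analyse.
#' @param outdir Output directory.
#' @param alignment Optional alignment path (aligned FASTA or Clustal).
#' @param alignment_format `"fasta"` or `"clustal"`.
#' @param ref_id Reference row for conservation calls (default: first FASTA
#'   record).
#' @param conservation Optional pre-computed conservation TSV (alternative
#'   to `alignment`).
#' @param evidence Optional site-evidence TSV.
#' @param scores_phospho,scores_glyco Imported score TSVs.
#' @param model_phospho,model_glyco Trained model JSON files
#'   ([save_model()]).
#' @param numbering `"met_cleaved"` or `"raw"`.
#' @param motif_classes,basic_set,dedupe_motifs Motif-scanner options.
#' @param gap_policy,min_support Conservation options.
#' @param params An [interplay_params()].
#' @param seed Seed recorded in the manifest (stages are deterministic).
#' @param verbose Emit stage messages to stderr.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, outdir,
                            alignment = NULL, alignment_format = "fasta",
                            ref_id = NULL, conservation = NULL,
                            evidence = NULL,
                            scores_phospho = NULL, scores_glyco = NULL,
                            model_phospho = NULL, model_glyco = NULL,
                            numbering = c("met_cleaved", "raw"),
                            motif_classes = MOTIF_CLASSES,
                            basic_set = BASIC_DEFAULT,
                            dedupe_motifs = FALSE,
                            gap_policy = "break", min_support = 1,
                            params = interplay_params(),
                            seed = 1L, verbose = FALSE) {
  numbering <- match.arg(numbering)
  for (arm in c("phospho", "glyco")) {
    s <- !is.null(get(paste0("scores_", arm)))
    m <- !is.null(get(paste0("model_", arm)))
    if (s == m)
      stop(sprintf("exactly one of scores_%s / model_%s must be given",
                   arm, arm), call. = FALSE)
  }
  if (!is.null(alignment) && !is.null(conservation))
    stop("give either alignment or conservation, not both", call. = FALSE)
  cfg <- list(fasta = fasta, outdir = outdir, alignment = alignment,
              alignment_format = alignment_format, ref_id = ref_id,
              conservation = conservation, evidence = evidence,
              scores_phospho = scores_phospho, scores_glyco = scores_glyco,
              model_phospho = model_phospho, model_glyco = model_glyco,
              numbering = numbering, motif_classes = motif_classes,
              basic_set = basic_set, dedupe_motifs = isTRUE(dedupe_motifs),
              gap_policy = gap_policy, min_support = min_support,
              params = params, seed = as.integer(seed),
              verbose = isTRUE(verbose))
  for (p in c("fasta", "alignment", "conservation", "evidence",
              "scores_phospho", "scores_glyco", "model_phospho",
              "model_glyco"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop(sprintf("input path for %s does not exist: %s", p, cfg[[p]]),
           call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

.stage <- function(cfg, name, expr) {
  if (cfg$verbose) message(sprintf("[yinyang] stage %s", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
}

#' Per-sequence site map from the stage outputs
#'
#' Pure function of the stage tables: one row per scored S/T site with its
#' predictor calls, motif, evidence, conservation class and interplay class
#' -- the per-subtype site-map layout used to summarise this kind of
#' analysis.
#'
#' @param calls data.frame from [call_sites()].
#' @return data.frame (the calls table with a logical `phospho_positive`,
#'   `glyco_positive` pair added), sorted by (seq_id, position).
#' @export
build_site_map <- function(calls) {
  out <- calls
  out$phospho_positive <- !is.na(out$phospho_score) &
    out$phospho_score >= attr(calls, "phospho_threshold", exact = TRUE) %||% 0.5
  out$glyco_positive <- !is.na(out$glyco_score) &
    out$glyco_score >= attr(calls, "glyco_threshold", exact = TRUE) %||% 0.5
  out <- out[order(out$seq_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full interplay-calling pipeline
#'
#' Reads sequences, applies the numbering convention, scans motifs, obtains
#' phospho/glyco scores (imported tables or trained models), classifies
#' conservation (from an alignment or a pre-computed table), transfers
#' by-similarity evidence, calls interplay classes and writes the TSV
#' bundle: `hits.tsv`, `conservation.tsv`, `scores_phospho.tsv`,
#' `scores_glyco.tsv`, `evidence.tsv`, `calls.tsv`, `site_map.tsv`,
#' `proposed_yin_yang.tsv`, `proposed_fn_yin_yang.tsv` and a JSON
#' `manifest.json` recording versions, seed and parameters.  Identical
#' config and seed give byte-identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisible list with the in-memory stage outputs and `paths`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!dir.exists(cfg$outdir) &&
      !dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory %s", cfg$outdir), call. = FALSE)
  set.seed(cfg$seed)

  records <- .stage(cfg, "sequence_io", {
    recs <- read_fasta(cfg$fasta)
    if (cfg$numbering == "met_cleaved")
      recs <- lapply(recs, apply_numbering, convention = "met_cleaved")
    recs
  })

  hits <- .stage(cfg, "motif_scanner", {
    do.call(rbind, lapply(records, scan_motifs, classes = cfg$motif_classes,
                          basic_set = cfg$basic_set, dedupe = cfg$dedupe_motifs))
  })
  rownames(hits) <- NULL

  ref <- cfg$ref_id %||% records[[1]]$id
  msa <- if (!is.null(cfg$alignment))
    .stage(cfg, "conservation",
           read_alignment(cfg$alignment, format = cfg$alignment_format))
  conservation <- .stage(cfg, "conservation", {
    if (!is.null(msa)) {
      conserved_sites(msa, ref,
                      numbering_offset = records[[ref]]$numbering_offset %||% 0L,
                      gap_policy = cfg$gap_policy,
                      min_support = cfg$min_support)
    } else if (!is.null(cfg$conservation)) {
      read_conservation_table(cfg$conservation)
    } else NULL
  })

  evidence <- .stage(cfg, "evidence", {
    if (is.null(cfg$evidence)) NULL
    else {
      ev <- read_site_table(cfg$evidence)
      if (!is.null(msa)) {
        offs <- setNames(rep(0L, 1L), ref)
        if (ref %in% names(records)) offs[ref] <- records[[ref]]$numbering_offset
        prop <- propagate_by_similarity(msa, ev, ref, offsets = offs,
                                        gap_policy = cfg$gap_policy,
                                        min_support = cfg$min_support)
        rbind(ev[ev$seq_id %in% names(records), , drop = FALSE], prop)
      } else ev[ev$seq_id %in% names(records), , drop = FALSE]
    }
  })

  get_scores <- function(arm) .stage(cfg, paste0("site_predictor_", arm), {
    sc <- cfg[[paste0("scores_", arm)]]
    if (!is.null(sc)) import_scores(sc, records = records)
    else {
      model <- load_model(cfg[[paste0("model_", arm)]])
      out <- do.call(rbind, lapply(records, predict_sites, model = model))
      rownames(out) <- NULL
      out
    }
  })
  scores_phospho <- get_scores("phospho")
  scores_glyco <- get_scores("glyco")

  calls <- .stage(cfg, "interplay_caller",
                  call_sites(scores_phospho, scores_glyco, evidence,
                             conservation, hits, cfg$params))
  attr(calls, "phospho_threshold") <- cfg$params$phospho_threshold
  attr(calls, "glyco_threshold") <- cfg$params$glyco_threshold
  site_map <- build_site_map(calls)
  proposed <- proposed_site_report(calls, cfg$params)

  paths <- list(hits = file.path(cfg$outdir, "hits.tsv"),
                conservation = file.path(cfg$outdir, "conservation.tsv"),
                evidence = file.path(cfg$outdir, "evidence.tsv"),
                scores_phospho = file.path(cfg$outdir, "scores_phospho.tsv"),
                scores_glyco = file.path(cfg$outdir, "scores_glyco.tsv"),
                calls = file.path(cfg$outdir, "calls.tsv"),
                site_map = file.path(cfg$outdir, "site_map.tsv"),
                proposed_yin_yang = file.path(cfg$outdir, "proposed_yin_yang.tsv"),
                proposed_fn_yin_yang = file.path(cfg$outdir, "proposed_fn_yin_yang.tsv"),
                manifest = file.path(cfg$outdir, "manifest.json"))
  wt <- function(df, p) write.table(df, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  wt(hits, paths$hits)
  if (!is.null(conservation)) wt(conservation, paths$conservation)
  if (!is.null(evidence)) wt(evidence, paths$evidence)
  wt(scores_phospho, paths$scores_phospho)
  wt(scores_glyco, paths$scores_glyco)
  wt(calls, paths$calls)
  wt(site_map, paths$site_map)
  wt(proposed$yin_yang, paths$proposed_yin_yang)
  wt(proposed$fn_yin_yang, paths$proposed_fn_yin_yang)

  manifest <- list(
    package = "yinyang",
    version = as.character(packageVersion("yinyang")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    numbering = cfg$numbering,
    motif_classes = cfg$motif_classes,
    basic_set = cfg$basic_set,
    gap_policy = cfg$gap_policy,
    min_support = cfg$min_support,
    params = unclass(cfg$params),
    inputs = Filter(Negate(is.null),
                    cfg[c("fasta", "alignment", "conservation", "evidence",
                          "scores_phospho", "scores_glyco", "model_phospho",
                          "model_glyco")]),
    n_sequences = length(records),
    n_calls = nrow(calls))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(records = records, hits = hits, conservation = conservation,
                 evidence = evidence, scores_phospho = scores_phospho,
                 scores_glyco = scores_glyco, calls = calls,
                 site_map = site_map, proposed = proposed, paths = paths))
}
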