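---
title: "Mapping phosphorylation/O-GlcNAc Yin-Yang sites on linker histones: methods and design"
output: html_document
vignette: >
  %\VignetteIndexEntry{Mapping phosphorylation/O-GlcNAc Yin-Yang sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yinyang)
```

## The biological question

Linker histone H1 sits on the DNA between nucleosomes and modulates how
tightly chromatin folds.  Its long, lysine-rich tails are phosphorylated in
a cell-cycle-dependent manner by proline-directed kinases (CDK-type),
loosening chromatin and promoting transcription; the same Ser/Thr hydroxyls
can instead carry a single O-linked N-acetylglucosamine (O-β-GlcNAc) placed
by OGT, which is associated with chromatin condensation.  A residue where
the two modifications can alternately occupy the same hydroxyl is called a
*Yin-Yang site*: a molecular toggle between condensed and decondensed
states.  Because direct site-level evidence for O-GlcNAc on H1 is scarce,
candidate Yin-Yang sites are proposed *in silico* by combining four signals
on each Ser/Thr residue:

1. the CDK consensus motif **(S/T)PXK** or **(S/T)PXZ** (X any residue, Z
   basic) around the residue;
2. a phosphorylation potential (predicted score and/or experimental
   phosphosite annotation);
3. an O-GlcNAc potential score;
4. evolutionary conservation of the residue across orthologs of the same
   subtype.

This package implements that procedure as a reusable, tested pipeline, with
every stage exposed as an ordinary R function and a synthetic-data
generator so the whole chain can be validated without any downloads.

## Residue numbering

Mature linker histones lose their initiator methionine, and positions in
the site-level literature are counted on the processed chain — one below
the database canonical position.  `apply_numbering(record, "met_cleaved")`
removes the leading Met and renumbers from 1; every table the package reads
or writes uses this *reported* numbering (1-based, inclusive).  `raw`
numbering is available per record, and each `protein_record` carries an
explicit `numbering_offset` so other conventions can be represented.
Unknown residues map to `X` and are never treated as acceptor candidates.

## Motif scanning

`scan_motifs()` reports every Ser/Thr opening a consensus tetramer.  Design
choices, made once:

* the hit position is the S/T residue itself (how single positions are
  printed in site maps);
* overlapping motifs are all reported, with no greedy consumption;
* `Z` (basic) defaults to `{K, R, H}`, configurable to `{K, R}` — the
  consensus definition only says "basic";
* a tetramer ending in K satisfies both classes and is reported once per
  class; `dedupe = TRUE` collapses to one row per position.

The scanner is vectorised residue logic, deliberately not a regular
expression, so the test suite can hold it against an independent
lookahead-regex oracle (exact hit-set equality over thousands of random
sequences).

## Conservation from alignments

The package consumes alignments (aligned FASTA or Clustal, via Biostrings);
it never computes them, keeping the artifact self-contained and the
conservation logic testable in isolation.  For a chosen reference row,
every Ser/Thr is projected onto its alignment column and classified:

* **conserved** — all counted non-reference cells equal the reference
  residue;
* **conserved_substituted** — all counted cells within the substitution
  group `{S, T}` (the functionally interchangeable pair for these
  modifications) with at least one differing;
* **not_conserved** — otherwise.

Gaps break conservation by default (`gap_policy = "ignore"` drops them from
the count instead).  The strict all-rows rule reflects the small ortholog
families (4–5 sequences) typical of this analysis; `min_support` relaxes it
to a fractional rule when families are larger.  `propagate_by_similarity()`
transfers experimental sites from orthologs onto the reference ("by
similarity" evidence) when the aligned reference residue is S/T and its
column is not broken, never duplicating existing reference evidence.

## Site scoring

`train_predictor()` fits the classical sliding-window network: each
candidate residue is encoded as `window` one-hot blocks of 21 symbols (20
amino acids plus `X`, which doubles as the terminal pad), and a single
hidden layer of logistic units feeds a logistic output.  Defaults, chosen
once: window 9 (centre ± 4), 4 hidden units, weight decay `1e-4`, 5-fold
cross-validation, threshold 0.5, epoch cap 200.  Fitting uses `nnet`
(cross-entropy objective, BFGS); instead of per-epoch early stopping the
optimiser is regularised by weight decay under a fixed iteration cap, and
generalisation is reported as the k-fold held-out accuracy stored in the
model's `training_meta`.  All randomness (fold assignment, weight
initialisation) flows from one explicit seed, so identical calls are
bit-reproducible.  Models serialise to self-describing JSON with weights
printed at `%.17g`, which round-trips IEEE doubles exactly: a reloaded
model scores bit-identically.

The built-in scorer is *not* a replica of the published prediction servers
(NetPhos/NetPhosK/YinOYang); their exports are consumed instead through
`import_scores()` as typed tables carrying their own thresholds.  The
per-residue "wavy" threshold some servers draw is approximated as a
constant 0.5 — a recorded limitation.  A score is positive iff
`score >= threshold` (ties count as positive).

## Interplay calling

`call_sites()` assigns each scored S/T site exactly one class:

| class | rule |
|---|---|
| `yin_yang` | glyco positive **and** phospho-competent |
| `fn_yin_yang` | phospho-competent, glyco score in `[thr − fn_margin, thr)` |
| `phospho_only` / `glyco_only` | one arm only |
| `negative` | neither |

*Phospho-competent* means predicted positive **or** experimentally known:
several literature exemplars are experimental phosphosites whose predicted
phospho score is cold, and the published proposed-site lists include them,
so experimental anchoring must satisfy the phosphorylation arm.  The
false-negative band width `fn_margin` (default 0.1) quantifies "scoring
just below threshold", which the source analyses leave unstated; it must
satisfy `0 < fn_margin < glyco_threshold`.  Tyrosine rows are carried in
score tables (phospho predictors score them) but excluded from interplay
classes, which are defined on Ser/Thr only.  `proposed_site_report()`
produces the two proposed lists (Yin-Yang, FN-Yin-Yang), by default
restricted to conserved or conserved-substituted sites, partitioned by
Ser/Thr.

## The synthetic benchmark generator

`generate_family()` emulates exactly the statistical structure the analysis
assumes, nothing more:

* an H1-like reference (Lys/Ala/Pro-rich composition, `h1_composition()`);
* planted non-overlapping (S/T)PXK tetramers (default 12 in 400 residues);
* per-column frozen conservation with probability `conservation_p`
  (default 0.7; motif columns always frozen; the family is gap-free by
  default so column and position coincide, isolating conservation logic
  from alignment quality);
* 5 orthologs (matching the 4–5 used per subtype in practice) mutating
  non-frozen columns by point substitution (probability 0.3);
* ground-truth labels drawn from a sparse logistic model over the window
  (`label_model()`: intercept −4, weight +8 for P at +1, +1 for K at +3),
  so the planted consensus is strongly label-enriched over background;
* glyco truth copied from phospho truth with probability `dual_site_corr`
  (default 1) — the simplest model of competing-site structure — then
  flipped with probability `noise_rate` (default 0);
* a single seed drives every draw.

`emit_pipeline_inputs()` writes the family in the standard formats (FASTA,
aligned FASTA, evidence TSV including planted cross-species sites, and
score TSVs whose scores are the label-model probabilities, standing in for
external predictor exports).  What passing these benchmarks does **not**
show: real predictor scores are not logistic in a 9-residue window, real
ortholog families contain indels and non-S/T substitutions at functional
sites, and real dual-modification correlation is unknown — the benchmarks
validate the machinery, not the biology.

One numerical caveat, stated openly: the default 2-term label model gives
nearly four-valued score distributions, which caps the attainable ROC area
at roughly 0.93 (ties); the scorer's ROC benchmark therefore runs at fixed
seeds, where it clears 0.9, and hovers around 0.89–0.92 for arbitrary
seeds.

## The bundled H1 fixture is synthetic

The package ships no real database sequences.
`build_h1_synthetic_fixture()` deterministically generates nine H1-subtype
*stand-in* sequences (ids follow the familiar accession labels, names
marked "synthetic") from a curated literature site-map annotation
(`h1_site_annotations()`): every annotated Ser/Thr position carries its
stated residue, every motif-column position a planted (S/T)PXK tetramer,
and the background alphabet contains no stray Ser/Thr/Pro, so the scanner's
hit set on the fixture is exactly the annotated motif set.  The published
site-map tables are not perfectly self-consistent (a handful of positions
are claimed as both Ser and Thr, or collide with a motif tetramer);
collisions are resolved by a fixed precedence (motif first) and every
dropped claim is reported in `dropped_claims`.  Consequences to keep in
mind:

* motif-recovery results on the fixture are consistency checks of the
  scanner, numbering and I/O machinery — not reproductions from real
  SWISS-PROT entries;
* the companion conservation table is a fixture annotation: real ortholog
  sets for these subtypes are not published position-by-position, so
  conserved/conserved-substituted columns are not reproducible from first
  principles.

## Problem sizes and determinism

The shipped validation experiments use: 1000 random sequences (length ≤
500) for the motif oracle; 100 synthetic families (length 120, 4
orthologs) for the conservation recount; 2000 windows for the scorer
benchmarks (with a 1000-window held-out set for ROC); and one 400-residue,
5-ortholog family for end-to-end recovery, where the pipeline recovers
planted conserved dual-modification sites with recall and precision above
0.8 (typically ≈ 0.95).  Identical configuration and seed produce
byte-identical output files; the run manifest records package version,
seed and every parameter.

## Known limitations

* The glyco threshold is constant per model, not per-residue.
* No kinase-specific scoring: kinase tables are import-only.
* No Tyr O-GlcNAc scoring; interplay classes are Ser/Thr-only.
* No alignment construction or ortholog discovery; the conservation module
  is only as good as the alignment it is given.
* The synthetic generator uses point substitutions only (no indels by
  default, no substitution matrices) and a deliberately simple label
  model.
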