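# yinyang

Proposes candidate **Yin-Yang sites** — Ser/Thr residues where
phosphorylation and O-β-GlcNAc modification can alternately occupy the same
hydroxyl — on protein sequences, with the human linker histone H1 subtypes
as the motivating system.  Phosphorylation of the H1 tails by
proline-directed (CDK-type) kinases decondenses chromatin; O-GlcNAc on the
same residues is associated with condensation, so residues carrying both
potentials are candidate molecular toggles for chromatin state.

The pipeline combines, per Ser/Thr residue of each sequence:

* **consensus motif scanning** for the CDK motifs `(S/T)PXK` and `(S/T)PXZ`
  (X = any residue, Z = basic, default `{K,R,H}`), hits reported at the S/T
  position;
* **modification scores** — either a built-in sliding-window one-hot neural
  scorer (window *w* = 9, one hidden layer, logistic activations, k-fold
  cross-validated, threshold 0.5) or imported NetPhos/YinOYang-style score
  tables; a site is positive iff `score ≥ threshold`;
* **experimental evidence** (Phospho.ELM-style tables) including
  "by-similarity" transfer of ortholog sites through an alignment;
* **conservation** classified per alignment column as *conserved*,
  *conserved-substituted* (only S↔T varies) or *not conserved*.

Each scored site gets exactly one interplay class:

```
yin_yang      :  glyco ≥ t_g           and  (phospho ≥ t_p  or  experimental)
fn_yin_yang   :  t_g − m ≤ glyco < t_g and  (phospho ≥ t_p  or  experimental)
phospho_only / glyco_only / negative   otherwise
```

with thresholds `t_p = t_g = 0.5` and false-negative margin `m = 0.1` by
default; the proposed-site report keeps the `yin_yang` / `fn_yin_yang`
calls on conserved or conserved-substituted residues, partitioned by
Ser/Thr.

A synthetic-data module generates ortholog families with planted motifs,
frozen conserved columns and correlated phospho/glyco ground truth, so
every stage — and the full pipeline — is validated end to end without any
downloads.  The bundled nine-subtype H1 fixture is **synthetic**: stand-in
sequences built from a curated literature site-map annotation (see the
methods vignette, `vignettes/yinyang-methods.Rmd`).

## Worked example

Scan the H1.2 stand-in for CDK consensus motifs on mature-chain (Met-removed)
numbering:

```r
library(yinyang)
recs <- lapply(read_fasta(h1_fixture_path()), apply_numbering, "met_cleaved")
scan_motifs(recs$P16403)
#>   seq_id position residue motif_class tetramer
#> 1 P16403       30       T       STPXK     TPAK
#> 2 P16403       30       T       STPXZ     TPAK
#> 3 P16403      145       T       STPXK     TPKK
#> 4 P16403      145       T       STPXZ     TPKK
#> 5 P16403      153       T       STPXK     TPLK
#> 6 P16403      153       T       STPXZ     TPLK
#> 7 P16403      172       S       STPXK     SPAK
#> 8 P16403      172       S       STPXZ     SPAK
```

Ser-172 — the mitotic phosphosite of H1.2 — opens an `SPAK` tetramer, and
every tetramer ending in K matches both motif classes (use `dedupe = TRUE`
for one row per position).  Call interplay classes from the bundled score,
evidence and conservation tables and keep the proposed H1.4 sites:

```r
fx <- build_h1_synthetic_fixture()
calls <- call_sites(fx$scores_phospho, fx$scores_glyco, fx$evidence, fx$conservation)
rep <- proposed_site_report(calls)
subset(rep$yin_yang, seq_id == "P10412")
#>    seq_id position residue    class phospho_score glyco_score experimental ...
#> 9  P10412       35       S yin_yang           0.8         0.7         TRUE
#> 10 P10412       50       S yin_yang           0.8         0.7        FALSE
#> 11 P10412      186       S yin_yang           0.8         0.7         TRUE
#> 12 P10412       17       T yin_yang           0.8         0.7         TRUE
#> 13 P10412      145       T yin_yang           0.8         0.7         TRUE
#> 14 P10412      202       T yin_yang           0.8         0.7        FALSE
```

Ser-186 and Thr-145 of H1.4 are experimentally known phosphosites with
positive O-GlcNAc potential — textbook Yin-Yang candidates — while e.g.
Ser-50 is proposed on predicted scores and conservation alone.  The same
stages run from the shell:

```sh
Rscript inst/cli/yinyang.R scan --fasta inst/extdata/h1_subtypes_synthetic.fasta \
        --numbering met_cleaved --motifs stpxk,stpxz --basic KRH --out hits.tsv
Rscript inst/cli/yinyang.R run  --fasta ... --phospho P.tsv --glyco G.tsv \
        --conservation C.tsv --evidence E.tsv --outdir out/
```

`run` writes the full TSV bundle (hits, scores, conservation, calls, site
map, the two proposed-site lists) plus a `manifest.json` with versions,
seed and parameters; identical config and seed give byte-identical files.

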