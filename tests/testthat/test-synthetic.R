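test_that("full conservation freezes every column and same seed reproduces the family", {
  cfg <- synthetic_family_config(length = 150L, n_motifs = 4L,
                                 conservation_p = 1, seed = 11L)
  fam <- generate_family(cfg)
  seqs <- vapply(fam$records, `[[`, "", "sequence")
  expect_true(all(seqs == seqs[[1]]))
  calls <- conserved_sites(fam$alignment, "ref")
  expect_true(all(calls$class == "conserved"))

  fam2 <- generate_family(cfg)
  expect_identical(fam, fam2)
})

test_that("planted motifs are recovered exactly when the background is proline-free", {
  comp <- c(K = 0.3, A = 0.3, S = 0.1, T = 0.1, G = 0.1, E = 0.099,
            P = 0.001)
  cfg <- synthetic_family_config(length = 300L, n_motifs = 10L,
                                 composition = comp, seed = 19L)
  # analytic background collision bound: an accidental hit needs a
  # background P one position right of an S/T with K two later
  p <- comp / sum(comp)
  exp_collisions <- 300 * (p[["S"]] + p[["T"]]) * p[["P"]] * p[["K"]]
  expect_lt(exp_collisions, 0.05)
  fam <- generate_family(cfg)
  hits <- scan_motifs(fam$records$ref, classes = "STPXK", dedupe = TRUE)
  expect_identical(sort(hits$position), fam$planted_motifs)
})

test_that("truth bookkeeping is internally consistent", {
  fam <- generate_family(synthetic_family_config(seed = 3L))
  ref <- strsplit(fam$records$ref$sequence, "")[[1]]
  expect_true(all(ref[fam$planted_motifs] %in% c("S", "T")))
  expect_true(all(ref[fam$planted_motifs + 1L] == "P"))
  expect_true(all(ref[fam$planted_motifs + 3L] == "K"))
  expect_true(all(fam$truth$residue %in% c("S", "T")))
  # frozen columns identical across all rows
  mats <- vapply(fam$records, function(r) strsplit(r$sequence, "")[[1]],
                 character(fam$config$length))
  frozen_rows <- mats[fam$frozen, , drop = FALSE]
  expect_true(all(frozen_rows == frozen_rows[, 1]))
  # full coupling and zero noise: glyco truth equals phospho truth
  expect_identical(fam$truth$glyco, fam$truth$phospho)
})

test_that("label prevalence matches the logistic model within binomial error", {
  fam <- generate_family(synthetic_family_config(length = 3000L,
                                                 n_motifs = 30L, seed = 23L))
  expected <- sum(fam$truth$p_phospho)
  sd <- sqrt(sum(fam$truth$p_phospho * (1 - fam$truth$p_phospho)))
  expect_lt(abs(sum(fam$truth$phospho) - expected), 4 * sd)
})

test_that("emitted pipeline inputs re-read losslessly and reflect the truth at zero noise", {
  fam <- generate_family(synthetic_family_config(seed = 31L))
  d <- withr::local_tempdir()
  paths <- emit_pipeline_inputs(fam, d)
  recs <- read_fasta(paths$fasta)
  expect_equal(vapply(recs, `[[`, "", "sequence"),
               vapply(fam$records, `[[`, "", "sequence"))
  aln <- read_alignment(paths$alignment)
  expect_equal(aln$seqs, fam$alignment$seqs)
  ev <- read_site_table(paths$evidence, records = recs)
  truth_pos <- fam$truth$position[fam$truth$phospho]
  ref_ev <- ev[ev$seq_id == "ref", ]
  expect_true(all(ref_ev$position %in% truth_pos))
  sp <- read_score_table(paths$scores_phospho, records = recs["ref"])
  expect_equal(sp$position, fam$truth$position)
  expect_equal(sp$score, fam$truth$p_phospho)
})

test_that("infeasible motif placement errors out", {
  expect_error(synthetic_family_config(length = 20L, n_motifs = 6L),
               "exceeds")
  expect_error(generate_family(synthetic_family_config(length = 48L,
                                                       n_motifs = 12L,
                                                       seed = 1L)),
               "overlap")
})

test_that("window example generator balances the separable task and labels by the model", {
  we <- generate_window_examples(200, task = "p_plus_one", seed = 5)
  expect_equal(sum(we$examples$label), 100L)
  centre <- 5L
  has_p <- vapply(we$examples$seq_id, function(id)
    substring(we$records[[id]]$sequence, centre + 1L, centre + 1L) == "P", TRUE)
  expect_identical(unname(has_p), we$examples$label == 1L)

  wl <- generate_window_examples(500, task = "label_model", seed = 6)
  # labels must be strongly enriched where the model fires
  p_next <- vapply(wl$examples$seq_id, function(id)
    substring(wl$records[[id]]$sequence, centre + 1L, centre + 1L) == "P", TRUE)
  expect_gt(mean(wl$examples$label[p_next]), 0.8)
  expect_lt(mean(wl$examples$label[!p_next]), 0.2)
})
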