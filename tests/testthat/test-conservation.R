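test_that("column classification follows the strict conserved / substituted / broken rules", {
  expect_equal(classify_column(c("S", "S", "S", "S"), "S")$class, "conserved")
  expect_equal(classify_column(c("S", "S", "S", "S"), "S")$support, 1)
  expect_equal(classify_column(c("S", "S", "T", "T"), "S")$class,
               "conserved_substituted")
  expect_equal(classify_column(c("S", "S", "K", "A"), "S")$class,
               "not_conserved")
  expect_error(classify_column(character(), "S"), "empty")
  expect_error(classify_column("S", "K"), "S or T")
})

test_that("gaps break conservation by default but can be ignored", {
  expect_equal(classify_column(c("S", "-", "S"), "S")$class, "not_conserved")
  expect_equal(classify_column(c("S", "-", "S"), "S",
                               gap_policy = "ignore")$class, "conserved")
  expect_equal(classify_column(c("-", "-"), "S", gap_policy = "ignore")$class,
               "not_conserved")
})

test_that("min_support relaxes the all-rows rule", {
  col <- c("S", "S", "S", "A")
  expect_equal(classify_column(col, "S")$class, "not_conserved")
  expect_equal(classify_column(col, "S", min_support = 0.75)$class, "conserved")
})

test_that("identical alignments are fully conserved with support 1", {
  msa <- multiple_alignment(c("a", "b"), c("MSTAKS", "MSTAKS"))
  calls <- conserved_sites(msa, "a")
  expect_equal(nrow(calls), 3L)
  expect_true(all(calls$class == "conserved"))
  expect_true(all(calls$support == 1))
})

test_that("a gap under a reference S column follows the gap policy", {
  msa <- multiple_alignment(c("a", "b", "c"), c("MSTA", "M-TA", "MSTA"))
  calls <- conserved_sites(msa, "a")
  expect_equal(calls$class[calls$position == 2], "not_conserved")
  calls2 <- conserved_sites(msa, "a", gap_policy = "ignore")
  expect_equal(calls2$class[calls2$position == 2], "conserved")
})

test_that("conservation calls equal a brute-force per-column recount on synthetic families", {
  for (i in 1:20) {
    fam <- generate_family(synthetic_family_config(
      length = 120L, n_orthologs = 4L, n_motifs = 3L, seed = 100L + i))
    got <- conserved_sites(fam$alignment, "ref")
    expect_equal(got, brute_force_conservation(fam$alignment, "ref"))
  }
})

test_that("row order of the alignment does not change calls", {
  fam <- generate_family(synthetic_family_config(length = 100L, n_motifs = 2L,
                                                 seed = 5L))
  msa <- fam$alignment
  perm <- multiple_alignment(rev(msa$ids), rev(unname(msa$seqs)))
  expect_equal(conserved_sites(perm, "ref"), conserved_sites(msa, "ref"))
})

test_that("reference position to column mapping is a bijection over non-gap cells", {
  msa <- tiny_msa()
  cols <- yinyang:::.row_pos_to_col(msa, "human")
  back <- yinyang:::.row_col_to_pos(msa, "human")
  expect_equal(back[cols], seq_along(cols))
  expect_false(anyDuplicated(cols) > 0)
  expect_equal(sum(!is.na(back)), nchar(ungapped_row(msa, "human")))
})

test_that("by-similarity transfer lands on conserved aligned S/T only", {
  msa <- multiple_alignment(c("human", "mouse"), c("MSTAK", "MSTAK"))
  ev <- data.frame(seq_id = "mouse", position = 2L, residue = "S",
                   source = "experimental", provenance = "elm",
                   stringsAsFactors = FALSE)
  got <- propagate_by_similarity(msa, ev, "human")
  expect_equal(got$position, 2L)
  expect_equal(got$source, "by_similarity")

  # aligned to a non-acceptor residue: nothing transfers
  msa2 <- multiple_alignment(c("human", "mouse"), c("MATAK", "MSTAK"))
  expect_equal(nrow(propagate_by_similarity(msa2, ev, "human")), 0L)

  # existing human experimental evidence is not duplicated
  ev2 <- rbind(ev, data.frame(seq_id = "human", position = 2L, residue = "S",
                              source = "experimental", provenance = "elm",
                              stringsAsFactors = FALSE))
  expect_equal(nrow(propagate_by_similarity(msa, ev2, "human")), 0L)

  expect_error(propagate_by_similarity(
    msa, transform(ev, seq_id = "rat"), "human"), "absent")
})

test_that("planted cross-species sites transfer exactly per generator bookkeeping", {
  for (s in 1:5) {
    fam <- generate_family(synthetic_family_config(length = 200L,
                                                   n_motifs = 5L,
                                                   seed = 700L + s))
    cs <- fam$planted_cross_species
    ev <- fam$evidence[fam$evidence$provenance == "synthetic_cross_species", ]
    got <- propagate_by_similarity(fam$alignment, fam$evidence, "ref")
    ref_known <- fam$evidence$position[fam$evidence$seq_id == "ref"]
    expected <- sort(unique(cs$ref_position[!cs$ref_position %in% ref_known]))
    expect_equal(sort(got$position), expected)
  }
})
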