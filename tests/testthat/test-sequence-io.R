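test_that("FASTA parsing yields validated raw-numbered records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x some description", "mseta"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1L)
  expect_equal(recs$x$id, "x")
  expect_equal(recs$x$sequence, "MSETA")
  expect_equal(recs$x$name, "some description")
  expect_equal(recs$x$numbering_offset, 0L)
})

test_that("FASTA read/write round trip is lossless", {
  f <- withr::local_tempfile(fileext = ".fasta")
  set.seed(41)
  recs <- lapply(1:5, function(i)
    protein_record(sprintf("r%d", i), random_sequence(sample(30:200, 1))))
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(vapply(back, `[[`, "", "sequence"),
               setNames(vapply(recs, `[[`, "", "sequence"),
                        vapply(recs, `[[`, "", "id")))
})

test_that("FASTA errors: empty file, illegal residue named by position", {
  f <- withr::local_tempfile(fileext = ".fasta")
  file.create(f)
  expect_error(read_fasta(f), "empty")
  writeLines(c(">x", "MSBTA"), f)
  expect_error(read_fasta(f), "'B' at position 3")
})

test_that("bundled synthetic H1 fixture has the nine accession-style ids", {
  recs <- read_fasta(h1_fixture_path())
  expect_length(recs, 9L)
  expect_setequal(names(recs),
                  c("Q02539", "P16403", "P16402", "P10412", "P16401",
                    "P07305", "P22492", "Q81ZA3", "Q92522"))
  expect_true(all(vapply(recs, function(r)
    substring(r$sequence, 1, 1) == "M", TRUE)))
})

test_that("met-cleaved numbering drops the initiator Met and renumbers from 1", {
  r <- protein_record("x", "MSETA")
  mc <- apply_numbering(r, "met_cleaved")
  expect_equal(mc$sequence, "SETA")
  expect_equal(residue_at(mc, 1), "S")
  expect_identical(apply_numbering(r, "raw"), r)
  expect_error(apply_numbering(mc, "met_cleaved"), "start with M")
})

test_that("met-cleaved lookup at r equals raw lookup at r+1 for random sequences", {
  set.seed(7)
  for (i in 1:25) {
    raw <- protein_record("x", paste0("M", random_sequence(sample(10:80, 1))))
    mc <- apply_numbering(raw, "met_cleaved")
    for (p in seq_len(length(mc)))
      expect_identical(residue_at(mc, p), residue_at(raw, p + 1L))
  }
})

test_that("site and score tables round trip and are cross-checked", {
  rec <- apply_numbering(protein_record("H1.2", "MASPKKSTA"), "met_cleaved")
  ev <- data.frame(seq_id = "H1.2", position = c(2L, 6L), residue = c("S", "S"),
                   source = c("experimental", "by_similarity"),
                   provenance = c("Phospho.ELM", "ortholog"),
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(ev, f)
  expect_equal(read_site_table(f, records = rec), ev)

  ev_bad <- ev; ev_bad$residue[1] <- "T"
  write_site_table(ev_bad, f)
  expect_error(read_site_table(f, records = rec), "H1.2 position 2")

  sc <- data.frame(seq_id = "H1.2", position = c(2L, 7L), residue = c("S", "T"),
                   predictor = "phospho", score = c(0.98, 0.12),
                   threshold = 0.5, stringsAsFactors = FALSE)
  write_score_table(sc, f)
  expect_equal(read_score_table(f, records = rec), sc)

  sc_bad <- sc; sc_bad$score[2] <- 1.2
  write_score_table(sc_bad, f)
  expect_error(read_score_table(f), "outside \\[0,1\\]")
})

test_that("empty site table reads to an empty typed frame", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("seq_id\tposition\tresidue\tsource\tprovenance", f)
  expect_equal(nrow(read_site_table(f)), 0L)
})

test_that("alignment round trips through aligned FASTA and Clustal", {
  msa <- tiny_msa()
  f <- withr::local_tempfile(fileext = ".afa")
  write_alignment(msa, f)
  back <- read_alignment(f, format = "fasta")
  expect_equal(back$seqs, msa$seqs)
  expect_equal(ungapped_row(back, "human"), "MSTAKSA")

  clu <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL 2.1 multiple sequence alignment", "", "",
               "human           MS-TAKSA",
               "mouse           MSATAKSA",
               "rat             MSATAKTA",
               "                ** *** *", ""),
             clu)
  expect_equal(read_alignment(clu, format = "clustal")$seqs, msa$seqs)
})

test_that("alignment validation rejects ragged rows and single rows", {
  expect_error(multiple_alignment(c("a", "b"), c("MSA", "MSAA")), "length")
  expect_error(multiple_alignment("a", "MSA"), ">= 2 rows")
  expect_error(multiple_alignment(c("a", "a"), c("MSA", "MSA")), "duplicate")
})
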