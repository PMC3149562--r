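mk_scores <- function(pos, res, score, predictor, id = "p1", thr = 0.5) {
  data.frame(seq_id = id, position = as.integer(pos), residue = res,
             predictor = predictor, score = score, threshold = thr,
             stringsAsFactors = FALSE)
}

test_that("interplay params are validated", {
  expect_error(interplay_params(fn_margin = 0), "fn_margin")
  expect_error(interplay_params(fn_margin = 0.6, glyco_threshold = 0.5),
               "fn_margin")
  expect_silent(interplay_params())
})

test_that("score combinations map to the documented classes", {
  p <- mk_scores(c(1, 2, 3, 4, 5), c("S", "T", "S", "S", "T"),
                 c(0.8, 0.9, 0.9, 0.2, 0.1), "phospho")
  g <- mk_scores(c(1, 2, 3, 4, 5), c("S", "T", "S", "S", "T"),
                 c(0.6, 0.45, 0.2, 0.7, 0.1), "glyco")
  calls <- call_sites(p, g)
  expect_equal(calls$class,
               c("yin_yang", "fn_yin_yang", "phospho_only", "glyco_only",
                 "negative"))
})

test_that("an experimentally known phosphosite with positive glyco score is yin_yang", {
  p <- mk_scores(188, "S", 0.2, "phospho", id = "P16402")
  g <- mk_scores(188, "S", 0.7, "glyco", id = "P16402")
  ev <- data.frame(seq_id = "P16402", position = 188L, residue = "S",
                   source = "experimental", provenance = "elm",
                   stringsAsFactors = FALSE)
  calls <- call_sites(p, g, evidence = ev)
  expect_equal(calls$class, "yin_yang")
  expect_true(calls$experimental)
})

test_that("the literature exemplar sites come out as yin_yang with experimental flags", {
  fx <- build_h1_synthetic_fixture()
  calls <- call_sites(fx$scores_phospho, fx$scores_glyco, fx$evidence,
                      fx$conservation)
  exemplars <- data.frame(
    seq_id = c("P16402", "P10412", "P10412", "P16401", "P22492"),
    position = c(188L, 186L, 145L, 17L, 177L),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(exemplars))) {
    row <- calls[calls$seq_id == exemplars$seq_id[i] &
                   calls$position == exemplars$position[i], ]
    expect_equal(row$class, "yin_yang", info = exemplars$seq_id[i])
    expect_true(row$experimental, info = exemplars$seq_id[i])
  }
})

test_that("classes are exhaustive, mutually exclusive and match the rule oracle", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    pos <- sort(sample(1:200, n))
    res <- sample(c("S", "T"), n, replace = TRUE)
    p <- mk_scores(pos, res, round(runif(n), 3), "phospho")
    g <- mk_scores(pos, res, round(runif(n), 3), "glyco")
    # drop some rows so single-arm sites occur
    p2 <- p[runif(n) > 0.2, ]; g2 <- g[runif(n) > 0.2, ]
    ev_idx <- which(runif(n) < 0.2)
    ev <- data.frame(seq_id = rep("p1", length(ev_idx)),
                     position = pos[ev_idx], residue = res[ev_idx],
                     source = rep("experimental", length(ev_idx)),
                     provenance = rep("x", length(ev_idx)),
                     stringsAsFactors = FALSE)
    calls <- call_sites(p2, g2, evidence = ev)
    expect_setequal(calls$position, union(p2$position, g2$position))
    for (i in seq_len(nrow(calls)))
      expect_equal(calls$class[i],
                   rule_based_class(calls$phospho_score[i],
                                    calls$glyco_score[i],
                                    calls$experimental[i]))
  }
})

test_that("fn band widens monotonically and yin_yang shrinks with the glyco threshold", {
  set.seed(37)
  n <- 60
  pos <- 1:n
  res <- sample(c("S", "T"), n, replace = TRUE)
  p <- mk_scores(pos, res, runif(n), "phospho")
  g <- mk_scores(pos, res, runif(n), "glyco")
  margins <- c(0.05, 0.1, 0.2, 0.3)
  fn_counts <- vapply(margins, function(m)
    sum(call_sites(p, g, params = interplay_params(fn_margin = m))$class ==
          "fn_yin_yang"), 0)
  expect_true(all(diff(fn_counts) >= 0))
  thrs <- c(0.3, 0.5, 0.7, 0.9)
  yy_counts <- vapply(thrs, function(t)
    sum(call_sites(p, g, params = interplay_params(glyco_threshold = t,
                                                   fn_margin = 0.1))$class ==
          "yin_yang"), 0)
  expect_true(all(diff(yy_counts) <= 0))
})

test_that("calls are invariant to input row order and reject bad inputs", {
  set.seed(41)
  n <- 20
  pos <- sample(1:100, n)
  res <- sample(c("S", "T"), n, replace = TRUE)
  p <- mk_scores(pos, res, runif(n), "phospho")
  g <- mk_scores(pos, res, runif(n), "glyco")
  shuffle <- sample(n)
  expect_equal(call_sites(p[shuffle, ], g[rev(shuffle), ]),
               call_sites(p, g))
  expect_error(call_sites(rbind(p, p[1, ]), g), "duplicate")
  g_bad <- g; g_bad$residue[1] <- setdiff(c("S", "T"), g$residue[1])
  expect_error(call_sites(p, g_bad), "conflicting residue")
})

test_that("tyrosine rows are carried in scores but excluded from calls", {
  p <- mk_scores(c(1, 2), c("S", "Y"), c(0.8, 0.9), "phospho")
  g <- mk_scores(1, "S", 0.7, "glyco")
  calls <- call_sites(p, g)
  expect_equal(calls$position, 1L)
})

test_that("the proposed-site report honours the conservation requirement", {
  p <- mk_scores(c(1, 2), c("S", "T"), c(0.8, 0.9), "phospho")
  g <- mk_scores(c(1, 2), c("S", "T"), c(0.7, 0.45), "glyco")
  cons <- data.frame(seq_id = "p1", position = 1:2, residue = c("S", "T"),
                     class = "not_conserved", support = 0,
                     stringsAsFactors = FALSE)
  calls <- call_sites(p, g, conservation_calls = cons)
  rep_on <- proposed_site_report(calls)
  expect_equal(nrow(rep_on$yin_yang), 0L)
  expect_equal(nrow(rep_on$fn_yin_yang), 0L)
  rep_off <- proposed_site_report(
    calls, interplay_params(require_conservation_for_proposed = FALSE))
  expect_equal(rep_off$yin_yang$position, 1L)
  expect_equal(rep_off$fn_yin_yang$position, 2L)
})
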