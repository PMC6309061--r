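test_that("hypergeometric tail matches the draw-enumeration oracle on worked examples", {
  # f(10,4,5,3): draws with >= 3 of the 5 marked items among C(10,4) = 210
  expect_equal(hg_tail_oracle(10, 4, 5, 3), 55 / 210)
  expect_equal(hypergeom_tail(10, 4, 5, 3), 55 / 210, tolerance = 1e-12)
  # f(5,2,2,2): the single favorable draw out of C(5,2) = 10
  expect_equal(hg_tail_oracle(5, 2, 2, 2), 0.1)
  expect_equal(hypergeom_tail(5, 2, 2, 2), 0.1, tolerance = 1e-12)
  # k = 0 and exhaustive draws are certain events
  expect_equal(hypergeom_tail(97, 13, 41, 0), 1)
  expect_equal(hypergeom_tail(6, 6, 4, 4), 1)
})

test_that("scores are -log10 of the tail", {
  expect_equal(score_disease(10, 4, 5, 3), -log10(55 / 210),
               tolerance = 1e-12)
  expect_equal(score_disease(5, 2, 2, 2), 1, tolerance = 1e-12)
  expect_equal(score_disease(1234, 56, 78, 0), 0)
})

test_that("invalid contingencies are refused with the offending inequality named", {
  expect_error(hypergeom_tail(10, 11, 5, 3), "n > m")
  expect_error(hypergeom_tail(10, 4, 11, 3), "j > m")
  expect_error(hypergeom_tail(10, 4, 5, 6), "k > min")
  expect_error(hypergeom_tail(10, 4, 5, -1), "k")
  expect_error(hypergeom_tail(10.5, 4, 5, 3), "integer")
})

test_that("log-space tail agrees with the distribution-function route", {
  # independent cross-check: stats::phyper upper tail on random contingencies
  set.seed(33)
  for (i in 1:200) {
    m <- sample(2:5000, 1)
    n <- sample(1:m, 1)
    j <- sample(0:m, 1)
    k <- sample(0:min(n, j), 1)
    s_pkg <- -hypergeom_tail(m, n, j, k, log = TRUE) / log(10)
    s_ref <- -stats::phyper(k - 1, j, m - j, n, lower.tail = FALSE,
                            log.p = TRUE) / log(10)
    expect_lt(abs(s_pkg - s_ref), 1e-9 * max(1, abs(s_ref)),
              label = sprintf("score gap at m=%d n=%d j=%d k=%d", m, n, j, k))
  }
})

test_that("score is monotone in k and antitone in j", {
  set.seed(91)
  for (i in 1:50) {
    m <- sample(20:2000, 1)
    n <- sample(2:min(m, 200), 1)
    j <- sample(5:m, 1)
    ks <- 0:min(n, j)
    s <- score_disease(m, n, j, ks)
    expect_true(all(diff(s) >= -1e-9))
    k <- sample(ks, 1)
    js <- seq.int(max(k, 1), m, length.out = min(20, m)) |> round()
    sj <- score_disease(m, n, js, k)
    expect_true(all(diff(sj) <= 1e-9))
  }
})

test_that("the two-disease walkthrough ranks and scores as enumerated", {
  tab <- two_disease_table()
  r <- prioritize(tab, c(1L, 2L, 3L))
  expect_equal(r$disease, c("D A", "D B"))
  # D_A: all C(4,3) = 4 draws contain >= 3 of its 3 publications? exactly 1
  expect_equal(hg_tail_oracle(4, 3, 3, 3), 1 / 4)
  expect_equal(r$score[1], -log10(1 / 4), tolerance = 1e-12)
  # D_B: k=1 of j=2 is certain when drawing 3 of 4
  expect_equal(hg_tail_oracle(4, 3, 2, 1), 1)
  expect_equal(r$score[2], 0)
  expect_equal(r$k, c(3L, 1L))
  expect_equal(r$j, c(3L, 2L))
  expect_equal(r$n, c(3L, 3L))
  expect_equal(r$rank, 1:2)
})

test_that("ties break by j descending, then disease name ascending", {
  corpus <- medline_corpus(
    data.frame(pmid = 1:6, date = as.Date("2000-01-01") + 1:6, title = "t",
               abstract = "", stringsAsFactors = FALSE),
    data.frame(pmid = c(1L, 2L, 1L, 2L, 3L, 4L, 5L, 6L),
               heading = c("B Pair", "B Pair", "A Pair", "A Pair",
                           "Common X", "Common X", "Common X", "Common X"),
               stringsAsFactors = FALSE))
  vocab <- data.frame(name = c("A Pair", "B Pair", "Common X"),
                      ui = c("D1", "D2", "D3"),
                      tree_numbers = c("C01.1", "C01.2", "C01.3"),
                      stringsAsFactors = FALSE)
  tab <- build_link_table(corpus, vocab, quiet = TRUE)
  # query {1,2}: A Pair and B Pair have identical (k=2, j=2) by symmetry
  r <- prioritize(tab, c(1L, 2L))
  expect_equal(r$score[1], r$score[2])
  expect_equal(r$disease[1:2], c("A Pair", "B Pair"))  # name ascending
  # query {3,4}: Common X (k=2, j=4) ties no one; add pairs at k=0 -> absent
  r2 <- prioritize(tab, c(3L, 4L))
  expect_equal(r2$disease, "Common X")
  # j-descending on equal scores: two diseases at score 0 rank by j
  r3 <- prioritize(tab, c(1L, 3L))
  zero <- r3[r3$score == min(r3$score), ]
  if (nrow(zero) > 1) expect_true(all(diff(zero$j) <= 0))
})

test_that("prioritize drops non-table PMIDs and is order-invariant", {
  tab <- two_disease_table()
  r <- prioritize(tab, c(99L, 1L, 2L, 3L, 1000L))
  expect_equal(r$n[1], 3L)
  expect_equal(attr(r, "dropped"), 2L)
  perm <- prioritize(tab, c(3L, 1000L, 2L, 99L, 1L))
  expect_equal(as.data.frame(perm), as.data.frame(r))
  # sum over report of k equals total disease links of table-resident pmids
  expect_equal(sum(r$k), sum(tab$links$pmid %in% c(1L, 2L, 3L)))
  expect_true(all(r$k >= 1L))
})

test_that("a query disjoint from the table yields an empty ranking, not an error", {
  tab <- two_disease_table()
  expect_message(r <- prioritize(tab, c(98L, 99L)), "no query PMIDs")
  expect_equal(nrow(r), 0L)
  expect_equal(attr(r, "dropped"), 2L)
})

test_that("supporting publications are the k query hits, newest first", {
  tab <- two_disease_table()
  r <- prioritize(tab, c(1L, 2L, 3L, 4L))
  sup <- supporting_pmids(r, "D A")
  expect_equal(sort(sup), 1:3)
  expect_length(sup, r$k[r$disease == "D A"])
  dates <- tab$publications$date[match(sup, tab$publications$pmid)]
  expect_true(all(diff(as.numeric(dates)) <= 0))  # most recent first
  oldest <- prioritize(tab, c(1L, 2L, 3L, 4L), newest_first = FALSE)
  expect_equal(supporting_pmids(oldest, "D A"), rev(sup))
})

test_that("max_diseases truncates with ranks kept consecutive", {
  gen <- generate_corpus(corpus_spec(20, 200, seed = 3))
  tab <- build_link_table(gen$corpus, gen$vocabulary, quiet = TRUE)
  r <- prioritize(tab, tab$publications$pmid[1:50], max_diseases = 5)
  expect_lte(nrow(r), 5L)
  expect_equal(r$rank, seq_len(nrow(r)))
})

test_that("rankings round-trip through TSV and JSON exports", {
  tab <- two_disease_table()
  r <- prioritize(tab, c(1L, 2L, 3L))
  for (ext in c(".tsv", ".json")) {
    path <- tempfile(fileext = ext)
    write_ranking(r, path)
    back <- read_ranking(path)
    expect_equal(as.data.frame(back), as.data.frame(r), tolerance = 1e-12,
                 info = ext)
    expect_equal(attr(back, "supporting"), attr(r, "supporting"), info = ext)
    expect_equal(attr(back, "n_in_table"), attr(r, "n_in_table"), info = ext)
  }
})
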