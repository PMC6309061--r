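toy_assocs <- function() {
  data.frame(
    term = c("g", "g", "g", "g", "h", "h", "x", "x"),
    disease = c("D1", "D2", "D3", "D3", "D4", "D4", "D5", "D6"),
    source = c("GAD", "CTD_curated", "GAD", "CTD_curated",
               "GAD", "CTD_curated", "CTD_curated", "CTD_curated"),
    publication_count = c(3L, 5L, 1L, 4L, 2L, 2L, 9L, 9L),
    evidence = c("", "", "", "", "", "", "therapeutic", "marker/mechanism"),
    stringsAsFactors = FALSE)
}

test_that("the four gold-standard criteria implement union/intersection with count thresholds", {
  a <- toy_assocs()
  g1 <- build_gold_standard(a, 1)
  expect_setequal(relevant_diseases(g1, "g"), c("D1", "D2", "D3"))
  expect_setequal(relevant_diseases(g1, "h"), "D4")

  # criterion 2: (g, D3) has count 1 in GAD -> out; single-source pairs with
  # enough support stay in
  g2 <- build_gold_standard(a, 2)
  expect_setequal(relevant_diseases(g2, "g"), c("D1", "D2"))

  # criterion 3: intersection keeps only pairs present in both sources
  g3 <- build_gold_standard(a, 3)
  expect_setequal(relevant_diseases(g3, "g"), "D3")
  expect_false("x" %in% names(g3$relevant))

  # criterion 4: (g, D3) fails the per-database count in GAD
  g4 <- build_gold_standard(a, 4)
  expect_false("g" %in% names(g4$relevant))
  expect_setequal(relevant_diseases(g4, "h"), "D4")

  expect_error(build_gold_standard(a, 5), "criterion")
  expect_error(build_gold_standard(a[a$source == "GAD", ], 1), "CTD_curated")
})

test_that("a gene with disjoint sources is dropped under intersection", {
  a <- data.frame(term = "g", disease = c("D1", "D2"),
                  source = c("GAD", "CTD_curated"),
                  publication_count = c(3L, 5L), evidence = "",
                  stringsAsFactors = FALSE)
  expect_setequal(relevant_diseases(build_gold_standard(a, 1), "g"),
                  c("D1", "D2"))
  expect_length(build_gold_standard(a, 3)$relevant, 0L)
})

test_that("therapeutic gold standard keeps only exact CTD_curated evidence", {
  a <- toy_assocs()
  gt <- therapeutic_gold_standard(a)
  expect_equal(names(gt$relevant), "x")
  expect_equal(relevant_diseases(gt, "x"), "D5")
  a$evidence[7] <- "Therapeutic"  # case-variant must not match
  expect_length(therapeutic_gold_standard(a)$relevant, 0L)
})

test_that("precision / recall / F on hand-checked sets", {
  m <- precision_recall_f(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f_measure, 2 / 3)
  ident <- precision_recall_f(c("A", "B"), c("A", "B"))
  expect_equal(unlist(ident), c(precision = 1, recall = 1, f_measure = 1))
  disj <- precision_recall_f("A", "B")
  expect_equal(unlist(disj), c(precision = 0, recall = 0, f_measure = 0))
  none <- precision_recall_f(character(), "B")
  expect_equal(unlist(none), c(precision = 0, recall = 0, f_measure = 0))
  expect_error(precision_recall_f("A", character()), "non-empty")
})

test_that("F is the harmonic mean of precision and recall", {
  set.seed(17)
  universe <- paste0("D", 1:30)
  for (i in 1:50) {
    retrieved <- sample(universe, sample(1:20, 1))
    relevant <- sample(universe, sample(1:20, 1))
    m <- precision_recall_f(retrieved, relevant)
    if (m$precision > 0 && m$recall > 0) {
      expect_equal(1 / m$f_measure, (1 / m$precision + 1 / m$recall) / 2,
                   tolerance = 1e-12)
    } else {
      expect_equal(m$f_measure, 0)
    }
  }
})

test_that("average precision on hand-computed rankings", {
  expect_equal(average_precision(c("D1", "x", "D2", "y"), c("D1", "D2")),
               (1 + 2 / 3) / 2)
  expect_equal(average_precision("D1", "D1"), 1)
  # relevant item never retrieved contributes 0
  expect_equal(average_precision(c("D1", "x"), c("D1", "D2")), 0.5)
  expect_error(average_precision(c("D1", "D1"), "D1"), "duplicate")
})

test_that("average-precision properties: bound, perfect-prefix, tail invariance", {
  set.seed(29)
  universe <- paste0("D", 1:25)
  for (i in 1:50) {
    ranked <- sample(universe, sample(5:25, 1))
    relevant <- sample(universe, sample(1:8, 1))
    ap <- average_precision(ranked, relevant)
    expect_gte(ap, 0); expect_lte(ap, 1)
    # AveP == 1 iff the relevant items fill the top ranks
    in_list <- intersect(relevant, ranked)
    perfect <- length(in_list) == length(relevant) &&
      setequal(utils::head(ranked, length(relevant)), relevant)
    expect_equal(ap == 1, perfect)
    # permuting items below the last relevant hit changes nothing
    hits <- which(ranked %in% relevant)
    if (length(hits) && max(hits) < length(ranked) - 1) {
      tail_idx <- (max(hits) + 1):length(ranked)
      shuffled <- ranked
      shuffled[tail_idx] <- sample(shuffled[tail_idx])
      expect_equal(average_precision(shuffled, relevant), ap)
    }
  }
})

test_that("MAP is the arithmetic mean of per-query average precision", {
  expect_equal(map_score(c(1.0, 0.5)), 0.75)
  expect_equal(map_score(c(0, 0, 0)), 0)
  expect_equal(map_score(rep(0.77, 100)), 0.77)
  expect_error(map_score(numeric()), "at least one")
})

test_that("precision at k keeps the denominator fixed at k", {
  ranked10 <- c(paste0("R", 1:5), paste0("x", 1:5))
  expect_equal(precision_at_k(ranked10, paste0("R", 1:5), 10), 0.5)
  expect_equal(precision_at_k(ranked10, "R1", 1), 1)
  expect_equal(precision_at_k(c("R1", "x", "R2"), paste0("R", 1:9), 10), 0.2)
  expect_equal(precision_at_k(ranked10, paste0("R", 1:5), c(1, 5, 10)),
               c(1, 1, 0.5))
  expect_error(precision_at_k(ranked10, "R1", 0), ">= 1")
  # at k == |ranked| it equals set precision
  expect_equal(precision_at_k(ranked10, paste0("R", 1:5), 10),
               precision_recall_f(ranked10, paste0("R", 1:5))$precision)
})

test_that("precision-recall curves walk the ranking cutoff by cutoff", {
  expect_equal(pr_curve("D1", "D1"),
               data.frame(rank = 1L, recall = 1, precision = 1))
  curve <- pr_curve(c("x", "D1"), "D1")
  expect_equal(curve$recall, c(0, 1))
  expect_equal(curve$precision, c(0, 0.5))
  disj <- pr_curve(c("a", "b"), "D9")
  expect_true(all(disj$precision == 0))
  set.seed(5)
  rnd <- pr_curve(sample(paste0("D", 1:40)), paste0("D", 1:7))
  expect_true(all(diff(rnd$recall) >= 0))
})

test_that("rank_of_gold finds the first relevant disease and tallies batches", {
  expect_equal(rank_of_gold(c("Dg", "x"), "Dg"), 1L)
  expect_equal(rank_of_gold(c("x", "y", "Dg"), "Dg"), 3L)
  expect_true(is.na(rank_of_gold(c("x", "y"), "Dg")))
  gold <- build_gold_standard(toy_assocs(), 1)
  tallies <- rank_of_gold_counts(
    list(g = c("D2", "x"), h = c("x", "y", "z", "u", "D4")), gold)
  expect_equal(unname(tallies$ranks), c(1L, 5L))
  expect_equal(tallies$counts, c(top1 = 1L, top2 = 1L, top5 = 2L))
})

test_that("criteria nest: 4 within 3 within 1, and 2 within 1", {
  set.seed(12)
  for (rep in 1:20) {
    gen <- generate_corpus(corpus_spec(
      30, 50, seed = rep,
      planted_queries = list(
        list(token = "qa", targets = sample(30, 4), multiplier = 5, n_pubs = 10),
        list(token = "qb", targets = sample(30, 3), multiplier = 3, n_pubs = 10))))
    assocs <- generate_gold_standard(gen$truth, noise = 0.5, n_spurious = 2,
                                     disease_pool = synthetic_disease_names(30),
                                     seed = rep + 100)
    gs <- lapply(1:4, function(cr) build_gold_standard(assocs, cr))
    for (term in names(gs[[1]]$relevant)) {
      r1 <- relevant_diseases(gs[[1]], term)
      expect_true(all(relevant_diseases(gs[[2]], term) %in% r1))
      r3 <- relevant_diseases(gs[[3]], term)
      expect_true(all(r3 %in% r1))
      expect_true(all(relevant_diseases(gs[[4]], term) %in% r3))
    }
  }
})

test_that("association tables round-trip and reject bad schemas", {
  a <- toy_assocs()
  path <- tempfile(fileext = ".tsv")
  write_associations(a, path)
  expect_equal(read_associations(path), a)
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("term\tdisease", "g\tD1"), bad)
  expect_error(read_associations(bad), "lacks column")
  dup <- a[c(1, 1, 2), ]
  dup_path <- tempfile(fileext = ".tsv")
  write_associations(dup, dup_path)
  expect_error(read_associations(dup_path), "duplicate")
})

test_that("evaluate_rankings aggregates per-query metrics and their means", {
  gold <- build_gold_standard(toy_assocs(), 1)
  ev <- evaluate_rankings(
    list(g = c("D1", "x", "D2"), h = c("D4", "y")), gold,
    top_n = 100, k = c(1, 2))
  expect_equal(nrow(ev$per_query), 2L)
  g_row <- ev$per_query[ev$per_query$term == "g", ]
  expect_equal(g_row$precision, 2 / 3)
  expect_equal(g_row$recall, 2 / 3)
  expect_equal(g_row$average_precision, (1 + 2 / 3) / 3)
  expect_equal(ev$mean[["average_precision"]],
               map_score(ev$per_query$average_precision))
})
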