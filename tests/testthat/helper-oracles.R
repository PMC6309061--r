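# Independent oracles and tiny fixture builders shared across test files.

# Brute-force hypergeometric upper tail by enumerating every size-n draw
# from m items of which items 1..j are marked; counts draws with >= k marks.
# Only feasible for small m, which is exactly its job.
hg_tail_oracle <- function(m, n, j, k) {
  if (k <= 0) return(1)
  draws <- utils::combn(m, n)
  marked <- colSums(draws <= j)
  mean(marked >= k)
}

# Character-level tree-prefix matcher: tree falls under prefix iff the two
# are equal, or tree extends prefix and the character right after the prefix
# is a dot. Written without startsWith so it is an independent check of the
# package's matching rule.
tree_match_oracle <- function(tree, prefix) {
  tc <- strsplit(tree, "")[[1]]
  pc <- strsplit(prefix, "")[[1]]
  if (length(tc) < length(pc)) return(FALSE)
  if (!all(tc[seq_along(pc)] == pc)) return(FALSE)
  length(tc) == length(pc) || tc[length(pc) + 1] == "."
}

# A human-writable vocabulary: three diseases, a non-disease, and the four
# unspecific headings that must always be rejected.
toy_vocabulary <- function() {
  vocab <- data.frame(
    name = c("Neoplasms", "Lung Neoplasms", "Mental Disorders", "Humans",
             "Disease", "Disease Progression", "Disease Attributes",
             "Disease Models, Animal"),
    ui = c("D009369", "D008175", "D001523", "D006801",
           "D004194", "D018450", "D020969", "D004195"),
    tree_numbers = c("C04", "C04.588.894.797.520;C08.381.540", "F03",
                     "B01.050", "C23.550.288", "C23.550.291",
                     "C23.550.291.500", "C23.300"),
    stringsAsFactors = FALSE
  )
  class(vocab) <- c("mesh_vocabulary", "data.frame")
  vocab
}

# In-memory corpus for the three-record link-table walkthrough plus two
# records the builder must reject (pre-1960 date; excluded heading only).
toy_corpus <- function() {
  articles <- data.frame(
    pmid = 1:5,
    date = as.Date(c("2001-05-10", "1999-01-01", "2010-12-31",
                     "1955-06-01", "2005-03-03")),
    title = c("neoplasms study", "humans only", "lung and neoplasms",
              "old paper", "unspecific"),
    abstract = "",
    stringsAsFactors = FALSE
  )
  headings <- data.frame(
    pmid = c(1L, 2L, 3L, 3L, 4L, 5L),
    heading = c("Neoplasms", "Humans", "Neoplasms", "Lung Neoplasms",
                "Neoplasms", "Disease"),
    stringsAsFactors = FALSE
  )
  medline_corpus(articles, headings)
}

toy_link_table <- function() {
  suppressMessages(build_link_table(toy_corpus(), toy_vocabulary(),
                                    quiet = TRUE))
}

# Hand-built link table {D_A on pmids 1,2,3; D_B on pmids 3,4} (m = 4) used
# by the prioritization walkthrough.
two_disease_table <- function() {
  corpus <- medline_corpus(
    articles = data.frame(
      pmid = 1:4,
      date = as.Date(c("2001-01-01", "2002-01-01", "2003-01-01", "2004-01-01")),
      title = "t", abstract = "", stringsAsFactors = FALSE),
    headings = data.frame(
      pmid = c(1L, 2L, 3L, 3L, 4L),
      heading = c("D A", "D A", "D A", "D B", "D B"),
      stringsAsFactors = FALSE)
  )
  vocab <- data.frame(name = c("D A", "D B"), ui = c("D1", "D2"),
                      tree_numbers = c("C01.100", "C01.200"),
                      stringsAsFactors = FALSE)
  suppressMessages(build_link_table(corpus, vocab, quiet = TRUE))
}

# Tiny PubMed-dialect XML document written to a temp file; returns the path.
write_fixture_xml <- function(body, path = tempfile(fileext = ".xml")) {
  writeLines(c("<?xml version=\"1.0\"?>", "<PubmedArticleSet>", body,
               "</PubmedArticleSet>"), path)
  path
}

article_xml <- function(pmid, year = 2000, month = NULL, day = NULL,
                        title = "A title", headings = character(),
                        medline_date = NULL, omit_pmid = FALSE) {
  pubdate <- if (!is.null(medline_date)) {
    sprintf("<MedlineDate>%s</MedlineDate>", medline_date)
  } else {
    paste0(sprintf("<Year>%d</Year>", year),
           if (!is.null(month)) sprintf("<Month>%s</Month>", month),
           if (!is.null(day)) sprintf("<Day>%d</Day>", day))
  }
  mesh <- if (length(headings)) {
    paste0("<MeshHeadingList>",
           paste0("<MeshHeading><DescriptorName>", headings,
                  "</DescriptorName></MeshHeading>", collapse = ""),
           "</MeshHeadingList>")
  } else ""
  paste0(
    "<PubmedArticle><MedlineCitation>",
    if (!omit_pmid) sprintf("<PMID>%d</PMID>", pmid),
    "<Article>",
    "<Journal><JournalIssue><PubDate>", pubdate,
    "</PubDate></JournalIssue></Journal>",
    "<ArticleTitle>", title, "</ArticleTitle>",
    "</Article>", mesh,
    "</MedlineCitation></PubmedArticle>")
}

# Rank of the planted target disease in one synthetic replicate; diseases
# the query never touched (k = 0) get the mid-rank of the unscored block so
# ranks are comparable across replicates.
planted_rank <- function(seed, multiplier, target = 10L, n_diseases = 50L,
                         n_publications = 2000L, n_query_pubs = 50L,
                         midrank_missing = FALSE) {
  spec <- corpus_spec(
    n_diseases, n_publications,
    planted_queries = list(list(token = "genex", targets = target,
                                multiplier = multiplier,
                                n_pubs = n_query_pubs)),
    seed = seed)
  gen <- generate_corpus(spec)
  tab <- build_link_table(gen$corpus, gen$vocabulary, quiet = TRUE)
  qr <- retrieve_pmids("genex", fixture_backend(gen$corpus))
  r <- suppressMessages(prioritize(tab, qr))
  ranks <- rep(nrow(r) + (n_diseases - nrow(r) + 1) / 2, n_diseases)
  names(ranks) <- synthetic_disease_names(n_diseases)
  ranks[r$disease] <- r$rank
  if (midrank_missing) ranks else ranks[[gen$truth$disease[1]]]
}
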