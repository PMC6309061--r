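# MEDLINE/PubMed XML parsing + query->PMID retrieval backends.

MONTH3 <- c(Jan = 1L, Feb = 2L, Mar = 3L, Apr = 4L, May = 5L, Jun = 6L,
            Jul = 7L, Aug = 8L, Sep = 9L, Oct = 10L, Nov = 11L, Dec = 12L)

# "Mar" / "03" / "3" -> integer month; NA when unparseable.
parse_month <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NA_integer_)
  if (grepl("^[0-9]+$", x)) return(as.integer(x))
  unname(MONTH3[substr(x, 1, 3)])
}

#' Construct a MEDLINE corpus object
#'
#' The in-memory container for a set of publication records. `articles` holds
#' one row per publication (PMID, publication date, title, abstract);
#' `headings` is the long-format PMID-to-MeSH-heading relation, preserving
#' the heading order of each record.
#'
#' @param articles Data frame with columns `pmid` (integer), `date` (`Date`),
#'   `title`, `abstract` (character).
#' @param headings Data frame with columns `pmid` and `heading`; every `pmid`
#'   must appear in `articles`. Articles absent from `headings` simply have
#'   no MeSH annotation.
#' @return An object of class `medline_corpus`.
#' @export
medline_corpus <- function(articles, headings) {
  stopifnot(all(c("pmid", "date", "title", "abstract") %in% names(articles)),
            all(c("pmid", "heading") %in% names(headings)))
  articles$pmid <- as.integer(articles$pmid)
  headings$pmid <- as.integer(headings$pmid)
  if (anyDuplicated(articles$pmid)) {
    stop("duplicate PMID(s) in corpus: ",
         paste(unique(articles$pmid[duplicated(articles$pmid)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(articles$pmid <= 0L)) stop("PMIDs must be positive", call. = FALSE)
  yr <- as.integer(format(articles$date, "%Y"))
  if (any(yr < 1900L, na.rm = TRUE)) {
    stop("publication years before 1900 are not supported", call. = FALSE)
  }
  orphan <- setdiff(headings$pmid, articles$pmid)
  if (length(orphan)) {
    stop("headings reference unknown PMID(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  structure(list(articles = articles, headings = headings),
            class = "medline_corpus")
}

#' @export
print.medline_corpus <- function(x, ...) {
  cat(sprintf("<medline_corpus> %d articles, %d MeSH heading assignments\n",
              nrow(x$articles), nrow(x$headings)))
  invisible(x)
}

#' MeSH headings of one publication
#'
#' @param corpus A [medline_corpus()].
#' @param pmid A single PMID.
#' @return Character vector of descriptor names in record order.
#' @export
corpus_headings <- function(corpus, pmid) {
  corpus$headings$heading[corpus$headings$pmid == as.integer(pmid)]
}

#' Parse MEDLINE/PubMed XML
#'
#' Reads a `PubmedArticleSet`-dialect document into a [medline_corpus()].
#' The publication date is taken from `Journal/JournalIssue/PubDate`
#' (`Year`/`Month`/`Day`), falling back to the leading four-digit year of a
#' `MedlineDate`; a missing month or day defaults to January / the 1st so
#' every record carries a sortable calendar date.
#'
#' @param path Path to the XML file (or a literal XML string).
#' @return A `medline_corpus`. Articles without a `MeshHeadingList`
#'   contribute no rows to `headings`.
#' @export
read_medline_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, "//PubmedArticle")
  n <- length(arts)
  pmid <- integer(n); title <- character(n); abstract <- character(n)
  date <- rep(as.Date(NA), n)
  head_list <- vector("list", n)
  for (i in seq_len(n)) {
    a <- arts[[i]]
    id <- xml2::xml_find_first(a, ".//MedlineCitation/PMID")
    if (inherits(id, "xml_missing") || !nzchar(xml2::xml_text(id))) {
      stop(sprintf("article %d has no PMID", i), call. = FALSE)
    }
    pmid[i] <- as.integer(xml2::xml_text(id))
    t <- xml2::xml_find_first(a, ".//Article/ArticleTitle")
    title[i] <- if (inherits(t, "xml_missing")) "" else xml2::xml_text(t)
    ab <- xml2::xml_find_all(a, ".//Article/Abstract/AbstractText")
    abstract[i] <- paste(xml2::xml_text(ab), collapse = " ")
    date[i] <- parse_article_date(a, i)
    mh <- xml2::xml_find_all(a, ".//MeshHeadingList/MeshHeading/DescriptorName")
    head_list[[i]] <- xml2::xml_text(mh)
  }
  articles <- data.frame(pmid = pmid, date = date, title = title,
                         abstract = abstract, stringsAsFactors = FALSE)
  headings <- data.frame(
    pmid = rep.int(pmid, lengths(head_list)),
    heading = unlist(head_list, use.names = FALSE) %||% character(),
    stringsAsFactors = FALSE
  )
  medline_corpus(articles, headings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_article_date <- function(article, idx) {
  pd <- xml2::xml_find_first(article, ".//Journal/JournalIssue/PubDate")
  year <- NA_integer_; month <- NA_integer_; day <- NA_integer_
  if (!inherits(pd, "xml_missing")) {
    y <- xml2::xml_find_first(pd, "./Year")
    if (!inherits(y, "xml_missing")) {
      year <- as.integer(xml2::xml_text(y))
      month <- parse_month(xml2::xml_text(
        xml2::xml_find_first(pd, "./Month")))
      d <- xml2::xml_find_first(pd, "./Day")
      if (!inherits(d, "xml_missing")) day <- as.integer(xml2::xml_text(d))
    } else {
      md <- xml2::xml_find_first(pd, "./MedlineDate")
      if (!inherits(md, "xml_missing")) {
        m <- regmatches(xml2::xml_text(md),
                        regexpr("[0-9]{4}", xml2::xml_text(md)))
        if (length(m)) year <- as.integer(m)
      }
    }
  }
  if (is.na(year)) {
    stop(sprintf("article %d has no parseable publication year", idx),
         call. = FALSE)
  }
  if (is.na(month)) month <- 1L
  if (is.na(day)) day <- 1L
  as.Date(sprintf("%04d-%02d-%02d", year, month, day))
}

#' Serialize a corpus to PubMed-dialect XML
#'
#' Writes the same `PubmedArticleSet` dialect [read_medline_xml()] reads, so
#' corpora round-trip; used for fixtures and by the synthetic-corpus
#' generator.
#'
#' @param corpus A [medline_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_medline_xml <- function(corpus, path) {
  a <- corpus$articles
  split_heads <- split(corpus$headings$heading,
                       factor(corpus$headings$pmid, levels = a$pmid))
  mesh_blocks <- vapply(split_heads, function(h) {
    if (length(h) == 0L) return("")
    paste0("      <MeshHeadingList>\n",
           paste(sprintf("        <MeshHeading><DescriptorName>%s</DescriptorName></MeshHeading>",
                         xml_escape(h)), collapse = "\n"),
           "\n      </MeshHeadingList>\n")
  }, character(1))
  abstract_blocks <- ifelse(
    nzchar(a$abstract),
    sprintf("        <Abstract><AbstractText>%s</AbstractText></Abstract>\n",
            xml_escape(a$abstract)),
    ""
  )
  recs <- sprintf(paste0(
    "  <PubmedArticle>\n",
    "    <MedlineCitation>\n",
    "      <PMID>%d</PMID>\n",
    "      <Article>\n",
    "        <Journal><JournalIssue><PubDate>",
    "<Year>%s</Year><Month>%s</Month><Day>%s</Day>",
    "</PubDate></JournalIssue></Journal>\n",
    "        <ArticleTitle>%s</ArticleTitle>\n",
    "%s",
    "      </Article>\n",
    "%s",
    "    </MedlineCitation>\n",
    "  </PubmedArticle>"),
    a$pmid,
    format(a$date, "%Y"), format(a$date, "%m"), format(a$date, "%d"),
    xml_escape(a$title), abstract_blocks, mesh_blocks)
  writeLines(c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
               "<PubmedArticleSet>", recs, "</PubmedArticleSet>"), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Retrieval backends

#' Offline fixture retrieval backend
#'
#' Matches a query against a corpus by case-insensitive whole-token search
#' over the stored title + abstract text. This is a deliberately simple
#' stand-in for a live PubMed search so that the full pipeline is testable
#' without network access; it is not a model of PubMed's query translation.
#'
#' @param corpus A [medline_corpus()].
#' @return A retrieval backend object.
#' @export
fixture_backend <- function(corpus) {
  stopifnot(inherits(corpus, "medline_corpus"))
  structure(list(corpus = corpus), class = c("fixture_backend", "pmid_backend"))
}

#' Live NCBI E-utilities retrieval backend
#'
#' Queries PubMed through the eSearch endpoint, paging with
#' `retstart`/`retmax` until the reported `Count` (or `max_results`) is
#' exhausted. The query string is forwarded verbatim. Requires network
#' access; transient HTTP failures are retried with backoff up to `retries`
#' times before erroring.
#'
#' @param base_url eSearch endpoint URL.
#' @param api_key Optional NCBI API key.
#' @param retries Bounded retry count for transient failures.
#' @param delay Seconds to sleep between requests (NCBI etiquette: stay
#'   at or under 3 requests/second without an API key).
#' @return A retrieval backend object.
#' @export
eutils_backend <- function(base_url = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/esearch.fcgi",
                           api_key = NULL, retries = 3L, delay = 0.34) {
  structure(list(base_url = base_url, api_key = api_key,
                 retries = as.integer(retries), delay = delay),
            class = c("eutils_backend", "pmid_backend"))
}

#' Retrieve PMIDs for a query
#'
#' @param query Non-empty free-text query.
#' @param backend A [fixture_backend()] or [eutils_backend()].
#' @param max_results Cap on the number of PMIDs returned.
#' @param min_date Optional `Date` floor on publication date (forwarded as
#'   `mindate` to the live backend; applied to stored dates by the fixture
#'   backend).
#' @return A `query_result`: list with `query`, `pmids` (deduplicated
#'   integer vector), `backend` label and `retrieved_at` timestamp.
#' @export
retrieve_pmids <- function(query, backend, max_results = Inf, min_date = NULL) {
  if (!is.character(query) || length(query) != 1L || !nzchar(query)) {
    stop("query must be a non-empty string", call. = FALSE)
  }
  if (!inherits(backend, "pmid_backend")) {
    stop("unknown retrieval backend; use fixture_backend() or eutils_backend()",
         call. = FALSE)
  }
  UseMethod("retrieve_pmids", backend)
}

#' @export
retrieve_pmids.default <- function(query, backend, max_results = Inf,
                                   min_date = NULL) {
  stop("unknown retrieval backend class: ",
       paste(class(backend), collapse = "/"), call. = FALSE)
}

#' @export
retrieve_pmids.fixture_backend <- function(query, backend, max_results = Inf,
                                           min_date = NULL) {
  a <- backend$corpus$articles
  text <- tolower(paste(a$title, a$abstract))
  tokens <- strsplit(text, "[^a-z0-9]+")
  qtok <- tolower(query)
  hit <- vapply(tokens, function(tk) qtok %in% tk, logical(1))
  if (!is.null(min_date)) hit <- hit & a$date >= as.Date(min_date)
  pmids <- unique(a$pmid[hit])
  if (is.finite(max_results)) pmids <- utils::head(pmids, max_results)
  new_query_result(query, pmids, "fixture")
}

#' @export
retrieve_pmids.eutils_backend <- function(query, backend, max_results = Inf,
                                          min_date = NULL) {
  page <- 10000L
  got <- integer(0)
  start <- 0L
  count <- NA_integer_
  repeat {
    retmax <- if (is.finite(max_results)) {
      min(page, max_results - length(got))
    } else page
    if (retmax <= 0L) break
    params <- c(
      db = "pubmed", term = utils::URLencode(query, reserved = TRUE),
      retstart = start, retmax = retmax, retmode = "xml",
      if (!is.null(min_date)) c(mindate = format(as.Date(min_date), "%Y/%m/%d"),
                                datetype = "pdat"),
      if (!is.null(backend$api_key)) c(api_key = backend$api_key)
    )
    url <- paste0(backend$base_url, "?",
                  paste(names(params), params, sep = "=", collapse = "&"))
    doc <- eutils_fetch(url, backend$retries, backend$delay)
    if (is.na(count)) {
      count <- as.integer(xml2::xml_text(
        xml2::xml_find_first(doc, "//eSearchResult/Count")))
    }
    ids <- as.integer(xml2::xml_text(xml2::xml_find_all(doc, "//IdList/Id")))
    got <- c(got, ids)
    start <- start + length(ids)
    if (length(ids) == 0L || start >= count || length(got) >= max_results) break
  }
  if (is.finite(max_results)) got <- utils::head(got, max_results)
  new_query_result(query, unique(got), "live-eutils")
}

eutils_fetch <- function(url, retries, delay) {
  for (attempt in seq_len(retries + 1L)) {
    Sys.sleep(delay)
    res <- tryCatch(xml2::read_xml(url), error = identity)
    if (!inherits(res, "error")) return(res)
    if (attempt > retries) {
      stop("E-utilities request failed after ", retries, " retries: ",
           conditionMessage(res), call. = FALSE)
    }
    Sys.sleep(delay * 2^attempt)
  }
}

new_query_result <- function(query, pmids, backend_label) {
  structure(
    list(query = query, pmids = as.integer(pmids), backend = backend_label,
         retrieved_at = utc_timestamp()),
    class = "query_result"
  )
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf("<query_result> %s: %d PMIDs via %s backend (%s)\n",
              shQuote(x$query), length(x$pmids), x$backend, x$retrieved_at))
  invisible(x)
}
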