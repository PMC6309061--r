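# Disease prioritization: the hypergeometric tail score computed in log
# space, and the ranking of diseases for a query's PMID set.

check_contingency <- function(m, n, j, k) {
  args <- cbind(m = m, n = n, j = j, k = k)
  if (any(args != floor(args)) || any(is.na(args))) {
    stop("contingency counts must be non-negative integers", call. = FALSE)
  }
  viol <- function(bad, msg) {
    if (any(bad)) stop("invalid contingency: ", msg, " (first offending set: m=",
                       m[bad][1], ", n=", n[bad][1], ", j=", j[bad][1],
                       ", k=", k[bad][1], ")", call. = FALSE)
  }
  viol(k < 0, "k < 0")
  viol(n > m, "n > m")
  viol(j > m, "j > m")
  viol(k > pmin(n, j), "k > min(n, j)")
  invisible(NULL)
}

# Natural-log upper-tail probability of the hypergeometric distribution:
# log P(X >= k) for X ~ Hypergeom(m, j, n). Each summand
# C(j,i) * C(m-j, n-i) / C(m,n) is evaluated through lchoose (log-gamma) and
# the sum is collapsed with log-sum-exp, so the result is finite and
# negative-or-zero even when the probability underflows double precision
# (scores in the thousands correspond to tails ~ 10^-1000s).
log_hypergeom_tail_1 <- function(m, n, j, k) {
  top <- min(n, j)
  # certain event: every draw of n contains at least max(0, n-(m-j)) marked
  if (k <= max(0, n - (m - j))) return(0)
  i <- k:top
  terms <- lchoose(j, i) + lchoose(m - j, n - i) - lchoose(m, n)
  min(logsumexp(terms), 0)
}

#' Hypergeometric upper-tail probability
#'
#' Probability of observing `k` or more disease-annotated publications when
#' `n` publications are drawn without replacement from a table of `m`
#' publications of which `j` carry the disease:
#' \deqn{f(m,n,j,k) = \sum_{i=k}^{\min(n,j)} \frac{{j \choose i}{m-j \choose n-i}}{{m \choose n}}.}
#' Computed in log space (log-gamma binomial coefficients combined with
#' log-sum-exp), so the returned log-scale value stays finite for contingency
#' tables whose tail probability underflows double precision.
#'
#' @param m Total publications in the link table.
#' @param n Query publications present in the table.
#' @param j Disease's publications in the table.
#' @param k Query publications annotated with the disease. All four are
#'   recycled to a common length; each tuple must satisfy
#'   `0 <= k <= min(n, j)`, `n <= m`, `j <= m`.
#' @param log Return the natural-log probability instead of the probability.
#' @return Numeric vector of tail probabilities in `[0, 1]` (or their
#'   natural logs).
#' @seealso [score_disease()] for the `-log10` ranking score.
#' @export
hypergeom_tail <- function(m, n, j, k, log = FALSE) {
  sizes <- c(length(m), length(n), length(j), length(k))
  len <- max(sizes)
  if (any(sizes == 0L)) return(numeric(0))
  m <- rep_len(as.numeric(m), len); n <- rep_len(as.numeric(n), len)
  j <- rep_len(as.numeric(j), len); k <- rep_len(as.numeric(k), len)
  check_contingency(m, n, j, k)
  lp <- vapply(seq_len(len),
               function(z) log_hypergeom_tail_1(m[z], n[z], j[z], k[z]),
               numeric(1))
  if (log) lp else exp(lp)
}

#' Disease enrichment score
#'
#' The ranking score \eqn{S_D = -\log_{10} f(m,n,j,k)} of a disease given a
#' query: the base-10 negative log of the hypergeometric upper-tail
#' probability from [hypergeom_tail()]. A score of 0 means the overlap is no
#' larger than expected (`f = 1`); with `m`, `n` and `j` fixed the score is
#' strictly increasing in `k`. No multiple-testing correction is applied:
#' the raw tail probability is the ranking statistic.
#'
#' @inheritParams hypergeom_tail
#' @return Non-negative, finite numeric vector of scores.
#' @export
score_disease <- function(m, n, j, k) {
  -hypergeom_tail(m, n, j, k, log = TRUE) / log(10)
}

#' Rank diseases for a query's PMID set
#'
#' For each disease co-annotated with at least one query publication present
#' in the link table, builds the contingency (`m`, `n`, `j`, `k`) and scores
#' it with [score_disease()]. Only query PMIDs present in the table
#' participate: `n` counts table-resident query publications and the number
#' dropped (no disease annotation, pre-dating the table, or unknown) is
#' recorded. Ordering is score descending, ties broken by `j` descending
#' (better-documented diseases first), residual ties by disease name
#' ascending.
#'
#' @param table A `link_table`.
#' @param query A `query_result` from [retrieve_pmids()], or a plain vector
#'   of PMIDs.
#' @param max_diseases Truncate the ranking to this many diseases
#'   (default: unlimited).
#' @param newest_first Order each disease's supporting publications most
#'   recent first (`FALSE` for oldest first).
#' @return A data frame of class `disease_ranking` with columns `rank`,
#'   `disease`, `score`, `k`, `j`, `n`, `m`, plus attributes `supporting`
#'   (named list of PMID vectors, one per disease, date-ordered), `query`,
#'   `backend`, `n_retrieved`, `n_in_table`, `dropped`.
#' @export
prioritize <- function(table, query, max_diseases = Inf, newest_first = TRUE) {
  stopifnot(inherits(table, "link_table"))
  if (nrow(table$publications) == 0L) {
    stop("cannot prioritize against an empty link table", call. = FALSE)
  }
  if (inherits(query, "query_result")) {
    pmids <- query$pmids
    qlabel <- query$query
    backend <- query$backend
  } else {
    pmids <- as.integer(query)
    qlabel <- NA_character_
    backend <- NA_character_
  }
  pmids <- unique(pmids)
  m <- nrow(table$publications)
  in_table <- intersect(pmids, table$publications$pmid)
  n <- length(in_table)
  dropped <- length(pmids) - n
  if (n == 0L) {
    message("prioritize: no query PMIDs are present in the link table")
    return(new_disease_ranking(
      empty_ranking_frame(), supporting = list(), query = qlabel,
      backend = backend, n_retrieved = length(pmids), n_in_table = 0L,
      dropped = dropped))
  }

  hits <- table$links[table$links$pmid %in% in_table, , drop = FALSE]
  k_tab <- table(hits$disease)
  diseases <- names(k_tab)
  k <- as.integer(k_tab)
  j_all <- disease_counts(table)
  j <- as.integer(j_all[diseases])
  score <- score_disease(m, n, j, k)

  ord <- order(-score, -j, diseases)
  res <- data.frame(
    rank = seq_along(ord),
    disease = diseases[ord],
    score = score[ord],
    k = k[ord], j = j[ord], n = n, m = m,
    stringsAsFactors = FALSE
  )
  if (is.finite(max_diseases)) res <- utils::head(res, max_diseases)
  res$rank <- seq_len(nrow(res))

  dates <- table$publications$date[match(hits$pmid, table$publications$pmid)]
  ord_sup <- order(if (newest_first) -as.numeric(dates) else as.numeric(dates),
                   if (newest_first) -hits$pmid else hits$pmid)
  sup <- split(hits$pmid[ord_sup], hits$disease[ord_sup])
  sup <- sup[res$disease]

  new_disease_ranking(res, supporting = sup, query = qlabel,
                      backend = backend, n_retrieved = length(pmids),
                      n_in_table = n, dropped = dropped)
}

empty_ranking_frame <- function() {
  data.frame(rank = integer(), disease = character(), score = numeric(),
             k = integer(), j = integer(), n = integer(), m = integer(),
             stringsAsFactors = FALSE)
}

new_disease_ranking <- function(df, supporting, query, backend,
                                n_retrieved, n_in_table, dropped) {
  structure(df,
            supporting = supporting,
            query = query, backend = backend,
            n_retrieved = n_retrieved, n_in_table = n_in_table,
            dropped = dropped,
            generated_at = utc_timestamp(),
            class = c("disease_ranking", "data.frame"))
}

#' Supporting publications of a ranked disease
#'
#' @param ranking A `disease_ranking`.
#' @param disease Disease name present in the ranking.
#' @return Date-ordered integer vector of supporting PMIDs (length `k`).
#' @export
supporting_pmids <- function(ranking, disease) {
  sup <- attr(ranking, "supporting")
  if (!disease %in% names(sup)) {
    stop(shQuote(disease), " is not in this ranking", call. = FALSE)
  }
  sup[[disease]]
}

#' @export
print.disease_ranking <- function(x, n = 10L, ...) {
  q <- attr(x, "query")
  cat("Disease ranking",
      if (!is.na(q)) paste0("for query ", shQuote(q)) else "", "\n")
  cat(sprintf("  %d of %d retrieved PMIDs in table (m = %s); %d dropped; %d diseases scored\n",
              attr(x, "n_in_table"), attr(x, "n_retrieved"),
              if (nrow(x)) format(x$m[1], big.mark = ",") else "?",
              attr(x, "dropped"), nrow(x)))
  if (nrow(x) == 0L) {
    cat("  (no diseases: query has no table-resident PMIDs)\n")
    return(invisible(x))
  }
  print.data.frame(utils::head(as.data.frame(x), n), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > n) cat("  ... and", nrow(x) - n, "more diseases\n")
  invisible(x)
}

#' @export
summary.disease_ranking <- function(object, ...) {
  out <- list(
    query = attr(object, "query"),
    n_retrieved = attr(object, "n_retrieved"),
    n_in_table = attr(object, "n_in_table"),
    dropped = attr(object, "dropped"),
    n_diseases = nrow(object),
    top = utils::head(as.data.frame(object), 5L),
    score_range = if (nrow(object)) range(object$score) else c(NA, NA)
  )
  class(out) <- "summary.disease_ranking"
  out
}

#' @export
print.summary.disease_ranking <- function(x, ...) {
  cat(sprintf("Query %s: %d PMIDs retrieved, %d in table, %d dropped\n",
              shQuote(x$query), x$n_retrieved, x$n_in_table, x$dropped))
  cat(sprintf("%d diseases scored; scores span [%.4g, %.4g]\n",
              x$n_diseases, x$score_range[1], x$score_range[2]))
  cat("Top diseases:\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.disease_ranking <- function(x, n = 20L, ...) {
  if (nrow(x) == 0L) {
    stop("nothing to plot: empty ranking", call. = FALSE)
  }
  top <- utils::head(x, n)
  op <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(top$score), names.arg = rev(top$disease),
                    horiz = TRUE, las = 1, xlab = expression(-log[10] ~ f),
                    main = if (!is.na(attr(x, "query"))) {
                      paste("Diseases for", shQuote(attr(x, "query")))
                    } else "Disease ranking", ...)
  invisible(x)
}

#' Write a disease ranking to TSV or JSON
#'
#' TSV columns: `rank`, `disease`, `score`, `k`, `j`, `n`, `m`,
#' `supporting_pmids` (semicolon-joined, date-ordered); run metadata travels
#' in `#`-comment lines. The JSON export mirrors the same schema with a
#' `summary` block.
#'
#' @param ranking A `disease_ranking`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "tsv"
  }
  sup <- attr(ranking, "supporting")
  sup_str <- vapply(ranking$disease,
                    function(d) paste(sup[[d]], collapse = ";"), character(1))
  if (format == "tsv") {
    df <- as.data.frame(ranking)
    writeLines(c(
      paste0("#query=", attr(ranking, "query")),
      paste0("#backend=", attr(ranking, "backend")),
      paste0("#n_retrieved=", attr(ranking, "n_retrieved")),
      paste0("#n_in_table=", attr(ranking, "n_in_table")),
      paste0("#dropped=", attr(ranking, "dropped")),
      paste0("#generated_at=", attr(ranking, "generated_at")),
      "rank\tdisease\tscore\tk\tj\tn\tm\tsupporting_pmids",
      if (nrow(df)) paste(df$rank, df$disease,
                          formatC(df$score, digits = 15, format = "g"),
                          df$k, df$j, df$n, df$m, sup_str, sep = "\t")
    ), path)
  } else {
    obj <- list(
      summary = list(query = attr(ranking, "query"),
                     backend = attr(ranking, "backend"),
                     n_retrieved = attr(ranking, "n_retrieved"),
                     n_in_table = attr(ranking, "n_in_table"),
                     dropped = attr(ranking, "dropped"),
                     generated_at = attr(ranking, "generated_at")),
      results = cbind(as.data.frame(ranking),
                      supporting_pmids = unname(sup_str))
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a disease ranking written by [write_ranking()]
#'
#' @param path Path to a `.tsv` or `.json` ranking file.
#' @return A `disease_ranking`.
#' @export
read_ranking <- function(path) {
  if (tolower(tools::file_ext(path)) == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- obj$results
    meta <- obj$summary
    if (is.null(df) || nrow(df) == 0L) {
      df <- cbind(empty_ranking_frame(), supporting_pmids = character())
    }
  } else {
    parsed <- read_commented_tsv(path)
    header <- "rank\tdisease\tscore\tk\tj\tn\tm\tsupporting_pmids"
    if (!length(parsed$body) || parsed$body[[1L]] != header) {
      stop("ranking TSV schema mismatch: unexpected header", call. = FALSE)
    }
    body <- parsed$body[-1L]
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 8L)) {
      stop("ranking TSV schema mismatch: expected 8 fields per row",
           call. = FALSE)
    }
    col <- function(i) vapply(parts, `[[`, character(1), i)
    df <- if (length(parts)) {
      data.frame(rank = as.integer(col(1)), disease = col(2),
                 score = as.numeric(col(3)), k = as.integer(col(4)),
                 j = as.integer(col(5)), n = as.integer(col(6)),
                 m = as.integer(col(7)), supporting_pmids = col(8),
                 stringsAsFactors = FALSE)
    } else cbind(empty_ranking_frame(), supporting_pmids = character())
    meta <- list(
      query = comment_field(parsed$comments, "query"),
      backend = comment_field(parsed$comments, "backend"),
      n_retrieved = as.integer(comment_field(parsed$comments, "n_retrieved")),
      n_in_table = as.integer(comment_field(parsed$comments, "n_in_table")),
      dropped = as.integer(comment_field(parsed$comments, "dropped"))
    )
  }
  sup <- lapply(strsplit(df$supporting_pmids, ";", fixed = TRUE), as.integer)
  names(sup) <- df$disease
  df$supporting_pmids <- NULL
  if (is.null(meta$query) || identical(meta$query, "NA")) {
    meta$query <- NA_character_
  }
  if (is.null(meta$backend) || identical(meta$backend, "NA")) {
    meta$backend <- NA_character_
  }
  new_disease_ranking(df, supporting = sup, query = meta$query,
                      backend = meta$backend,
                      n_retrieved = as.integer(meta$n_retrieved),
                      n_in_table = as.integer(meta$n_in_table),
                      dropped = as.integer(meta$dropped))
}
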