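# The publication-to-disease link table: the bipartite structure housing m
# (its publication count) and each disease's j (its publication count).

new_link_table <- function(publications, links, filter_desc,
                           built_at = utc_timestamp()) {
  publications <- publications[order(publications$pmid), , drop = FALSE]
  links <- links[order(links$pmid, links$disease), , drop = FALSE]
  rownames(publications) <- NULL
  rownames(links) <- NULL
  structure(
    list(publications = publications, links = links,
         filter_desc = filter_desc, built_at = built_at),
    class = "link_table"
  )
}

#' Build a publication-to-disease link table
#'
#' A publication enters the table iff its date is on or after `min_date` and
#' at least one of its MeSH headings resolves to a vocabulary descriptor that
#' passes the disease-branch filter. Publications with no qualifying disease
#' heading are excluded entirely, so the table's publication count `m` counts
#' only disease-bearing publications. Repeated headings on one record are
#' deduplicated: a PMID contributes at most 1 to any disease's count `j`.
#'
#' @param corpus A [medline_corpus()].
#' @param vocab A vocabulary from [read_mesh_vocabulary()] (descriptor names
#'   must be unique; headings are matched by exact descriptor-name string).
#' @param filter A [disease_filter()].
#' @param min_date Date floor; defaults to 1960-01-01.
#' @param quiet Suppress the note counting headings absent from the
#'   vocabulary (they are ignored).
#' @return An object of class `link_table` with elements `publications`
#'   (data frame `pmid`, `date`), `links` (data frame `pmid`, `disease`),
#'   `filter_desc` and `built_at`.
#' @export
build_link_table <- function(corpus, vocab, filter = disease_filter(),
                             min_date = as.Date("1960-01-01"),
                             quiet = FALSE) {
  stopifnot(inherits(corpus, "medline_corpus"))
  if (is.null(vocab) || nrow(vocab) == 0L) {
    stop("empty vocabulary: cannot decide which headings are diseases",
         call. = FALSE)
  }
  if (anyDuplicated(vocab$name)) {
    stop("vocabulary descriptor names must be unique", call. = FALSE)
  }
  min_date <- as.Date(min_date)
  disease_names <- vocab$name[is_disease(vocab, filter)]

  h <- corpus$headings
  unknown <- !(h$heading %in% vocab$name)
  if (!quiet && any(unknown)) {
    message(sprintf("link_table: ignoring %d heading assignment(s) absent from the vocabulary (%d distinct)",
                    sum(unknown), length(unique(h$heading[unknown]))))
  }
  links <- h[h$heading %in% disease_names, c("pmid", "heading")]
  names(links)[2L] <- "disease"
  links <- unique(links)

  a <- corpus$articles
  keep_date <- a$pmid[a$date >= min_date]
  links <- links[links$pmid %in% keep_date, , drop = FALSE]
  pubs <- a[a$pmid %in% links$pmid, c("pmid", "date")]
  new_link_table(pubs, links, format_filter(filter))
}

#' Link-table summary statistics
#'
#' @param table A `link_table`.
#' @return Named list: `diseases` (distinct disease count), `publications`
#'   (`m`, the table's publication count) and `relationships` (total
#'   publication-to-disease pairs, which always equals the sum over diseases
#'   of their publication counts `j`).
#' @export
table_stats <- function(table) {
  stopifnot(inherits(table, "link_table"))
  list(diseases = length(unique(table$links$disease)),
       publications = nrow(table$publications),
       relationships = nrow(table$links))
}

#' Per-disease publication counts j
#'
#' @param table A `link_table`.
#' @return Named integer vector: for each disease, the number of table
#'   publications annotated with it.
#' @export
disease_counts <- function(table) {
  stopifnot(inherits(table, "link_table"))
  tab <- table(table$links$disease)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.link_table <- function(x, ...) {
  s <- table_stats(x)
  cat(sprintf("<link_table> %d diseases, m = %d publications, %d relationships\n",
              s$diseases, s$publications, s$relationships))
  cat("  built_at:", x$built_at, "\n  filter:  ", x$filter_desc, "\n")
  invisible(x)
}

#' @export
summary.link_table <- function(object, ...) {
  j <- sort(disease_counts(object), decreasing = TRUE)
  s <- table_stats(object)
  out <- list(stats = s, top_diseases = utils::head(j, 10L),
              date_range = range(object$publications$date))
  class(out) <- "summary.link_table"
  out
}

#' @export
print.summary.link_table <- function(x, ...) {
  cat(sprintf("Link table: %d diseases, m = %d, %d relationships\n",
              x$stats$diseases, x$stats$publications, x$stats$relationships))
  if (x$stats$publications > 0) {
    cat("Publication dates:", format(x$date_range[1]), "to",
        format(x$date_range[2]), "\n")
    cat("Most-published diseases (j):\n")
    print(x$top_diseases)
  }
  invisible(x)
}

#' Persist a link table as TSV
#'
#' One row per publication: `pmid`, ISO date, semicolon-joined disease names
#' (sorted). `built_at` and the filter description travel in `#`-comment
#' header lines so [read_link_table()] reconstructs an identical object.
#'
#' @param table A `link_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_link_table <- function(table, path) {
  stopifnot(inherits(table, "link_table"))
  by_pub <- split(table$links$disease,
                  factor(table$links$pmid, levels = table$publications$pmid))
  diseases <- vapply(by_pub, function(d) paste(sort(d), collapse = ";"),
                     character(1))
  writeLines(c(
    paste0("#built_at=", table$built_at),
    paste0("#filter=", table$filter_desc),
    "pmid\tdate\tdiseases",
    paste(table$publications$pmid, format(table$publications$date, "%Y-%m-%d"),
          diseases, sep = "\t")
  ), path)
  invisible(path)
}

#' Load a link table written by [write_link_table()]
#'
#' @param path Path to the TSV file.
#' @return A `link_table`.
#' @export
read_link_table <- function(path) {
  parsed <- read_commented_tsv(path)
  lines <- readLines(path, warn = FALSE)
  header_at <- which(!startsWith(lines, "#"))[1L]
  if (is.na(header_at) || !identical(lines[[header_at]], "pmid\tdate\tdiseases")) {
    stop(sprintf("link-table schema mismatch at line %d: expected header 'pmid\\tdate\\tdiseases'",
                 if (is.na(header_at)) length(lines) else header_at),
         call. = FALSE)
  }
  body_idx <- seq_along(lines) > header_at & nzchar(lines) &
    !startsWith(lines, "#")
  rows <- which(body_idx)
  parts <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop(sprintf("link-table schema mismatch at line %d: expected 3 tab-separated fields, found %d",
                 rows[bad[[1L]]], lengths(parts)[bad[[1L]]]), call. = FALSE)
  }
  pmid <- as.integer(vapply(parts, `[[`, character(1), 1L))
  date <- as.Date(vapply(parts, `[[`, character(1), 2L))
  dlists <- strsplit(vapply(parts, `[[`, character(1), 3L), ";", fixed = TRUE)
  if (any(is.na(pmid)) || any(is.na(date))) {
    off <- rows[which(is.na(pmid) | is.na(date))[1L]]
    stop(sprintf("link-table schema mismatch at line %d: unparseable pmid or date", off),
         call. = FALSE)
  }
  publications <- data.frame(pmid = pmid, date = date, stringsAsFactors = FALSE)
  links <- data.frame(
    pmid = rep.int(pmid, lengths(dlists)),
    disease = unlist(dlists, use.names = FALSE) %||% character(),
    stringsAsFactors = FALSE
  )
  new_link_table(publications, links,
                 filter_desc = comment_field(parsed$comments, "filter"),
                 built_at = comment_field(parsed$comments, "built_at"))
}

#' Remove one publication from a link table
#'
#' Drops the publication and all its disease links; `m` decreases by exactly
#' one and each affected disease's `j` by exactly one.
#'
#' @param table A `link_table`.
#' @param pmid PMID to remove (must be present).
#' @return The reduced `link_table`.
#' @export
drop_publication <- function(table, pmid) {
  stopifnot(inherits(table, "link_table"))
  pmid <- as.integer(pmid)
  if (!pmid %in% table$publications$pmid) {
    stop("PMID ", pmid, " is not in the table", call. = FALSE)
  }
  new_link_table(
    table$publications[table$publications$pmid != pmid, , drop = FALSE],
    table$links[table$links$pmid != pmid, , drop = FALSE],
    table$filter_desc, table$built_at
  )
}
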