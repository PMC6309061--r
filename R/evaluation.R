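# Gold-standard construction from curated association tables and ranked-list
# information-retrieval metrics.

#' Read / write curated association tables
#'
#' Neutral TSV schema for curated term-disease associations:
#' `term`, `disease`, `source` (e.g. `"GAD"`, `"CTD_curated"`),
#' `publication_count`, `evidence` (free-text code such as `"therapeutic"`).
#' One row per (term, disease, source).
#'
#' @param path Path to the TSV file (header required).
#' @return Data frame with those five columns.
#' @export
read_associations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
  needed <- c("term", "disease", "source", "publication_count", "evidence")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("association table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[needed]
  df$publication_count <- as.integer(df$publication_count)
  key <- paste(df$term, df$disease, df$source, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (term, disease, source) row(s) in association table",
         call. = FALSE)
  }
  df
}

#' @rdname read_associations
#' @param assocs Association data frame.
#' @export
write_associations <- function(assocs, path) {
  utils::write.table(assocs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

new_gold_standard <- function(relevant, criterion) {
  relevant <- relevant[lengths(relevant) > 0L]
  structure(list(relevant = relevant, criterion = as.character(criterion)),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("<gold_standard> criterion %s: %d terms, %d associations\n",
              x$criterion, length(x$relevant), sum(lengths(x$relevant))))
  invisible(x)
}

# (term, disease) pairs of one source with their publication counts
source_pairs <- function(assocs, src) {
  s <- assocs[assocs$source == src, , drop = FALSE]
  s$pair <- paste(s$term, s$disease, sep = "\r")
  s
}

#' Build a gold standard from two curated databases
#'
#' Combines the `"GAD"` and `"CTD_curated"` rows of an association table
#' into per-term relevant-disease sets under one of four stringency
#' criteria:
#' \enumerate{
#'   \item union of the two sources' (term, disease) pairs;
#'   \item union, restricted to pairs with at least `min_pubs` supporting
#'     publications in each database in which they appear;
#'   \item intersection of the two sources;
#'   \item intersection, with at least `min_pubs` supporting publications in
#'     both.
#' }
#' "More than one supporting publication" is the default `min_pubs = 2`.
#' Terms whose relevant set comes out empty are dropped. By construction the
#' relevant sets nest: criterion 4 within 3 within 1, and 2 within 1.
#'
#' @param assocs Association data frame (see [read_associations()]); must
#'   contain both a `"GAD"` and a `"CTD_curated"` source.
#' @param criterion Integer 1-4.
#' @param min_pubs Minimum per-database publication count for criteria 2
#'   and 4.
#' @return A `gold_standard`: list with `relevant` (named list mapping term
#'   to character vector of disease names) and `criterion`.
#' @export
build_gold_standard <- function(assocs, criterion, min_pubs = 2L) {
  if (!criterion %in% 1:4) {
    stop("criterion must be 1, 2, 3 or 4", call. = FALSE)
  }
  for (src in c("GAD", "CTD_curated")) {
    if (!src %in% assocs$source) {
      stop("association table has no ", shQuote(src), " rows", call. = FALSE)
    }
  }
  gad <- source_pairs(assocs, "GAD")
  ctd <- source_pairs(assocs, "CTD_curated")
  keep <- switch(as.character(criterion),
    "1" = union(gad$pair, ctd$pair),
    "2" = {
      ok_gad <- gad$pair[gad$publication_count >= min_pubs]
      ok_ctd <- ctd$pair[ctd$publication_count >= min_pubs]
      u <- union(gad$pair, ctd$pair)
      # a pair must meet the threshold in every database in which it appears
      u[(!u %in% gad$pair | u %in% ok_gad) &
        (!u %in% ctd$pair | u %in% ok_ctd)]
    },
    "3" = intersect(gad$pair, ctd$pair),
    "4" = intersect(gad$pair[gad$publication_count >= min_pubs],
                    ctd$pair[ctd$publication_count >= min_pubs])
  )
  if (length(keep) == 0L) return(new_gold_standard(list(), criterion))
  parts <- strsplit(keep, "\r", fixed = TRUE)
  term <- vapply(parts, `[[`, character(1), 1L)
  disease <- vapply(parts, `[[`, character(1), 2L)
  new_gold_standard(split(disease, term), criterion)
}

#' Therapeutic drug-disease gold standard
#'
#' Keeps only `CTD_curated` rows whose evidence code is exactly
#' `"therapeutic"` (case-sensitive): the curated drug-to-disease treatment
#' relationships.
#'
#' @param assocs Association data frame (see [read_associations()]).
#' @return A `gold_standard` with criterion label `"therapeutic"`.
#' @export
therapeutic_gold_standard <- function(assocs) {
  s <- assocs[assocs$source == "CTD_curated" & assocs$evidence == "therapeutic",
              , drop = FALSE]
  new_gold_standard(split(s$disease, s$term), "therapeutic")
}

#' Relevant diseases for one term
#'
#' @param gold A `gold_standard`.
#' @param term Query term.
#' @return Character vector of relevant disease names (empty if the term is
#'   absent).
#' @export
relevant_diseases <- function(gold, term) {
  gold$relevant[[term]] %||% character()
}

# ---------------------------------------------------------------------------
# Ranked-list metrics

#' Set-based precision, recall and F-measure
#'
#' `p = |relevant ∩ retrieved| / |retrieved|`,
#' `r = |relevant ∩ retrieved| / |relevant|`,
#' `F = 2pr / (p + r)` (0 when `p + r = 0`). Retrieval order is irrelevant;
#' duplicates in `retrieved` are collapsed. An empty retrieved list yields
#' `p = r = F = 0` by convention.
#'
#' @param retrieved Character vector of retrieved disease names.
#' @param relevant Non-empty character vector (or set) of relevant diseases.
#' @return Named list with elements `precision`, `recall`, `f_measure`.
#' @export
precision_recall_f <- function(retrieved, relevant) {
  relevant <- unique(as.character(relevant))
  if (length(relevant) == 0L) {
    stop("relevant set must be non-empty", call. = FALSE)
  }
  retrieved <- unique(as.character(retrieved))
  hit <- length(intersect(retrieved, relevant))
  p <- if (length(retrieved)) hit / length(retrieved) else 0
  r <- hit / length(relevant)
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f_measure = f)
}

#' Average precision of a ranked list
#'
#' Mean, over all relevant items, of the precision at each relevant item's
#' rank; relevant items never retrieved contribute 0. Equals 1 iff the
#' relevant items occupy the top `|relevant|` ranks.
#'
#' @param ranked Character vector, best first; duplicates are an error.
#' @param relevant Non-empty character vector of relevant diseases.
#' @return Average precision in `[0, 1]`.
#' @export
average_precision <- function(ranked, relevant) {
  relevant <- unique(as.character(relevant))
  if (length(relevant) == 0L) {
    stop("relevant set must be non-empty", call. = FALSE)
  }
  ranked <- as.character(ranked)
  if (anyDuplicated(ranked)) {
    stop("ranked list contains duplicate entries", call. = FALSE)
  }
  if (length(ranked) == 0L) return(0)
  hits <- ranked %in% relevant
  prec_at <- cumsum(hits) / seq_along(ranked)
  sum(prec_at[hits]) / length(relevant)
}

#' Mean average precision over a query set
#'
#' @param per_query_ap Non-empty numeric vector of per-query average
#'   precisions.
#' @return Their arithmetic mean.
#' @export
map_score <- function(per_query_ap) {
  if (length(per_query_ap) == 0L) {
    stop("map_score needs at least one query's average precision",
         call. = FALSE)
  }
  mean(as.numeric(per_query_ap))
}

#' Precision at rank k
#'
#' `|top-k ∩ relevant| / k`. The denominator stays `k` even when fewer than
#' `k` items were retrieved, so short lists are penalised rather than
#' flattered.
#'
#' @param ranked Character vector, best first.
#' @param relevant Character vector of relevant diseases.
#' @param k Positive cutoff(s); vectorised.
#' @return Numeric vector of precisions, one per `k`.
#' @export
precision_at_k <- function(ranked, relevant, k) {
  k <- as.integer(k)
  if (any(k < 1L)) stop("k must be >= 1", call. = FALSE)
  vapply(k, function(kk) {
    sum(utils::head(ranked, kk) %in% relevant) / kk
  }, numeric(1))
}

#' Precision-recall curve of a ranked list
#'
#' One point per rank cutoff 1..length(ranked): recall and precision of the
#' top-cutoff prefix. Recall is non-decreasing along the curve.
#'
#' @inheritParams average_precision
#' @return Data frame with columns `rank`, `recall`, `precision`.
#' @export
pr_curve <- function(ranked, relevant) {
  relevant <- unique(as.character(relevant))
  ranked <- as.character(ranked)
  hits <- cumsum(ranked %in% relevant)
  data.frame(
    rank = seq_along(ranked),
    recall = if (length(relevant)) hits / length(relevant) else rep(0, length(ranked)),
    precision = if (length(ranked)) hits / seq_along(ranked) else numeric()
  )
}

#' Plot one or more precision-recall curves
#'
#' @param curves A data frame from [pr_curve()] or a named list of them.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_pr_curves <- function(curves, ...) {
  if (is.data.frame(curves)) curves <- list(curve = curves)
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "Recall",
                 ylab = "Precision", ...)
  for (i in seq_along(curves)) {
    graphics::lines(curves[[i]]$recall, curves[[i]]$precision, col = i,
                    lwd = 2, type = "s")
  }
  if (length(curves) > 1L) {
    graphics::legend("topright", legend = names(curves),
                     col = seq_along(curves), lwd = 2, bty = "n")
  }
  invisible(curves)
}

#' Rank of the first relevant disease
#'
#' @inheritParams average_precision
#' @return 1-based rank of the first relevant item in `ranked`, or
#'   `NA_integer_` when no relevant item was retrieved.
#' @export
rank_of_gold <- function(ranked, relevant) {
  hit <- which(ranked %in% relevant)
  if (length(hit)) hit[[1L]] else NA_integer_
}

#' Tally gold-standard ranks across queries
#'
#' Batch companion to [rank_of_gold()]: for each query's ranked list, find
#' the rank of its first relevant disease and count how many queries place
#' it within each cutoff.
#'
#' @param rankings Named list of ranked character vectors, one per query
#'   term.
#' @param gold A `gold_standard` covering (at least) those terms.
#' @param top Cutoffs to tally (default 1, 2, 5).
#' @return List with `ranks` (named integer vector, `NA` = not found) and
#'   `counts` (named vector: queries whose gold disease ranks within each
#'   cutoff).
#' @export
rank_of_gold_counts <- function(rankings, gold, top = c(1L, 2L, 5L)) {
  ranks <- vapply(names(rankings), function(term) {
    rank_of_gold(rankings[[term]], relevant_diseases(gold, term))
  }, integer(1))
  counts <- vapply(top, function(tt) sum(!is.na(ranks) & ranks <= tt),
                   integer(1))
  names(counts) <- paste0("top", top)
  list(ranks = ranks, counts = counts)
}

#' Evaluate ranked lists against a gold standard
#'
#' Convenience wrapper computing, per query term, precision / recall /
#' F-measure of the (optionally truncated) list, average precision of the
#' full list and precision at each requested `k`; plus means over queries.
#' Terms without a relevant set in `gold` are skipped.
#'
#' @param rankings Named list of ranked disease-name vectors.
#' @param gold A `gold_standard`.
#' @param top_n Truncation applied before set-based precision/recall
#'   (default 100, i.e. the top of the list is what gets judged).
#' @param k Cutoffs for precision at k.
#' @return List with `per_query` (data frame) and `mean` (named numeric
#'   vector of column means, MAP included as `average_precision`).
#' @export
evaluate_rankings <- function(rankings, gold, top_n = 100L,
                              k = c(10L, 50L, 100L)) {
  terms <- intersect(names(rankings), names(gold$relevant))
  rows <- lapply(terms, function(term) {
    rel <- relevant_diseases(gold, term)
    ranked <- rankings[[term]]
    prf <- precision_recall_f(utils::head(ranked, top_n), rel)
    pk <- precision_at_k(ranked, rel, k)
    names(pk) <- paste0("p_at_", k)
    c(list(term = term, precision = prf$precision, recall = prf$recall,
           f_measure = prf$f_measure,
           average_precision = average_precision(ranked, rel)),
      as.list(pk))
  })
  per_query <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  if (is.null(per_query)) {
    stop("no query term overlaps the gold standard", call. = FALSE)
  }
  means <- colMeans(per_query[, setdiff(names(per_query), "term"),
                              drop = FALSE])
  list(per_query = per_query, mean = means)
}
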