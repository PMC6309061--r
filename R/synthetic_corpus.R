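# Synthetic corpus generator: publications with multinomially assigned
# disease MeSH annotations and planted query-specific enrichment, so the
# whole pipeline (retrieval -> link table -> prioritization -> evaluation)
# is testable offline with a known ground truth.

#' Zipf-profile multinomial weights
#'
#' Literature disease frequencies are heavy-tailed, so the generator's
#' default background weights follow a Zipf law: weight of disease `i`
#' proportional to `1 / i^s`.
#'
#' @param n Number of diseases.
#' @param s Zipf exponent (1 = classic).
#' @return Numeric weight vector summing to 1.
#' @export
zipf_weights <- function(n, s = 1) {
  w <- 1 / seq_len(n)^s
  w / sum(w)
}

#' Specify a synthetic corpus
#'
#' @param n_diseases Number of synthetic disease descriptors.
#' @param n_publications Corpus size.
#' @param background_weights Per-disease multinomial weights (default
#'   [zipf_weights()]); non-negative, not all zero.
#' @param diseases_per_pub Integer range of disease headings per
#'   publication (sampled uniformly; drawn without replacement within a
#'   publication).
#' @param planted_queries List of planted enrichments; each element a list
#'   with `token` (query word placed in the titles of its publications),
#'   `targets` (disease indices in `1..n_diseases`), `multiplier`
#'   (enrichment factor >= 1 applied to the targets' weights within the
#'   query's publications, then renormalized) and `n_pubs` (how many
#'   publications belong to the query).
#' @param seed RNG seed making generation deterministic.
#' @param date_range Length-2 `Date` vector publications dates are drawn
#'   uniformly from.
#' @return A validated `corpus_spec` object.
#' @export
corpus_spec <- function(n_diseases, n_publications,
                        background_weights = zipf_weights(n_diseases),
                        diseases_per_pub = 1:3,
                        planted_queries = list(),
                        seed = 1L,
                        date_range = as.Date(c("1990-01-01", "2016-12-31"))) {
  stopifnot(n_diseases >= 1L, n_publications >= 1L,
            length(background_weights) == n_diseases,
            all(diseases_per_pub >= 1L),
            max(diseases_per_pub) <= n_diseases,
            length(date_range) == 2L)
  if (any(background_weights < 0) || all(background_weights == 0)) {
    stop("background_weights must be non-negative and not all zero",
         call. = FALSE)
  }
  date_range <- as.Date(date_range)
  if (date_range[2] < date_range[1]) {
    stop("date_range must be increasing", call. = FALSE)
  }
  total_planted <- 0L
  for (q in planted_queries) {
    need <- c("token", "targets", "multiplier", "n_pubs")
    if (!all(need %in% names(q))) {
      stop("each planted query needs fields: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (q$multiplier < 1) {
      stop("enrichment multiplier must be >= 1", call. = FALSE)
    }
    if (!is.finite(q$multiplier) ||
        !all(is.finite(background_weights * q$multiplier))) {
      stop("enrichment multiplier degenerates the renormalized weights",
           call. = FALSE)
    }
    if (!all(q$targets %in% seq_len(n_diseases))) {
      stop("planted target indices must lie in 1..n_diseases", call. = FALSE)
    }
    total_planted <- total_planted + as.integer(q$n_pubs)
  }
  if (total_planted > n_publications) {
    stop("planted queries claim more publications than the corpus holds",
         call. = FALSE)
  }
  structure(
    list(n_diseases = as.integer(n_diseases),
         n_publications = as.integer(n_publications),
         background_weights = background_weights / sum(background_weights),
         diseases_per_pub = as.integer(diseases_per_pub),
         planted_queries = planted_queries,
         seed = as.integer(seed),
         date_range = date_range),
    class = "corpus_spec"
  )
}

#' Synthetic disease names
#'
#' @param n_diseases Number of diseases.
#' @return Character vector `"Synthetic Disease 001"`, ...
#' @export
synthetic_disease_names <- function(n_diseases) {
  sprintf("Synthetic Disease %03d", seq_len(n_diseases))
}

#' Vocabulary matching a synthetic corpus
#'
#' Every synthetic disease sits under tree `C04` (so it passes the default
#' disease-branch filter); a non-disease `"Humans"` descriptor (tree
#' `B01.050`) is included because the generator annotates every publication
#' with it, exercising vocabulary filtering downstream.
#'
#' @param spec A [corpus_spec()] (or an integer disease count).
#' @return A `mesh_vocabulary` data frame.
#' @export
corpus_vocabulary <- function(spec) {
  n <- if (inherits(spec, "corpus_spec")) spec$n_diseases else as.integer(spec)
  vocab <- data.frame(
    name = c(synthetic_disease_names(n), "Humans"),
    ui = c(sprintf("D9%05d", seq_len(n)), "D006801"),
    tree_numbers = c(sprintf("C04.%03d", seq_len(n)), "B01.050"),
    stringsAsFactors = FALSE
  )
  class(vocab) <- c("mesh_vocabulary", "data.frame")
  vocab
}

#' Generate a synthetic corpus with planted enrichment
#'
#' Each publication receives a uniform-random date in the spec's date range,
#' a disease-heading set drawn without replacement from the background
#' multinomial weights, and a `"Humans"` heading. Publications assigned to a
#' planted query carry the query's token in their title, and their
#' disease-draw weights have the target diseases' weights multiplied by the
#' enrichment factor before renormalization (multiplier 1 means no
#' enrichment). Generation is deterministic given the spec's seed and does
#' not disturb the caller's RNG state.
#'
#' @param spec A [corpus_spec()].
#' @return List with `corpus` (a [medline_corpus()]), `truth` (data frame
#'   `query`, `disease`, `multiplier`, `n_query_pubs`: the planted
#'   query-to-target-disease assignments) and `vocabulary`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_seed(spec$seed, {
    np <- spec$n_publications
    diseases <- synthetic_disease_names(spec$n_diseases)
    pmid <- 100000L + seq_len(np)

    planted_of_pub <- rep(NA_integer_, np)
    pos <- 1L
    for (qi in seq_along(spec$planted_queries)) {
      nq <- as.integer(spec$planted_queries[[qi]]$n_pubs)
      if (nq > 0L) {
        planted_of_pub[pos:(pos + nq - 1L)] <- qi
        pos <- pos + nq
      }
    }

    span <- as.integer(spec$date_range[2] - spec$date_range[1]) + 1L
    dates <- spec$date_range[1] + (sample.int(span, np, replace = TRUE) - 1L)

    ndis <- resample(spec$diseases_per_pub, np, replace = TRUE)
    weights <- vector("list", length(spec$planted_queries) + 1L)
    weights[[1L]] <- spec$background_weights
    for (qi in seq_along(spec$planted_queries)) {
      q <- spec$planted_queries[[qi]]
      w <- spec$background_weights
      w[q$targets] <- w[q$targets] * q$multiplier
      if (!all(is.finite(w)) || sum(w) <= 0) {
        stop("enrichment multiplier degenerates the renormalized weights",
             call. = FALSE)
      }
      weights[[qi + 1L]] <- w / sum(w)
    }

    head_list <- vector("list", np)
    for (p in seq_len(np)) {
      wsel <- weights[[if (is.na(planted_of_pub[p])) 1L else planted_of_pub[p] + 1L]]
      head_list[[p]] <- resample(diseases, ndis[p], prob = wsel)
    }

    title <- sprintf("Synthetic report %d on biomedical literature", pmid)
    planted <- !is.na(planted_of_pub)
    if (any(planted)) {
      tokens <- vapply(spec$planted_queries, `[[`, character(1), "token")
      title[planted] <- sprintf("A study of %s in a synthetic cohort (record %d)",
                                tokens[planted_of_pub[planted]], pmid[planted])
    }

    articles <- data.frame(pmid = pmid, date = dates, title = title,
                           abstract = "", stringsAsFactors = FALSE)
    headings <- data.frame(
      pmid = rep.int(pmid, lengths(head_list) + 1L),
      heading = unlist(mapply(function(h, i) c(h, "Humans"), head_list,
                              seq_len(np), SIMPLIFY = FALSE),
                       use.names = FALSE),
      stringsAsFactors = FALSE
    )

    truth <- if (length(spec$planted_queries)) {
      do.call(rbind, lapply(spec$planted_queries, function(q) {
        data.frame(query = q$token, disease = diseases[q$targets],
                   multiplier = q$multiplier,
                   n_query_pubs = as.integer(q$n_pubs),
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(query = character(), disease = character(),
                 multiplier = numeric(), n_query_pubs = integer(),
                 stringsAsFactors = FALSE)
    }

    list(corpus = medline_corpus(articles, headings), truth = truth,
         vocabulary = corpus_vocabulary(spec))
  })
}

#' Write the synthetic ground truth as TSV
#'
#' @param truth Ground-truth data frame from [generate_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Generate a curated-association table from planted ground truth
#'
#' Emulates a pair of curated databases covering the planted associations.
#' With `noise = 0` every planted (query, disease) pair appears under both
#' the `"GAD"` and `"CTD_curated"` sources with publication counts of at
#' least 2, so all four gold-standard criteria coincide. With positive
#' `noise`, each association suffers a perturbation with that probability:
#' one source's row is dropped, or one source's count is set to 1 —
#' exercising the distinctions between criteria 1-4. Weakly enriched
#' associations (small multiplier) are preferentially perturbed, mirroring
#' how poorly studied associations tend to be recorded in only one curated
#' database. `n_spurious` database-only associations per term (random
#' diseases never planted in the corpus, present in a single source) emulate
#' curated links the literature does not support.
#'
#' @param truth Ground-truth data frame from [generate_corpus()].
#' @param noise Perturbation probability in `[0, 1)`.
#' @param n_spurious Spurious single-source associations added per term.
#' @param disease_pool Disease names spurious associations are drawn from
#'   (required when `n_spurious > 0`).
#' @param evidence Evidence code for the emitted rows.
#' @param seed RNG seed; generation is deterministic given it.
#' @return Association data frame in the [read_associations()] schema.
#' @export
generate_gold_standard <- function(truth, noise = 0, n_spurious = 0L,
                                   disease_pool = NULL,
                                   evidence = "marker/mechanism", seed = 1L) {
  if (noise < 0 || noise >= 1) {
    stop("noise must lie in [0, 1)", call. = FALSE)
  }
  if (n_spurious > 0L && is.null(disease_pool)) {
    stop("disease_pool is required when n_spurious > 0", call. = FALSE)
  }
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      s <- truth$multiplier[i]
      counts <- 2L + stats::rpois(2L, lambda = max(s, 1))
      keep <- c(GAD = TRUE, CTD_curated = TRUE)
      # perturbation probability shrinks with enrichment strength: weak
      # associations are the ones a single database tends to miss
      p_perturb <- noise * min(1, 2 / max(s, 1))
      if (stats::runif(1) < p_perturb) {
        which_src <- sample.int(2L, 1L)
        if (stats::runif(1) < 0.5) keep[which_src] <- FALSE
        else counts[which_src] <- 1L
      }
      for (z in 1:2) {
        if (!keep[z]) next
        rows[[length(rows) + 1L]] <- data.frame(
          term = truth$query[i], disease = truth$disease[i],
          source = c("GAD", "CTD_curated")[z],
          publication_count = counts[z], evidence = evidence,
          stringsAsFactors = FALSE)
      }
    }
    if (n_spurious > 0L) {
      for (term in unique(truth$query)) {
        pool <- setdiff(disease_pool, truth$disease[truth$query == term])
        extra <- resample(pool, min(n_spurious, length(pool)))
        for (d in extra) {
          rows[[length(rows) + 1L]] <- data.frame(
            term = term, disease = d,
            source = resample(c("GAD", "CTD_curated"), 1L),
            publication_count = resample(1:3, 1L), evidence = evidence,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows) == 0L) {
      return(data.frame(term = character(), disease = character(),
                        source = character(), publication_count = integer(),
                        evidence = character(), stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
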