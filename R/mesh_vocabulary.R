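# MeSH descriptor vocabulary: loading and the disease-branch filter.

#' Default MeSH tree prefixes that define the disease branches
#'
#' The disease categories of the MeSH tree: C01 through C26 (Diseases) plus
#' F02 and F03 (Behavior and Behavior Mechanisms is excluded; F02
#' "Psychological Phenomena" and F03 "Mental Disorders" are included because
#' mental disorders are diseases but live outside the C branch).
#'
#' @return Character vector of tree-number prefixes.
#' @export
default_disease_prefixes <- function() {
  c(sprintf("C%02d", 1:26), "F02", "F03")
}

#' Default excluded MeSH headings
#'
#' Four headings that sit in the disease branches but are too unspecific to
#' be useful disease labels: "Disease", "Disease Progression",
#' "Disease Attributes" and "Disease Models, Animal".
#'
#' @return Character vector of canonical descriptor names.
#' @export
default_excluded_headings <- function() {
  c("Disease", "Disease Progression", "Disease Attributes",
    "Disease Models, Animal")
}

#' Create a disease-branch filter
#'
#' A filter decides whether a MeSH descriptor counts as a disease: at least
#' one of its tree numbers must fall under an included prefix, and its
#' canonical heading must not be on the exclusion list. Prefix matching is
#' dot-boundary aware: `"C26"` matches `"C26"` and `"C26.120"` but never
#' `"C260.1"`.
#'
#' @param included_prefixes Tree-number prefixes (top-level category codes or
#'   deeper dot-paths). Default: C01-C26, F02, F03.
#' @param excluded_names Canonical headings rejected regardless of tree
#'   position; compared exactly (case-sensitive).
#' @return An object of class `disease_filter`.
#' @examples
#' f <- disease_filter()
#' is_disease(data.frame(name = "Neoplasms", ui = "D009369",
#'                       tree_numbers = "C04"), f)
#' @export
disease_filter <- function(included_prefixes = default_disease_prefixes(),
                           excluded_names = default_excluded_headings()) {
  included_prefixes <- as.character(included_prefixes)
  if (length(included_prefixes) == 0L) {
    stop("disease_filter needs at least one included tree prefix", call. = FALSE)
  }
  bad <- !grepl("^[A-Z][0-9]{2}(\\.[0-9]+)*$", included_prefixes)
  if (any(bad)) {
    stop("malformed tree prefixes (expect letter + two digits, optionally dotted): ",
         paste(included_prefixes[bad], collapse = ", "), call. = FALSE)
  }
  structure(
    list(included_prefixes = included_prefixes,
         excluded_names = as.character(excluded_names)),
    class = "disease_filter"
  )
}

#' @export
print.disease_filter <- function(x, ...) {
  cat("<disease_filter>\n")
  cat("  prefixes:", paste(x$included_prefixes, collapse = " "), "\n")
  cat("  excluded:", paste(shQuote(x$excluded_names), collapse = ", "), "\n")
  invisible(x)
}

# one-line description for file headers / run summaries
format_filter <- function(f) {
  paste0("prefixes=", paste(f$included_prefixes, collapse = ","),
         ";excluded=", paste(f$excluded_names, collapse = "|"))
}

# TRUE iff a single tree number falls under a single prefix.
tree_matches_prefix <- function(tree, prefix) {
  tree == prefix | startsWith(tree, paste0(prefix, "."))
}

#' Is a descriptor a disease under a branch filter?
#'
#' @param descriptors A vocabulary data frame as returned by
#'   [read_mesh_vocabulary()] (columns `name`, `ui`, `tree_numbers`, the
#'   latter semicolon-joined), or any data frame with those columns.
#' @param filter A [disease_filter()].
#' @return Logical vector, one element per descriptor: `TRUE` iff the
#'   descriptor's name is not excluded and at least one of its tree numbers
#'   equals an included prefix or extends it across a dot boundary.
#' @export
is_disease <- function(descriptors, filter = disease_filter()) {
  stopifnot(inherits(filter, "disease_filter"),
            all(c("name", "tree_numbers") %in% names(descriptors)))
  trees <- strsplit(as.character(descriptors$tree_numbers), ";", fixed = TRUE)
  in_branch <- vapply(trees, function(tn) {
    tn <- tn[nzchar(tn)]
    if (length(tn) == 0L) return(FALSE)
    any(vapply(filter$included_prefixes,
               function(p) any(tree_matches_prefix(tn, p)), logical(1)))
  }, logical(1))
  in_branch & !(descriptors$name %in% filter$excluded_names)
}

#' Load a MeSH descriptor vocabulary
#'
#' Reads either the NLM descriptor XML dialect (`DescriptorRecordSet` /
#' `DescriptorRecord` with `DescriptorUI`, `DescriptorName/String` and
#' `TreeNumberList/TreeNumber`) or a headerless 3-column TSV fallback
#' (`name`, `ui`, semicolon-joined tree numbers) convenient for fixtures.
#' Qualifier (subheading) and supplementary-concept records are not
#' descriptors and are ignored by design; only main headings participate in
#' disease filtering.
#'
#' @param path Path to the vocabulary file. Format is sniffed from content
#'   (a leading `<` means XML) unless `format` is given.
#' @param format `"auto"`, `"xml"` or `"tsv"`.
#' @return A data frame of class `mesh_vocabulary` with columns `name`, `ui`
#'   and `tree_numbers` (semicolon-joined, `""` when the descriptor has no
#'   tree position).
#' @export
read_mesh_vocabulary <- function(path, format = c("auto", "xml", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) && grepl("^\\s*<", first)) "xml" else "tsv"
  }
  vocab <- switch(format,
    xml = parse_mesh_xml(path),
    tsv = parse_mesh_tsv(path)
  )
  dup <- unique(vocab$name[duplicated(vocab$name)])
  if (length(dup)) {
    stop("duplicate descriptor name(s) in vocabulary: ",
         paste(shQuote(dup), collapse = ", "), call. = FALSE)
  }
  class(vocab) <- c("mesh_vocabulary", "data.frame")
  vocab
}

parse_mesh_xml <- function(path) {
  doc <- xml2::read_xml(path)
  recs <- xml2::xml_find_all(doc, "//DescriptorRecord")
  name <- character(length(recs))
  ui <- character(length(recs))
  trees <- character(length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    nm <- xml2::xml_find_first(r, "./DescriptorName/String")
    id <- xml2::xml_find_first(r, "./DescriptorUI")
    if (inherits(nm, "xml_missing") || !nzchar(xml2::xml_text(nm))) {
      stop(sprintf("descriptor record %d has no DescriptorName/String", i),
           call. = FALSE)
    }
    name[i] <- xml2::xml_text(nm)
    ui[i] <- if (inherits(id, "xml_missing")) "" else xml2::xml_text(id)
    tn <- xml2::xml_find_all(r, "./TreeNumberList/TreeNumber")
    trees[i] <- paste(xml2::xml_text(tn), collapse = ";")
  }
  data.frame(name = name, ui = ui, tree_numbers = trees,
             stringsAsFactors = FALSE)
}

parse_mesh_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) && identical(tolower(lines[[1L]]),
                                 "name\tui\ttree_numbers")) {
    lines <- lines[-1L]
  }
  if (length(lines) == 0L) {
    return(data.frame(name = character(), ui = character(),
                      tree_numbers = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield < 2L | nfield > 3L)
  if (length(bad)) {
    stop(sprintf("malformed vocabulary TSV at record %d: %s",
                 bad[[1L]], shQuote(lines[[bad[[1L]]]])), call. = FALSE)
  }
  data.frame(
    name = vapply(parts, `[[`, character(1), 1L),
    ui = vapply(parts, `[[`, character(1), 2L),
    tree_numbers = vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "",
                          character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a vocabulary in the 3-column TSV fixture format
#'
#' @param vocab A vocabulary data frame (`name`, `ui`, `tree_numbers`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh_vocabulary <- function(vocab, path) {
  writeLines(paste(vocab$name, vocab$ui, vocab$tree_numbers, sep = "\t"), path)
  invisible(path)
}
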