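# Internal helpers shared across modules.

# log(sum(exp(x))) with max-shift; returns -Inf for empty input.
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Run `code` under `seed`, restoring the caller's RNG state afterwards so
# generators are deterministic without clobbering the session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# sample() without the scalar-x surprise: always samples elements of x.
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size = size, replace = replace, prob = prob)]
}

# Escape &, <, > for hand-rolled XML serialisation (attribute-free content).
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

utc_timestamp <- function(time = Sys.time()) {
  format(time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

# Read a TSV with '#'-prefixed header comments; returns the comment lines and
# the parsed body (all columns character).
read_commented_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  comments <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  list(comments = comments, body = body)
}

# Extract "#key=value" from header comment lines; NA when absent.
comment_field <- function(comments, key) {
  prefix <- paste0("#", key, "=")
  hit <- comments[startsWith(comments, prefix)]
  if (length(hit) == 0L) return(NA_character_)
  sub(prefix, "", hit[[1L]], fixed = TRUE)
}
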