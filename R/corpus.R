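# Corpus container and TSV round-trip I/O.
#
# A corpus is an ordinary tibble with one row per abstract record:
#   doc_id   unique opaque identifier
#   title    free text
#   abstract free text
#   label    "positive", "negative" or "unlabeled"
#   pool     "labeled" (manually reviewed) or "random" (drawn from the
#            background without review; unlabeled until an oracle labels it)

corpus_labels <- c("positive", "negative", "unlabeled")
corpus_pools <- c("labeled", "random")

#' Validate and normalize a corpus tibble
#'
#' Checks the corpus contract: required columns, character types, unique
#' `doc_id`, and legal `label`/`pool` values. Missing `label` is filled with
#' `"unlabeled"`; missing `pool` defaults to `"labeled"` for labeled rows and
#' `"random"` for unlabeled rows.
#'
#' @param x A data frame with at least `doc_id`, `title`, `abstract` columns.
#' @return A tibble with columns `doc_id`, `title`, `abstract`, `label`,
#'   `pool`, in the input row order.
#' @export
as_corpus <- function(x) {
  if (!is.data.frame(x)) stop_altriage("corpus must be a data frame", "type")
  x <- as_tibble(x)
  for (col in c("doc_id", "title", "abstract")) {
    if (!col %in% names(x)) {
      stop_altriage(paste0("missing required column '", col, "'"), "missing_column")
    }
  }
  if (!"label" %in% names(x)) x$label <- "unlabeled"
  x$label <- tolower(as.character(x$label))
  x$label[is.na(x$label) | x$label == ""] <- "unlabeled"
  bad <- setdiff(unique(x$label), corpus_labels)
  if (length(bad)) {
    stop_altriage(paste0("unknown label value(s): ", paste(bad, collapse = ", ")),
                  "bad_label")
  }
  if (!"pool" %in% names(x)) {
    x$pool <- ifelse(x$label == "unlabeled", "random", "labeled")
  }
  x$pool <- tolower(as.character(x$pool))
  x$pool[is.na(x$pool) | x$pool == ""] <-
    ifelse(x$label[is.na(x$pool) | x$pool == ""] == "unlabeled", "random", "labeled")
  bad <- setdiff(unique(x$pool), corpus_pools)
  if (length(bad)) {
    stop_altriage(paste0("unknown pool value(s): ", paste(bad, collapse = ", ")),
                  "bad_pool")
  }
  x$doc_id <- as.character(x$doc_id)
  x$title <- as.character(x$title)
  x$abstract <- as.character(x$abstract)
  dup <- x$doc_id[duplicated(x$doc_id)]
  if (length(dup)) {
    stop_altriage(paste0("duplicate doc_id: ", paste(unique(dup), collapse = ", ")),
                  "duplicate_id")
  }
  x[, c("doc_id", "title", "abstract", "label", "pool"),
    drop = FALSE]
}

# TSV dialect: UTF-8, header required, internal tab/newline/carriage-return/
# backslash escaped as \t, \n, \r, \\ so the round trip is bit-exact for
# printable text. \x01 is the unescape placeholder and is rejected on write.
escape_field <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\r", "\\r", x, fixed = TRUE)
}

unescape_field <- function(x) {
  x <- gsub("\\\\", "\x01", x, fixed = TRUE)
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  gsub("\x01", "\\", x, fixed = TRUE)
}

#' Read an abstract corpus from TSV
#'
#' Reads a tab-separated file with a header row naming at least `doc_id`,
#' `title` and `abstract`; optional `label` and `pool` columns are filled with
#' defaults when absent (see [as_corpus()]). Fields use backslash escapes for
#' internal tabs and newlines, as written by [write_corpus_tsv()].
#'
#' @param path Path to a TSV file.
#' @return A corpus tibble.
#' @seealso [write_corpus_tsv()], [read_medline()]
#' @export
read_corpus_tsv <- function(path) {
  if (!file.exists(path)) stop_altriage(paste0("file not found: ", path), "io")
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop_altriage("empty file (no header row)", "io")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  cells <- strsplit(body, "\t", fixed = TRUE)
  n_col <- length(header)
  df <- lapply(seq_len(n_col), function(j) {
    unescape_field(vapply(cells, function(row) {
      if (length(row) >= j) row[j] else ""
    }, character(1)))
  })
  names(df) <- header
  as_corpus(as_tibble(df[!duplicated(names(df))]))
}

#' Write an abstract corpus to TSV
#'
#' Writes the five corpus columns with a header row. Internal tabs, newlines
#' and backslashes are backslash-escaped so that
#' `read_corpus_tsv(write_corpus_tsv(x, path))` reproduces every field
#' exactly.
#'
#' @param corpus A corpus tibble (validated with [as_corpus()]).
#' @param path Output file path.
#' @return `corpus`, invisibly.
#' @export
write_corpus_tsv <- function(corpus, path) {
  corpus <- as_corpus(corpus)
  txt <- c(corpus$title, corpus$abstract, corpus$doc_id)
  if (any(grepl("\x01", txt, fixed = TRUE))) {
    stop_altriage("fields may not contain the control character \\x01", "bad_text")
  }
  cols <- c("doc_id", "title", "abstract", "label", "pool")
  rows <- do.call(paste, c(lapply(cols, function(cl) escape_field(corpus[[cl]])),
                           sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = "\t"), rows), con, useBytes = TRUE)
  invisible(corpus)
}

#' Summarize corpus pool sizes
#'
#' @param corpus A corpus tibble.
#' @return A tibble with one row per (pool, label) combination and its count.
#' @export
corpus_summary <- function(corpus) {
  corpus <- as_corpus(corpus)
  dplyr::count(corpus, .data$pool, .data$label, name = "n_docs")
}
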