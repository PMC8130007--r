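# Text preprocessing: normalization, stemming, term-document count matrices,
# per-term standard deviations, and SD-threshold feature selection.
#
# The pipeline is deliberately minimal: lowercase, strip punctuation, drop
# pure-digit tokens, Porter-stem, count. No stop-word list and no TF-IDF;
# the SD filter is the only vocabulary pruning.

#' Normalize and tokenize a title/abstract pair
#'
#' Concatenates title and abstract, lowercases, replaces every non
#' alphanumeric character with whitespace (so hyphenated forms split), and
#' drops tokens consisting solely of digits. Token order is preserved.
#'
#' @param title,abstract Character vectors of equal length (or length 1).
#' @return For length-1 input, a character vector of tokens; otherwise a list
#'   of token vectors, one per document.
#' @examples
#' normalize_and_tokenize("Drug-Drug", "Interaction risk.")
#' @export
normalize_and_tokenize <- function(title, abstract) {
  text <- tolower(paste(title, abstract))
  text <- gsub("[^a-z0-9]+", " ", text)
  toks <- strsplit(trimws(text), " ", fixed = TRUE)
  toks <- lapply(toks, function(t) t[nzchar(t) & !grepl("^[0-9]+$", t)])
  if (length(toks) == 1) toks[[1]] else toks
}

doc_stems <- function(corpus) {
  toks <- normalize_and_tokenize(corpus$title, corpus$abstract)
  if (nrow(corpus) == 1) toks <- list(toks)
  lapply(toks, stem_tokens)
}

#' Build a term-document count matrix
#'
#' Tokenizes and Porter-stems every document (titles and abstracts together)
#' and counts stem occurrences. Terms are ordered lexicographically (C
#' locale) so matrices are bit-reproducible; the grand total of the matrix
#' equals the number of retained tokens.
#'
#' @param corpus A corpus tibble.
#' @return An object of class `altriage_tdm`: a list with `terms` (character),
#'   `doc_ids` (character) and `counts` (a sparse terms x documents
#'   [Matrix::dgCMatrix-class] of non-negative integers).
#' @export
build_tdm <- function(corpus) {
  corpus <- as_corpus(corpus)
  if (nrow(corpus) == 0) stop_altriage("corpus is empty", "empty_corpus")
  stems <- doc_stems(corpus)
  terms <- sort_terms(unique(unlist(stems, use.names = FALSE)))
  n_tok <- lengths(stems)
  j <- rep.int(seq_len(nrow(corpus)), n_tok)
  i <- match(unlist(stems, use.names = FALSE), terms)
  counts <- Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(length(terms), nrow(corpus)),
    dimnames = list(terms, corpus$doc_id)
  )
  structure(
    list(terms = terms, doc_ids = corpus$doc_id, counts = counts),
    class = "altriage_tdm"
  )
}

#' @export
print.altriage_tdm <- function(x, ...) {
  cat("<altriage_tdm> ", length(x$terms), " terms x ", length(x$doc_ids),
      " documents, ", sum(x$counts), " tokens\n", sep = "")
  invisible(x)
}

#' Per-term standard deviation of counts across documents
#'
#' Computes, for each term, the standard deviation of its count vector over
#' all documents. The default divisor is the population one (N); set
#' `divisor = "n-1"` for the sample convention.
#'
#' @param tdm An `altriage_tdm`.
#' @param divisor `"n"` (population, default) or `"n-1"` (sample).
#' @return A named numeric vector of SDs, one per term.
#' @export
term_sd <- function(tdm, divisor = c("n", "n-1")) {
  stopifnot(inherits(tdm, "altriage_tdm"))
  divisor <- match.arg(divisor)
  n <- length(tdm$doc_ids)
  if (n < 2) {
    stop_altriage("term SD needs at least 2 documents", "too_few_docs")
  }
  mu <- Matrix::rowSums(tdm$counts) / n
  ss <- Matrix::rowSums(tdm$counts^2)
  var_pop <- ss / n - mu^2
  var_pop[var_pop < 0] <- 0 # guard tiny negatives from cancellation
  v <- if (divisor == "n") var_pop else var_pop * n / (n - 1)
  out <- sqrt(v)
  names(out) <- tdm$terms
  out
}

#' Select features by standard-deviation threshold
#'
#' Keeps the terms whose count SD across documents strictly exceeds
#' `sd_threshold` (default 0.03); low-SD terms are near-constant across the
#' corpus and carry no discriminative signal for retrieval.
#'
#' @param tdm An `altriage_tdm`.
#' @param sd_threshold Non-negative scalar; strict inequality is applied.
#' @param divisor SD divisor convention, see [term_sd()].
#' @return An object of class `altriage_features`: list with
#'   `selected_terms`, `sd_values` (all terms), `sd_threshold`, `divisor`.
#' @export
select_features <- function(tdm, sd_threshold = 0.03, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  if (!is_scalar_number(sd_threshold) && !identical(sd_threshold, Inf)) {
    if (!(is.numeric(sd_threshold) && length(sd_threshold) == 1)) {
      stop_altriage("sd_threshold must be a single number", "bad_threshold")
    }
  }
  if (sd_threshold < 0) {
    stop_altriage("sd_threshold must be >= 0", "bad_threshold")
  }
  sds <- term_sd(tdm, divisor)
  structure(
    list(
      selected_terms = tdm$terms[sds > sd_threshold],
      sd_values = sds,
      sd_threshold = sd_threshold,
      divisor = divisor
    ),
    class = "altriage_features"
  )
}

#' @export
print.altriage_features <- function(x, ...) {
  cat("<altriage_features> ", length(x$selected_terms), "/",
      length(x$sd_values), " terms with SD > ", format(x$sd_threshold),
      " (divisor ", x$divisor, ")\n", sep = "")
  invisible(x)
}

#' @describeIn select_features Tidy view: one row per term with its SD and
#'   selection status.
#' @param x An `altriage_features` object.
#' @param ... Unused.
#' @export
tidy.altriage_features <- function(x, ...) {
  tibble(
    term = names(x$sd_values),
    sd = unname(x$sd_values),
    selected = names(x$sd_values) %in% x$selected_terms
  )
}

#' Vectorize documents over a selected feature set
#'
#' Builds the documents x selected-terms count matrix used by the
#' classifiers. Terms absent from the feature set (including terms never seen
#' when the features were selected) are ignored; documents containing no
#' selected term yield an all-zero row and are reported with a message.
#'
#' @param corpus A corpus tibble (any documents, not necessarily those used
#'   to build the feature set).
#' @param features An `altriage_features` object.
#' @return A sparse documents x terms [Matrix::dgCMatrix-class] with
#'   `doc_id` rownames and term colnames.
#' @export
vectorize_corpus <- function(corpus, features) {
  stopifnot(inherits(features, "altriage_features"))
  corpus <- as_corpus(corpus)
  if (length(features$selected_terms) == 0) {
    stop_altriage("feature set is empty", "empty_features")
  }
  stems <- doc_stems(corpus)
  n_tok <- lengths(stems)
  j <- match(unlist(stems, use.names = FALSE), features$selected_terms)
  i <- rep.int(seq_len(nrow(corpus)), n_tok)
  keep <- !is.na(j)
  x <- Matrix::sparseMatrix(
    i = i[keep], j = j[keep], x = 1,
    dims = c(nrow(corpus), length(features$selected_terms)),
    dimnames = list(corpus$doc_id, features$selected_terms)
  )
  n_zero <- sum(Matrix::rowSums(x) == 0)
  if (n_zero > 0) {
    inform(paste0(n_zero, " document(s) contain no selected term (zero rows)"))
  }
  x
}

#' Write / read a feature set as TSV
#'
#' The file has `#`-prefixed header lines recording the threshold and SD
#' divisor convention, then `term<TAB>sd<TAB>selected` rows.
#'
#' @param features An `altriage_features` object.
#' @param path File path.
#' @return `write_features()`: `features` invisibly. `read_features()`: the
#'   reconstructed `altriage_features`.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "altriage_features"))
  hdr <- c(
    paste0("# sd_threshold=", format(features$sd_threshold, digits = 17)),
    paste0("# divisor=", features$divisor),
    "term\tsd\tselected"
  )
  td <- tidy.altriage_features(features)
  rows <- paste(td$term, format(td$sd, digits = 17, trim = TRUE),
                ifelse(td$selected, "1", "0"), sep = "\t")
  writeLines(c(hdr, rows), path, useBytes = TRUE)
  invisible(features)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    hit <- meta[startsWith(meta, paste0("# ", key, "="))]
    sub(paste0("^# ", key, "="), "", hit[1])
  }
  body <- lines[!startsWith(lines, "#")][-1] # drop column header
  cells <- strsplit(body, "\t", fixed = TRUE)
  term <- vapply(cells, `[`, character(1), 1)
  sds <- as.numeric(vapply(cells, `[`, character(1), 2))
  sel <- vapply(cells, `[`, character(1), 3) == "1"
  names(sds) <- term
  structure(
    list(
      selected_terms = term[sel],
      sd_values = sds,
      sd_threshold = as.numeric(get_meta("sd_threshold")),
      divisor = get_meta("divisor")
    ),
    class = "altriage_features"
  )
}
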