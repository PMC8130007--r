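# MEDLINE tagged-format reader (PMID- / TI  - / AB  - fields with
# continuation lines indented by spaces).

#' Read abstracts from a MEDLINE tagged-format file
#'
#' Parses the classic MEDLINE display format: records separated by blank
#' lines, fields introduced by a four-character tag padded with spaces and a
#' `"- "` separator (`PMID- `, `TI  - `, `AB  - `), and continuation lines
#' indented with spaces. Multi-line field values are joined with single
#' spaces. Records lacking an `AB` field are kept with an empty abstract and
#' reported with a message; a record without a `PMID` is an error.
#'
#' @param path Path to a MEDLINE-format text file.
#' @return A corpus tibble: `PMID` becomes `doc_id`, `TI` the title and `AB`
#'   the abstract; all records are `unlabeled` members of the `random` pool
#'   until labels are assigned.
#' @export
read_medline <- function(path) {
  if (!file.exists(path)) stop_altriage(paste0("file not found: ", path), "io")
  lines <- readLines(path, encoding = "UTF-8")

  # fold continuation lines into their field line
  recs <- list()
  cur <- character() # vector of "TAG\x1fvalue" strings
  tag <- NULL
  flush_rec <- function() {
    if (length(cur)) recs[[length(recs) + 1]] <<- cur
    cur <<- character()
    tag <<- NULL
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      flush_rec()
    } else if (grepl("^[A-Z0-9]{1,4}\\s*- ", ln)) {
      tag <- sub("^([A-Z0-9]{1,4})\\s*- .*$", "\\1", ln)
      val <- sub("^[A-Z0-9]{1,4}\\s*- ", "", ln)
      cur <- c(cur, paste0(tag, "\x1f", val))
    } else if (grepl("^\\s+", ln) && length(cur)) {
      cur[length(cur)] <- paste(cur[length(cur)], trimws(ln))
    }
    # anything else (stray line outside a record) is ignored
  }
  flush_rec()

  if (length(recs) == 0) {
    return(as_corpus(tibble(doc_id = character(), title = character(),
                            abstract = character())))
  }

  field <- function(rec, want) {
    hits <- rec[sub("\x1f.*$", "", rec) == want]
    if (!length(hits)) return(NA_character_)
    paste(sub("^[^\x1f]*\x1f", "", hits), collapse = " ")
  }

  pmid <- vapply(recs, field, character(1), want = "PMID")
  if (anyNA(pmid)) {
    stop_altriage(paste0("record ", which(is.na(pmid))[1], " has no PMID field"),
                  "no_pmid")
  }
  ti <- vapply(recs, field, character(1), want = "TI")
  ab <- vapply(recs, field, character(1), want = "AB")
  if (anyNA(ab)) {
    inform(paste0(sum(is.na(ab)), " record(s) lack an AB field; ",
                  "kept with empty abstract"))
  }
  ti[is.na(ti)] <- ""
  ab[is.na(ab)] <- ""
  as_corpus(tibble(doc_id = pmid, title = ti, abstract = ab))
}
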