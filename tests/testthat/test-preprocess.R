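test_that("normalization lowercases, splits on punctuation, drops digit tokens", {
  expect_equal(normalize_and_tokenize("Drug-Drug", "Interaction risk."),
               c("drug", "drug", "interaction", "risk"))
  expect_equal(normalize_and_tokenize("", ""), character(0))
  expect_equal(normalize_and_tokenize("A 10 mg dose", ""), c("a", "mg", "dose"))
})

test_that("Porter stemmer reproduces canonical stems", {
  cases <- c(
    advanced = "advanc", interactions = "interact", drug = "drug",
    caresses = "caress", ponies = "poni", agreed = "agre", motoring = "motor",
    hopping = "hop", filing = "file", happy = "happi", sky = "sky",
    relational = "relat", vietnamization = "vietnam", operator = "oper",
    triplicate = "triplic", hopeful = "hope", goodness = "good",
    adjustable = "adjust", replacement = "replac", adoption = "adopt",
    activate = "activ", effective = "effect", rate = "rate", roll = "roll",
    controll = "control", electriciti = "electr", sensibiliti = "sensibl"
  )
  expect_equal(stem_tokens(names(cases)), unname(cases))
})

test_that("stemming is idempotent over the synthetic vocabulary", {
  words <- withr::with_seed(7, {
    base <- sample(altriage:::make_vocab(600), 1000, replace = TRUE)
    sfx <- sample(c("", "s", "ed", "ing"), 1000, replace = TRUE)
    paste0(base, sfx)
  })
  s1 <- stem_tokens(words)
  expect_equal(stem_tokens(s1), s1)
})

test_that("term-document matrix counts match a brute-force tally", {
  corp <- tibble::tibble(
    doc_id = paste0("d", 1:5),
    title = c("drug drug", "drug", "risk panel", "drug risk", "panel"),
    abstract = c("interaction", "interactions reported", "", "risks", "panels of panels"),
    label = "unlabeled", pool = "random"
  )
  tdm <- build_tdm(corp)
  expect_equal(as.numeric(tdm$counts["drug", ]), c(2, 1, 0, 1, 0))

  # independent tally: count stems per document with table()
  for (d in seq_len(nrow(corp))) {
    toks <- stem_tokens(normalize_and_tokenize(corp$title[d], corp$abstract[d]))
    tab <- table(toks)
    col <- tdm$counts[, d]
    expect_equal(as.numeric(col[names(tab)]), as.numeric(tab))
    expect_equal(sum(col), length(toks))
  }
  # conservation: grand total equals total retained tokens
  total <- sum(lengths(lapply(seq_len(nrow(corp)), function(d) {
    normalize_and_tokenize(corp$title[d], corp$abstract[d])
  })))
  expect_equal(sum(tdm$counts), total)
  # deterministic lexicographic term order
  expect_equal(tdm$terms, sort(tdm$terms, method = "radix"))
  expect_error(build_tdm(corp[0, ]), class = "altriage_empty_corpus")
})

test_that("per-term SD follows the population formula", {
  corp <- tibble::tibble(
    doc_id = paste0("d", 1:4),
    title = c("aa aa", "aa aa", "aa aa", "aa aa"),   # constant term
    abstract = c("bb", "", "", ""),                  # counts 1,0,0,0
    label = "unlabeled", pool = "random"
  )
  tdm <- build_tdm(corp)
  sds <- term_sd(tdm)
  expect_equal(unname(sds["aa"]), 0)
  expect_equal(unname(sds["bb"]), sqrt(3) / 4)
  # sample-divisor convention
  expect_equal(unname(term_sd(tdm, divisor = "n-1")["bb"]), 0.5)

  # homogeneity: scaling every count by k scales SD by k
  tdm3 <- tdm
  tdm3$counts <- tdm3$counts * 3
  expect_equal(term_sd(tdm3), 3 * term_sd(tdm))

  tdm1 <- build_tdm(corp[1, ])
  expect_error(term_sd(tdm1), class = "altriage_too_few_docs")
})

test_that("SD feature selection is strict and monotone in the threshold", {
  syn <- small_synthesis()
  tdm <- build_tdm(syn$corpus)
  sds <- term_sd(tdm)

  f0 <- select_features(tdm, 0)
  expect_setequal(f0$selected_terms, names(sds)[sds > 0])
  expect_false(any(sds[f0$selected_terms] == 0))

  expect_length(select_features(tdm, Inf)$selected_terms, 0)
  expect_error(select_features(tdm, -0.1), class = "altriage_bad_threshold")

  # strict-greater subset at a straddling threshold, vs independent filter
  thr <- unname(stats::quantile(sds, 0.5))
  f <- select_features(tdm, thr)
  expect_setequal(f$selected_terms, names(sds)[sds > thr])

  # raising the threshold never adds a term
  thresholds <- sort(c(0, 0.01, 0.03, thr, 2 * thr))
  sel <- lapply(thresholds, function(t) select_features(tdm, t)$selected_terms)
  for (i in seq_along(sel)[-1]) {
    expect_true(all(sel[[i]] %in% sel[[i - 1]]))
  }
})

test_that("vectorization is consistent with the TDM and drops unseen terms", {
  syn <- small_synthesis()
  corp <- syn$corpus[1:60, ]
  tdm <- build_tdm(corp)
  f <- select_features(tdm, 0.03)
  x <- vectorize_corpus(corp, f)

  # same corpus: matrix equals the TDM restricted to selected terms, transposed
  expect_equal(
    as.matrix(x),
    t(as.matrix(tdm$counts[f$selected_terms, , drop = FALSE])),
    ignore_attr = FALSE
  )

  # new document with out-of-vocabulary terms: they are ignored
  new_doc <- tibble::tibble(
    doc_id = "new1", title = "zzznovel wordzzz",
    abstract = paste(f$selected_terms[1], f$selected_terms[1]),
    label = "unlabeled", pool = "random"
  )
  xn <- vectorize_corpus(new_doc, f)
  expect_equal(sum(xn), 2)
  expect_equal(unname(xn[1, f$selected_terms[1]]), 2)

  # a document with no selected term yields an all-zero row (reported)
  none_doc <- new_doc
  none_doc$abstract <- "zzzq wwwq"
  expect_message(x0 <- vectorize_corpus(none_doc, f), "zero rows")
  expect_equal(sum(x0), 0)

  empty <- f
  empty$selected_terms <- character(0)
  expect_error(vectorize_corpus(corp, empty), class = "altriage_empty_features")
})

test_that("feature sets survive a TSV round trip", {
  syn <- small_synthesis()
  f <- select_features(build_tdm(syn$corpus[1:40, ]), 0.05)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_features(f, path)
  back <- read_features(path)
  expect_equal(back$selected_terms, f$selected_terms)
  expect_equal(back$sd_values, f$sd_values)
  expect_equal(back$sd_threshold, f$sd_threshold)
  expect_equal(back$divisor, f$divisor)
})
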