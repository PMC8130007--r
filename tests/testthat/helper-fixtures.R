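# Shared fixtures: small corpora, brute-force oracles, and a cached
# mid-size synthetic corpus for engine tests.

tiny_corpus <- function() {
  tibble::tibble(
    doc_id = c("d1", "d2", "d3"),
    title = c("Drug-Drug", "Placebo trial", "Gene panel"),
    abstract = c("Interaction risk.", "No interaction found", "Expression of 10 genes"),
    label = c("positive", "negative", "unlabeled"),
    pool = c("labeled", "labeled", "random")
  )
}

# small synthetic corpus used by several engine/synthetic tests; generated
# once per test run
small_synthesis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_corpus(synthetic_spec(
        vocab_size = 800L, n_pos = 150L, n_labeled_neg = 100L,
        n_random = 500L, doc_length_mean = 80, hidden_positive_rate = 0.01,
        seed = 42L
      ))
    }
    cache
  }
})

small_sizes <- function() {
  al_sizes(n_train_pos = 50L, n_train_neg = 40L, n_train_random = 150L,
           n_val_pos = 50L, n_val_neg = 40L, n_val_random = 50L)
}

# brute-force precision-at-recall: try every threshold (each observed score
# and one below the minimum), retrieval rule score >= t
bf_precision_at_recall <- function(scores, truth01, target) {
  cand <- c(sort(unique(scores), decreasing = TRUE), min(scores) - 1)
  n_pos <- sum(truth01 == 1)
  best_prec <- NA_real_
  for (t in cand) {
    ret <- scores >= t
    rec <- sum(truth01 == 1 & ret) / n_pos
    if (rec >= target) {
      # highest feasible threshold = first feasible in descending order
      best_prec <- sum(truth01 == 1 & ret) / sum(ret)
      break
    }
  }
  best_prec
}

# simple separable 2-D fixture for classifier tests, as a named count matrix
separable_xy <- function(n = 40, seed = 5) {
  withr::with_seed(seed, {
    n2 <- n / 2
    x <- rbind(
      cbind(rpois(n2, 8), rpois(n2, 1)),
      cbind(rpois(n2, 1), rpois(n2, 8))
    )
    colnames(x) <- c("termA", "termB")
    rownames(x) <- paste0("d", seq_len(n))
    list(x = x, y = rep(c("positive", "negative"), each = n2))
  })
}

expect_tbl_equal_chr <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
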