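# Synthetic corpus generator and ground-truth oracle.
#
# Documents are drawn from a topic-mixture multinomial model with three
# document classes -- DDI-safety positives, drug-related labeled negatives,
# and general background -- whose term distributions partially overlap, plus
# a small positive fraction hidden inside the unreviewed random pool. Only
# term counts matter downstream, so tokens are rendered as synthetic word
# strings; a fraction get inflectional suffixes so the stemmer does real
# work.

SYN_TOPICS <- c("pos_core", "drug_shared", "neg_specific",
                "bg_shared", "bg_specific", "filler")

#' Specify a synthetic corpus
#'
#' @param vocab_size Number of distinct base word stems (default 5000).
#' @param n_pos,n_labeled_neg Sizes of the manually labeled positive and
#'   negative pools (defaults 600 and 400).
#' @param n_random Size of the unreviewed random pool (default 9200).
#' @param hidden_positive_rate Fraction of the random pool that is truly
#'   positive (default 0.002; must be < 0.05). These hidden positives are
#'   what high-confidence mining can recover.
#' @param class_topic_mixtures Optional 3 x 6 matrix of per-class mixing
#'   weights over the six topics (rows `positive`, `labeled_neg`,
#'   `background`; rows must be non-negative and sum to 1). When `NULL`,
#'   defaults parameterized by `overlap_labeledneg_background` are used.
#' @param topic_concentration Dirichlet concentration for each topic's word
#'   distribution over its vocabulary block (default 0.05; smaller = more
#'   peaked topics).
#' @param doc_length_mean Poisson mean of tokens per document (default 180).
#' @param overlap_labeledneg_background Fraction of the background topic
#'   mass that the labeled-negative class also covers (default 0.5). Higher
#'   overlap makes labeled negatives resemble the background pool.
#' @param doc_mixture_concentration Dirichlet concentration of the
#'   per-document topic mixture around its class mixture (default 4).
#'   Within-class spread is what populates the uncertainty band and creates
#'   hard positives.
#' @param filler_fraction Fraction of the vocabulary reserved for the
#'   uniform ultra-rare filler topic (default 0.3); filler terms end up with
#'   count SDs at or below the selection threshold, exercising the SD filter.
#' @param suffix_rate Fraction of rendered tokens carrying an inflectional
#'   suffix ("s"/"ed"/"ing") that stemming must strip (default 0.3).
#' @param seed Integer master seed; generation is fully deterministic.
#' @return An object of class `altriage_synthetic_spec`.
#' @export
synthetic_spec <- function(vocab_size = 5000L,
                           n_pos = 600L,
                           n_labeled_neg = 400L,
                           n_random = 9200L,
                           hidden_positive_rate = 0.002,
                           class_topic_mixtures = NULL,
                           topic_concentration = 0.05,
                           doc_length_mean = 180,
                           overlap_labeledneg_background = 0.5,
                           doc_mixture_concentration = 4,
                           filler_fraction = 0.3,
                           suffix_rate = 0.3,
                           seed = 1L) {
  if (vocab_size < length(SYN_TOPICS)) {
    stop_altriage("vocab_size must be at least the number of topics", "bad_spec")
  }
  if (!(hidden_positive_rate >= 0 && hidden_positive_rate < 0.05)) {
    stop_altriage("hidden_positive_rate must be in [0, 0.05)", "bad_spec")
  }
  o <- overlap_labeledneg_background
  if (!(is_scalar_number(o) && o >= 0 && o <= 1)) {
    stop_altriage("overlap_labeledneg_background must be in [0, 1]", "bad_spec")
  }
  if (is.null(class_topic_mixtures)) {
    # Positives and labeled negatives both come from a drug-interaction
    # keyword query, so they share the drug topic heavily and the negatives
    # carry a sliver of the DDI-safety core; positives also use some general
    # background vocabulary that the labeled negatives barely cover, and the
    # background pool contains drug-related documents. The labeled-negative
    # class covers a fraction `o` of the background topic mass.
    # the filler topic gets a tiny weight: spread uniformly over its large
    # vocabulary block, each filler term appears a handful of times in the
    # whole corpus, which keeps its count SD at or below the selection
    # threshold -- the block the SD filter exists to remove
    class_topic_mixtures <- rbind(
      positive    = c(0.378, 0.289, 0.000, 0.210, 0.118, 0.005),
      labeled_neg = c(0.064, 0.342, 0.589 * (1 - o), 0.460 * o, 0.129 * o, 0.005),
      background  = c(0.054, 0.161, 0.050, 0.394, 0.336, 0.005)
    )
    colnames(class_topic_mixtures) <- SYN_TOPICS
  }
  class_topic_mixtures <- as.matrix(class_topic_mixtures)
  if (!all(dim(class_topic_mixtures) == c(3, 6)) ||
      any(class_topic_mixtures < 0) ||
      any(abs(rowSums(class_topic_mixtures) - 1) > 1e-8)) {
    stop_altriage(
      "class_topic_mixtures must be 3 x 6, non-negative, rows summing to 1",
      "bad_spec"
    )
  }
  structure(
    list(vocab_size = as.integer(vocab_size), n_pos = as.integer(n_pos),
         n_labeled_neg = as.integer(n_labeled_neg),
         n_random = as.integer(n_random),
         hidden_positive_rate = hidden_positive_rate,
         class_topic_mixtures = class_topic_mixtures,
         topic_concentration = topic_concentration,
         doc_length_mean = doc_length_mean,
         overlap_labeledneg_background = o,
         doc_mixture_concentration = doc_mixture_concentration,
         filler_fraction = filler_fraction,
         suffix_rate = suffix_rate,
         seed = as.integer(seed)),
    class = "altriage_synthetic_spec"
  )
}

#' Study-scale synthetic specification
#'
#' Returns [synthetic_spec()] defaults with the overlap structure arranged so
#' that the corpus exhibits the two failure modes the dual-model workflows
#' address: (a) a classifier trained on positives vs labeled negatives has
#' degraded precision on the random pool (including false positives scored
#' above 0.7, which makes high-confidence mining non-trivial), because
#' positives share general background vocabulary that labeled negatives only
#' partially cover; and (b) uncertainty samples concentrate in the
#' class-overlap region.
#'
#' @param ... Overrides passed to [synthetic_spec()] (e.g. `n_random`,
#'   `seed`).
#' @return An `altriage_synthetic_spec`.
#' @export
paper_like_spec <- function(...) {
  synthetic_spec(...)
}

# ---- synthetic vocabulary ---------------------------------------------------
# Deterministic pronounceable words built from CV syllables with a final
# consonant chosen so the word is its own Porter stem and stays that stem
# under "s"/"ed"/"ing" suffixing. Candidates failing that check are skipped,
# so the vocabulary depends only on its size.
.syn_vocab_cache <- new.env(parent = emptyenv())

make_vocab <- function(vocab_size) {
  key <- as.character(vocab_size)
  if (!is.null(.syn_vocab_cache[[key]])) return(.syn_vocab_cache[[key]])
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(cons, vow, paste0))          # 65 syllables
  fin <- c("k", "m", "p", "b", "f", "t", "d", "n")    # candidate final letters
  words <- character(0)
  idx <- 0L
  n_syl <- length(syl)
  while (length(words) < vocab_size) {
    i1 <- idx %% n_syl
    i2 <- (idx %/% n_syl) %% n_syl
    i3 <- (idx %/% (n_syl * n_syl)) %% length(fin)
    idx <- idx + 1L
    if (idx > n_syl * n_syl * length(fin)) {
      stop_altriage("vocab_size too large for the word constructor", "bad_spec")
    }
    w <- paste0(syl[i1 + 1], syl[i2 + 1], fin[i3 + 1])
    stems <- stem_tokens(c(w, paste0(w, c("s", "ed", "ing"))))
    if (all(stems == w)) words <- c(words, w)
  }
  words <- words[seq_len(vocab_size)]
  .syn_vocab_cache[[key]] <- words
  words
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  # zero-alpha components stay exactly zero
  g[alpha == 0] <- 0
  s <- sum(g)
  if (s == 0) return(rep(1 / length(alpha), length(alpha)))
  g / s
}

# topic-word distributions over vocabulary blocks
build_topics <- function(spec) {
  v <- spec$vocab_size
  n_filler <- max(1L, floor(spec$filler_fraction * v))
  n_core <- v - n_filler
  block_sizes <- diff(floor(seq(0, n_core, length.out = 6)))
  starts <- cumsum(c(0, block_sizes[-5]))
  topics <- matrix(0, nrow = v, ncol = 6,
                   dimnames = list(NULL, SYN_TOPICS))
  for (k in 1:5) {
    blk <- (starts[k] + 1):(starts[k] + block_sizes[k])
    topics[blk, k] <- rdirichlet1(rep(spec$topic_concentration, length(blk)))
  }
  topics[(n_core + 1):v, 6] <- 1 / n_filler # uniform ultra-rare filler
  topics
}

render_doc <- function(term_counts, words, suffix_rate) {
  toks <- rep.int(words, term_counts)
  if (length(toks) == 0) toks <- words[1]
  n <- length(toks)
  toks <- toks[sample.int(n)]
  pick <- runif(n) < suffix_rate
  if (any(pick)) {
    sfx <- sample(c("s", "ed", "ing"), sum(pick), replace = TRUE)
    toks[pick] <- paste0(toks[pick], sfx)
  }
  n_title <- min(8L, n)
  title <- paste(toks[seq_len(n_title)], collapse = " ")
  # sentence dressing exercises the normalizer: casing and punctuation
  substr(title, 1, 1) <- toupper(substr(title, 1, 1))
  abstract <- if (n > n_title) {
    paste0(paste(toks[(n_title + 1):n], collapse = " "), ".")
  } else ""
  list(title = title, abstract = abstract)
}

#' Generate a synthetic abstract corpus with ground truth
#'
#' Draws every document from its class's topic mixture: per-document mixture
#' ~ Dirichlet around the class mixture, length ~ Poisson, token counts ~
#' multinomial under the mixed topic-word distribution, rendered as synthetic
#' word strings (some suffixed). Labeled pools carry their labels; the
#' random pool is unlabeled and hides `Binomial(n_random,
#' hidden_positive_rate)` true positives.
#'
#' @param spec An [synthetic_spec()].
#' @return A list of class `altriage_synthesis` with elements `corpus` (a
#'   corpus tibble), `truth` (tibble: `doc_id`, `true_class` in
#'   `positive` / `labeled_neg_like` / `background`), and `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "altriage_synthetic_spec"))
  words <- make_vocab(spec$vocab_size)
  withr::with_seed(spec$seed, {
    topics <- build_topics(spec)
    n_hidden <- rbinom(1, spec$n_random, spec$hidden_positive_rate)
    classes <- c(
      rep("positive", spec$n_pos),
      rep("labeled_neg_like", spec$n_labeled_neg),
      # hidden positives at random positions in the random pool
      {
        cls <- rep("background", spec$n_random)
        if (n_hidden > 0) cls[sample.int(spec$n_random, n_hidden)] <- "positive"
        cls
      }
    )
    pool <- rep(c("labeled", "labeled", "random"),
                c(spec$n_pos, spec$n_labeled_neg, spec$n_random))
    label <- rep(c("positive", "negative", "unlabeled"),
                 c(spec$n_pos, spec$n_labeled_neg, spec$n_random))
    doc_id <- c(sprintf("P%05d", seq_len(spec$n_pos)),
                sprintf("N%05d", seq_len(spec$n_labeled_neg)),
                sprintf("R%05d", seq_len(spec$n_random)))
    mix_row <- c(positive = 1L, labeled_neg_like = 2L, background = 3L)
    n_doc <- length(doc_id)
    titles <- character(n_doc)
    abstracts <- character(n_doc)
    alpha0 <- spec$doc_mixture_concentration
    for (d in seq_len(n_doc)) {
      base_mix <- spec$class_topic_mixtures[mix_row[[classes[d]]], ]
      # shrink the per-document jitter toward the class mixture: every
      # document keeps a floor of its class's topical identity, so the
      # weakest positives stay separable in principle (hard, not hopeless)
      mix <- 0.35 * base_mix + 0.65 * rdirichlet1(alpha0 * base_mix)
      p_word <- as.numeric(topics %*% mix)
      len <- max(1L, rpois(1, spec$doc_length_mean))
      cnt <- as.integer(rmultinom(1, len, p_word))
      doc <- render_doc(cnt, words, spec$suffix_rate)
      titles[d] <- doc$title
      abstracts[d] <- doc$abstract
    }
  })
  corpus <- as_corpus(tibble(
    doc_id = doc_id, title = titles, abstract = abstracts,
    label = label, pool = pool
  ))
  structure(
    list(
      corpus = corpus,
      truth = tibble(doc_id = doc_id, true_class = classes),
      spec = spec
    ),
    class = "altriage_synthesis"
  )
}

#' @export
print.altriage_synthesis <- function(x, ...) {
  n_hidden <- sum(x$truth$true_class == "positive" &
                    x$corpus$pool == "random")
  cat("<altriage_synthesis> ", nrow(x$corpus), " documents (",
      x$spec$n_pos, " pos / ", x$spec$n_labeled_neg, " neg / ",
      x$spec$n_random, " random, ", n_hidden, " hidden positives)\n", sep = "")
  invisible(x)
}

#' Ground-truth labeling oracle
#'
#' Wraps a ground-truth table as a labeling authority standing in for manual
#' review: queried with document ids it returns `"positive"` for true
#' positives and `"negative"` otherwise, counting every newly requested
#' label (the manual-effort ledger). An optional label-noise rate flips each
#' returned label independently, for robustness experiments.
#'
#' @param truth Tibble with `doc_id` and `true_class` (as produced by
#'   [generate_corpus()]).
#' @param noise_rate Probability of flipping each returned label (default 0).
#' @param seed Seed for the noise draws.
#' @return An object of class `altriage_oracle`; use [oracle_label()] to
#'   query it and [oracle_query_count()] to read the effort counter.
#' @export
synthetic_oracle <- function(truth, noise_rate = 0, seed = 1L) {
  truth <- as_tibble(truth)
  stopifnot(all(c("doc_id", "true_class") %in% names(truth)))
  env <- new.env(parent = emptyenv())
  env$labels <- ifelse(truth$true_class == "positive", "positive", "negative")
  names(env$labels) <- truth$doc_id
  env$query_count <- 0L
  env$noise_rate <- noise_rate
  env$seed <- as.integer(seed)
  env$n_calls <- 0L
  structure(env, class = "altriage_oracle")
}

#' Query the oracle
#'
#' @param oracle An [synthetic_oracle()].
#' @param doc_ids Character vector of document ids to label.
#' @return Character vector of `"positive"`/`"negative"` labels; the
#'   oracle's query counter grows by `length(doc_ids)`.
#' @export
oracle_label <- function(oracle, doc_ids) {
  stopifnot(inherits(oracle, "altriage_oracle"))
  if (length(doc_ids) == 0) return(character(0))
  unknown <- setdiff(doc_ids, names(oracle$labels))
  if (length(unknown)) {
    stop_altriage(paste0("oracle has no ground truth for: ",
                         paste(head(unknown, 3), collapse = ", ")), "unknown_doc")
  }
  out <- unname(oracle$labels[doc_ids])
  if (oracle$noise_rate > 0) {
    oracle$n_calls <- oracle$n_calls + 1L
    flips <- withr::with_seed(
      derive_seed(oracle$seed, paste0("noise", oracle$n_calls)),
      runif(length(out)) < oracle$noise_rate
    )
    out[flips] <- ifelse(out[flips] == "positive", "negative", "positive")
  }
  oracle$query_count <- oracle$query_count + length(doc_ids)
  out
}

#' @rdname oracle_label
#' @export
oracle_query_count <- function(oracle) {
  stopifnot(inherits(oracle, "altriage_oracle"))
  oracle$query_count
}
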