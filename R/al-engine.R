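# Active-learning engine: the four workflow variants over training rounds.
#
# Variant                  random negs   dual models   validation update
# traditional                   no            no              no
# traditional_random_neg        yes           no              no
# dual_model                    yes           yes             no
# dual_model_val_update         yes           yes             yes
#
# ml1 = positives vs random negatives (present iff the variant uses random
# negatives); ml2 = positives vs manually labeled negatives (present iff the
# variant trains against labeled negatives, i.e. all but
# traditional_random_neg). The unlabeled pool is scored by ml1 when it
# exists (it is the model trained against the pool's own distribution),
# otherwise by ml2; configurable via `acquisition_model`.

AL_VARIANTS <- c("traditional", "traditional_random_neg",
                 "dual_model", "dual_model_val_update")

#' Active-learning workflow variant
#'
#' @param name One of `"traditional"`, `"traditional_random_neg"`,
#'   `"dual_model"`, `"dual_model_val_update"`.
#' @return A list of class `altriage_variant` with logical fields
#'   `uses_random_negatives`, `dual_models`, `updates_validation`.
#' @export
al_variant <- function(name = AL_VARIANTS) {
  name <- match.arg(name)
  structure(
    list(
      name = name,
      uses_random_negatives = name != "traditional",
      dual_models = name %in% c("dual_model", "dual_model_val_update"),
      updates_validation = name == "dual_model_val_update"
    ),
    class = "altriage_variant"
  )
}

#' Initial set sizes
#'
#' Defaults follow the study design: 200 positives and 200 labeled negatives
#' per training set, 1000 random negatives for the random-negative model,
#' and a 200/200/200 validation split (no random stratum for the traditional
#' variant).
#'
#' @param n_train_pos,n_train_neg,n_train_random Training strata sizes.
#' @param n_val_pos,n_val_neg,n_val_random Validation strata sizes.
#' @return A named list.
#' @export
al_sizes <- function(n_train_pos = 200L, n_train_neg = 200L,
                     n_train_random = 1000L, n_val_pos = 200L,
                     n_val_neg = 200L, n_val_random = 200L) {
  as.list(environment())
}

#' Split ratios for the validation-update variant
#'
#' How newly oracle-labeled documents are divided among the random-negative
#' training set, the labeled-negative training set, and the external
#' validation set.
#'
#' @param to_train_ml1,to_train_ml2,to_validation Non-negative fractions
#'   summing to 1 (defaults 0.4 / 0.3 / 0.3).
#' @return A named list of class `altriage_split_ratios`.
#' @export
split_ratios <- function(to_train_ml1 = 0.4, to_train_ml2 = 0.3,
                         to_validation = 0.3) {
  r <- c(to_train_ml1, to_train_ml2, to_validation)
  if (any(r < 0) || abs(sum(r) - 1) > 1e-8) {
    stop_altriage("split ratios must be non-negative and sum to 1", "bad_ratios")
  }
  structure(list(to_train_ml1 = to_train_ml1, to_train_ml2 = to_train_ml2,
                 to_validation = to_validation),
            class = "altriage_split_ratios")
}

# labeled-set tibble helper: doc_id + label (+ stratum for validation)
labeled_set <- function(doc_id, label, stratum = NULL) {
  out <- tibble(doc_id = doc_id, label = label)
  if (!is.null(stratum)) out$stratum <- stratum
  out
}

take_ids <- function(pool_ids, n, stratum, seed) {
  if (length(pool_ids) < n) {
    stop_altriage(paste0("insufficient documents for stratum '", stratum,
                         "': need ", n, ", have ", length(pool_ids)),
                  "insufficient_pool")
  }
  withr::with_seed(seed, sample(pool_ids, n))
}

#' Initialize active-learning state
#'
#' Draws seeded, pairwise-disjoint training and validation sets from the
#' corpus pools per the variant's design, and leaves the remaining random
#' pool documents as the unlabeled pool to be scored each round.
#'
#' @param corpus A corpus tibble with labeled positive/negative pools and an
#'   unlabeled random pool.
#' @param variant An [al_variant()] (or its name).
#' @param sizes An [al_sizes()] list.
#' @param seed Integer seed for the draws.
#' @return An object of class `altriage_al_state`: round counter, training
#'   set tibbles (`train_ml1` with strata `pos`/`random`, `train_ml2` with
#'   `pos`/`neg`), `validation` (strata `pos`/`neg`/`random`), and
#'   `unlabeled` doc ids.
#' @export
al_initialize <- function(corpus, variant, sizes = al_sizes(), seed = 1L) {
  if (is.character(variant)) variant <- al_variant(variant)
  stopifnot(inherits(variant, "altriage_variant"))
  corpus <- as_corpus(corpus)
  pos_ids <- corpus$doc_id[corpus$label == "positive" & corpus$pool == "labeled"]
  neg_ids <- corpus$doc_id[corpus$label == "negative" & corpus$pool == "labeled"]
  rand_ids <- corpus$doc_id[corpus$pool == "random"]

  tr_pos <- take_ids(pos_ids, sizes$n_train_pos, "training positives",
                     derive_seed(seed, "tr_pos"))
  val_pos <- take_ids(setdiff(pos_ids, tr_pos), sizes$n_val_pos,
                      "validation positives", derive_seed(seed, "val_pos"))
  tr_neg <- take_ids(neg_ids, sizes$n_train_neg, "training negatives",
                     derive_seed(seed, "tr_neg"))
  val_neg <- take_ids(setdiff(neg_ids, tr_neg), sizes$n_val_neg,
                      "validation negatives", derive_seed(seed, "val_neg"))

  tr_rand <- character(0)
  val_rand <- character(0)
  if (variant$uses_random_negatives) {
    tr_rand <- take_ids(rand_ids, sizes$n_train_random, "training random negatives",
                        derive_seed(seed, "tr_rand"))
  }
  if (variant$name != "traditional") {
    val_rand <- take_ids(setdiff(rand_ids, tr_rand), sizes$n_val_random,
                         "validation random negatives",
                         derive_seed(seed, "val_rand"))
  }

  train_ml1 <- if (variant$uses_random_negatives) {
    labeled_set(c(tr_pos, tr_rand),
                rep(c("positive", "negative"), c(length(tr_pos), length(tr_rand))),
                rep(c("pos", "random"), c(length(tr_pos), length(tr_rand))))
  } else NULL
  train_ml2 <- if (variant$name != "traditional_random_neg") {
    labeled_set(c(tr_pos, tr_neg),
                rep(c("positive", "negative"), c(length(tr_pos), length(tr_neg))),
                rep(c("pos", "neg"), c(length(tr_pos), length(tr_neg))))
  } else NULL
  validation <- labeled_set(
    c(val_pos, val_neg, val_rand),
    rep(c("positive", "negative", "negative"),
        c(length(val_pos), length(val_neg), length(val_rand))),
    rep(c("pos", "neg", "random"),
        c(length(val_pos), length(val_neg), length(val_rand)))
  )
  unlabeled <- setdiff(rand_ids, c(tr_rand, val_rand))

  structure(
    list(round = 1L, variant = variant,
         train_ml1 = train_ml1, train_ml2 = train_ml2,
         validation = validation, unlabeled = unlabeled,
         models = list(), seed = as.integer(seed)),
    class = "altriage_al_state"
  )
}

state_all_used <- function(state) {
  c(if (!is.null(state$train_ml1)) state$train_ml1$doc_id,
    if (!is.null(state$train_ml2)) state$train_ml2$doc_id,
    state$validation$doc_id)
}

# check pairwise disjointness of train/validation/unlabeled
assert_state_disjoint <- function(state) {
  sets <- list(
    train_ml1 = state$train_ml1$doc_id %||% character(0),
    train_ml2 = setdiff(state$train_ml2$doc_id %||% character(0),
                        state$train_ml1$doc_id %||% character(0)),
    validation = state$validation$doc_id,
    unlabeled = state$unlabeled
  )
  # train_ml1 and train_ml2 legitimately share the positive stratum; every
  # other pair must be disjoint
  if (length(intersect(c(sets$train_ml1, state$train_ml2$doc_id %||% character(0)),
                       sets$validation)) > 0 ||
      length(intersect(c(sets$train_ml1, state$train_ml2$doc_id %||% character(0)),
                       sets$unlabeled)) > 0 ||
      length(intersect(sets$validation, sets$unlabeled)) > 0) {
    stop_altriage("internal error: training/validation/unlabeled sets overlap",
                  "invariant")
  }
  invisible(TRUE)
}

# Model fit seeds are derived from the model name and its training-set
# composition, so refitting on unchanged data reproduces the identical model
# while any growth of the training set draws a fresh seed.
fit_state_models <- function(state, x, spec) {
  fit_one <- function(set, mname) {
    s <- spec
    s$seed <- derive_seed(spec$seed, paste0(mname, "_n", nrow(set)))
    fit_classifier(s, x[set$doc_id, , drop = FALSE], set$label)
  }
  models <- list()
  if (!is.null(state$train_ml1)) models$ml1 <- fit_one(state$train_ml1, "ml1")
  if (!is.null(state$train_ml2)) models$ml2 <- fit_one(state$train_ml2, "ml2")
  models
}

evaluate_state <- function(state, x, recall_target = 0.99) {
  val <- state$validation
  purrr::imap(state$models, function(model, mname) {
    p <- predict_proba(model, x[val$doc_id, , drop = FALSE])
    pred <- ifelse(p >= 0.5, "positive", "negative")
    m <- compute_metrics(confusion(pred, val$label))
    m$p_at_r <- precision_at_recall(p, val$label, recall_target)
    m$model <- mname
    m
  }) |> bind_rows()
}

route_acquired <- function(state, acquired, ratios, seed) {
  # acquired: tibble doc_id, prob, mechanism, label
  variant <- state$variant
  add_to <- function(set, docs, strata) {
    if (nrow(docs) == 0) return(set)
    bind_rows(set, labeled_set(docs$doc_id, docs$label, strata))
  }
  strata_for <- function(docs, set_kind) {
    # positives go to the positive stratum; oracle-confirmed negatives from
    # the random pool return to the random-negative stratum of ml1, the
    # labeled-negative stratum of ml2, and the "neg" stratum of validation
    # (they are manually labeled now)
    ifelse(docs$label == "positive", "pos",
           switch(set_kind, ml1 = "random", ml2 = "neg", val = "neg"))
  }
  if (!variant$updates_validation) {
    if (variant$name == "traditional") {
      state$train_ml2 <- add_to(state$train_ml2, acquired,
                                strata_for(acquired, "ml2"))
    } else if (variant$name == "traditional_random_neg") {
      state$train_ml1 <- add_to(state$train_ml1, acquired,
                                strata_for(acquired, "ml1"))
    } else {
      state$train_ml1 <- add_to(state$train_ml1, acquired,
                                strata_for(acquired, "ml1"))
      state$train_ml2 <- add_to(state$train_ml2, acquired,
                                strata_for(acquired, "ml2"))
    }
  } else {
    n <- nrow(acquired)
    shares <- c(ratios$to_train_ml1, ratios$to_train_ml2, ratios$to_validation)
    dest <- withr::with_seed(seed, {
      d <- rep(1:3, times = round_shares(n, shares))
      sample(d)
    })
    state$train_ml1 <- add_to(state$train_ml1, acquired[dest == 1, ],
                              strata_for(acquired[dest == 1, ], "ml1"))
    state$train_ml2 <- add_to(state$train_ml2, acquired[dest == 2, ],
                              strata_for(acquired[dest == 2, ], "ml2"))
    state$validation <- add_to(state$validation, acquired[dest == 3, ],
                               strata_for(acquired[dest == 3, ], "val"))
  }
  state
}

# largest-remainder apportionment of n into shares
round_shares <- function(n, shares) {
  raw <- n * shares / sum(shares)
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Run one active-learning round transition
#'
#' Scores the unlabeled pool with the acquisition model, draws uncertainty
#' samples (plus high-confidence positives when the variant uses random
#' negatives), labels them via the oracle, routes the newly labeled
#' documents into the training set(s) (and, for the validation-update
#' variant, the validation set), removes them from the pool, refits the
#' models, and advances the round counter. If the oracle fails the state is
#' returned unchanged.
#'
#' @param state An `altriage_al_state` whose models are fitted.
#' @param x Full documents x features matrix (rownames = doc ids).
#' @param oracle An [synthetic_oracle()] (or any object supporting
#'   [oracle_label()]).
#' @param sampling An [sampling_config()].
#' @param ratios An [split_ratios()] (used by the validation-update variant).
#' @param clf An [clf_spec()] used to refit models.
#' @param acquisition_model Which model(s) score the unlabeled pool for the
#'   uncertainty band: `"both"` (default when two models exist; the band is
#'   the union of the two models' bands, so each model's ambiguous region is
#'   represented), or `"ml1"` / `"ml2"` for a single scorer. High-confidence
#'   positive mining always uses the random-negative model when present --
#'   it is the model whose confident positives on the random pool are
#'   credible hidden-positive candidates.
#' @return The advanced `altriage_al_state`; its `acquisitions` field holds
#'   the acquisition log for the completed round.
#' @export
al_run_round <- function(state, x, oracle, sampling, ratios = split_ratios(),
                         clf = clf_spec(), acquisition_model = NULL) {
  stopifnot(inherits(state, "altriage_al_state"))
  variant <- state$variant
  acquisition_model <- acquisition_model %||%
    (if (length(state$models) > 1) "both" else names(state$models)[1])
  scorers <- if (acquisition_model == "both") names(state$models) else acquisition_model
  stopifnot(all(scorers %in% names(state$models)))

  pool_x <- x[state$unlabeled, , drop = FALSE]
  probs <- lapply(state$models[scorers], function(m) {
    if (length(state$unlabeled)) predict_proba(m, pool_x) else numeric(0)
  })
  # union of the scoring models' bands; the logged probability is the
  # primary scorer's (first model), the one closest to the band for docs
  # contributed by the other model
  in_band <- Reduce(`|`, lapply(probs, function(p) {
    p >= sampling$band_low & p <= sampling$band_high
  }))
  scores <- tibble(doc_id = state$unlabeled, prob = probs[[1]])
  band_scores <- scores[in_band, ]
  unc <- uncertainty_sample(
    tibble(doc_id = band_scores$doc_id,
           prob = pmin(pmax(band_scores$prob, sampling$band_low),
                       sampling$band_high)),
    sampling, seed = derive_seed(state$seed, paste0("unc_r", state$round))
  )
  unc$prob <- band_scores$prob[match(unc$doc_id, band_scores$doc_id)]
  unc$mechanism <- rep("uncertainty", nrow(unc))
  acq <- unc
  if (variant$uses_random_negatives) {
    miner <- if (!is.null(state$models$ml1)) "ml1" else scorers[1]
    mine_scores <- if (miner %in% scorers) {
      tibble(doc_id = state$unlabeled, prob = probs[[miner]])
    } else {
      tibble(doc_id = state$unlabeled,
             prob = predict_proba(state$models[[miner]], pool_x))
    }
    hc <- high_confidence_positives(mine_scores, sampling)
    hc$mechanism <- rep("high_conf_positive", nrow(hc))
    acq <- bind_rows(acq, hc[!hc$doc_id %in% acq$doc_id, ])
  }

  labels <- tryCatch(
    oracle_label(oracle, acq$doc_id),
    error = function(e) e
  )
  if (inherits(labels, "error")) {
    warn(paste0("oracle failed (", conditionMessage(labels),
                "); round aborted, state unchanged"))
    return(state)
  }
  acq$oracle_label <- labels
  acq$label <- labels
  acq$round <- rep(state$round, nrow(acq))

  new_state <- route_acquired(state, acq, ratios,
                              derive_seed(state$seed, paste0("split_r", state$round)))
  new_state$unlabeled <- setdiff(state$unlabeled, acq$doc_id)
  new_state$round <- state$round + 1L
  new_state$acquisitions <- bind_rows(
    state$acquisitions,
    acq[, c("round", "doc_id", "prob", "mechanism", "oracle_label")]
  )
  new_state$models <- fit_state_models(new_state, x, clf)
  assert_state_disjoint(new_state)
  new_state
}

set_sizes_row <- function(state) {
  count_strata <- function(set) {
    if (is.null(set)) return("")
    tab <- table(set$stratum)
    paste(paste0(as.integer(tab), c(pos = "+", neg = "-", random = "R")[names(tab)]),
          collapse = " ")
  }
  tibble(
    round = state$round,
    train_ml1 = count_strata(state$train_ml1),
    train_ml2 = count_strata(state$train_ml2),
    validation = count_strata(state$validation),
    n_unlabeled = length(state$unlabeled)
  )
}

#' Run a full active-learning experiment
#'
#' End-to-end driver: builds (or accepts) the feature space, initializes the
#' variant's training/validation sets, then alternates model fitting,
#' validation-set evaluation and sample acquisition for `rounds` rounds
#' (acquisition happens between rounds, so `rounds = 2` performs one
#' acquisition phase, the study design). All randomness derives from
#' `seed`.
#'
#' @param corpus A corpus tibble.
#' @param variant Variant name or [al_variant()].
#' @param oracle Labeling oracle for acquired documents.
#' @param clf An [clf_spec()].
#' @param sampling An [sampling_config()].
#' @param sizes An [al_sizes()].
#' @param ratios An [split_ratios()].
#' @param rounds Number of training rounds (default 2).
#' @param features Optional precomputed [select_features()] result; computed
#'   from the corpus when `NULL`.
#' @param x Optional precomputed feature matrix from [vectorize_corpus()].
#' @param recall_target Recall for the precision-at-recall metric (0.99).
#' @param seed Master seed.
#' @param acquisition_model See [al_run_round()].
#' @return An object of class `altriage_al_run`: per-round `metrics` tibble,
#'   `set_sizes` tibble, `acquisitions` log, per-round model list, final
#'   state, and the validation snapshots used at each round.
#' @export
al_run <- function(corpus, variant, oracle,
                   clf = clf_spec(),
                   sampling = sampling_config(),
                   sizes = al_sizes(),
                   ratios = split_ratios(),
                   rounds = 2L,
                   features = NULL, x = NULL,
                   recall_target = 0.99,
                   seed = 1L,
                   acquisition_model = NULL) {
  if (is.character(variant)) variant <- al_variant(variant)
  corpus <- as_corpus(corpus)
  if (is.null(x)) {
    if (is.null(features)) {
      features <- select_features(build_tdm(corpus))
    }
    x <- vectorize_corpus(corpus, features)
  }
  clf$seed <- derive_seed(seed, "clf")
  state <- al_initialize(corpus, variant, sizes, seed = derive_seed(seed, "init"))
  state$seed <- as.integer(derive_seed(seed, "rounds"))
  state$models <- fit_state_models(state, x, clf)
  assert_state_disjoint(state)

  metrics <- list()
  sizes_log <- list()
  models_by_round <- list()
  validation_by_round <- list()
  for (r in seq_len(rounds)) {
    m <- evaluate_state(state, x, recall_target)
    m$round <- r
    m$variant <- variant$name
    metrics[[r]] <- m
    sizes_log[[r]] <- set_sizes_row(state)
    models_by_round[[r]] <- state$models
    validation_by_round[[r]] <- state$validation
    if (r < rounds) {
      state <- al_run_round(state, x, oracle, sampling, ratios, clf,
                            acquisition_model)
    }
  }

  structure(
    list(
      variant = variant,
      metrics = bind_rows(metrics)[, c("variant", "round", "model", "tp", "fp",
                                       "tn", "fn", "recall", "precision", "f1",
                                       "p_at_r", "degenerate")],
      set_sizes = bind_rows(sizes_log),
      acquisitions = state$acquisitions %||%
        tibble(round = integer(), doc_id = character(), prob = numeric(),
               mechanism = character(), oracle_label = character()),
      models_by_round = models_by_round,
      validation_by_round = validation_by_round,
      final_state = state,
      features = features,
      x = x,
      recall_target = recall_target,
      seed = seed
    ),
    class = "altriage_al_run"
  )
}

#' @export
print.altriage_al_run <- function(x, ...) {
  cat("<altriage_al_run> variant=", x$variant$name, ", ",
      max(x$metrics$round), " round(s)\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' Combined retrieval decision from the dual models
#'
#' A deployed retriever needs one decision per document; the rule here is
#' conservative: retrieve only documents that both the random-negative model
#' and the labeled-negative model score at or above the threshold (AND
#' rule).
#'
#' @param ml1,ml2 Fitted `altriage_model`s sharing one feature space.
#' @param x Documents x features matrix.
#' @param threshold Probability threshold (default 0.5).
#' @return A tibble: `doc_id`, `prob_ml1`, `prob_ml2`, `retrieved`.
#' @export
combined_retrieve <- function(ml1, ml2, x, threshold = 0.5) {
  if (!identical(ml1$feature_terms, ml2$feature_terms)) {
    stop_altriage("models were fitted on different feature spaces", "feature_space")
  }
  p1 <- predict_proba(ml1, x)
  p2 <- predict_proba(ml2, x)
  tibble(
    doc_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    prob_ml1 = p1, prob_ml2 = p2,
    retrieved = p1 >= threshold & p2 >= threshold
  )
}
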