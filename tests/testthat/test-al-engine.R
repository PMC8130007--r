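# Engine tests run on the cached small synthetic corpus with scaled-down
# set sizes; the full-scale initialization example is checked separately.

engine_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      syn <- small_synthesis()
      f <- select_features(build_tdm(syn$corpus))
      cache <<- list(syn = syn, features = f,
                     x = vectorize_corpus(syn$corpus, f))
    }
    cache
  }
})

test_that("variant definitions encode the four workflow designs", {
  v <- lapply(c("traditional", "traditional_random_neg", "dual_model",
                "dual_model_val_update"), al_variant)
  expect_equal(vapply(v, `[[`, TRUE, "uses_random_negatives"),
               c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(vapply(v, `[[`, TRUE, "dual_models"),
               c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(vapply(v, `[[`, TRUE, "updates_validation"),
               c(FALSE, FALSE, FALSE, TRUE))
  expect_error(al_variant("fancy_new_method"))
  expect_error(split_ratios(0.5, 0.5, 0.5), class = "altriage_bad_ratios")
})

test_that("initialization reproduces the design's set sizes at full scale", {
  syn <- generate_corpus(synthetic_spec(vocab_size = 500, doc_length_mean = 30,
                                        seed = 77))
  st <- al_initialize(syn$corpus, "dual_model", seed = 1)
  expect_equal(nrow(st$train_ml1), 1200L) # 200+ and 1000R
  expect_equal(nrow(st$train_ml2), 400L)  # 200+ and 200-
  expect_equal(nrow(st$validation), 600L) # 200+ 200- 200R
  expect_equal(sum(st$validation$stratum == "random"), 200L)

  tr <- al_initialize(syn$corpus, "traditional", seed = 1)
  expect_null(tr$train_ml1)
  expect_equal(nrow(tr$train_ml2), 400L)
  expect_equal(nrow(tr$validation), 400L) # no random stratum
  expect_false("random" %in% tr$validation$stratum)

  # same seed, identical state; different seed, different draws
  st2 <- al_initialize(syn$corpus, "dual_model", seed = 1)
  expect_identical(st, st2)
  st3 <- al_initialize(syn$corpus, "dual_model", seed = 2)
  expect_false(identical(st$train_ml2$doc_id, st3$train_ml2$doc_id))
})

test_that("insufficient pools fail naming the stratum", {
  fx <- engine_fixture()
  too_much_random <- utils::modifyList(small_sizes(),
                                       list(n_train_random = 10000L))
  expect_error(
    al_initialize(fx$syn$corpus, "dual_model", too_much_random, seed = 1),
    "training random negatives", class = "altriage_insufficient_pool"
  )
  too_many_pos <- utils::modifyList(small_sizes(), list(n_train_pos = 10000L))
  expect_error(
    al_initialize(fx$syn$corpus, "traditional", too_many_pos, seed = 1),
    "training positives", class = "altriage_insufficient_pool"
  )
})

test_that("a full run keeps pools disjoint and accounts for every query", {
  fx <- engine_fixture()
  oracle <- synthetic_oracle(fx$syn$truth)
  run <- al_run(fx$syn$corpus, "dual_model_val_update", oracle,
                clf = clf_spec("logistic", seed = 1),
                sampling = sampling_config(uncertainty_budget = 80, seed = 2),
                sizes = small_sizes(), rounds = 2,
                features = fx$features, x = fx$x, seed = 31)
  st <- run$final_state

  # pairwise disjointness (training positives legitimately shared between
  # the two training sets)
  expect_length(intersect(st$train_ml1$doc_id, st$validation$doc_id), 0)
  expect_length(intersect(st$train_ml2$doc_id, st$validation$doc_id), 0)
  expect_length(intersect(st$train_ml1$doc_id, st$unlabeled), 0)
  expect_length(intersect(st$train_ml2$doc_id, st$unlabeled), 0)
  expect_length(intersect(st$validation$doc_id, st$unlabeled), 0)

  # pool shrinkage equals acquisitions; oracle effort equals the log length
  n0 <- length(al_initialize(fx$syn$corpus, "dual_model_val_update",
                             small_sizes(), seed = 31)$unlabeled)
  skip_if(n0 == 0)
  n_acq <- nrow(run$acquisitions)
  expect_equal(length(st$unlabeled), n0 - n_acq)
  expect_equal(oracle_query_count(oracle), n_acq)
  expect_false(any(duplicated(run$acquisitions$doc_id)))

  # validation grew by the acquired share routed to it
  expect_equal(nrow(st$validation),
               sum(small_sizes()$n_val_pos, small_sizes()$n_val_neg,
                   small_sizes()$n_val_random) +
                 sum(!run$acquisitions$doc_id %in%
                       c(st$train_ml1$doc_id, st$train_ml2$doc_id)))
})

test_that("an empty acquisition round changes only the round counter", {
  fx <- engine_fixture()
  oracle <- synthetic_oracle(fx$syn$truth)
  clf <- clf_spec("logistic", seed = 4)
  # traditional variant (no mining); place the band inside the widest gap of
  # the observed pool scores so it is empty by construction
  st <- al_initialize(fx$syn$corpus, "traditional", small_sizes(), seed = 8)
  st$models <- altriage:::fit_state_models(st, fx$x, clf)
  p <- sort(predict_proba(st$models$ml2,
                          fx$x[st$unlabeled, , drop = FALSE]))
  mid <- p[p > 0.05 & p < 0.95]
  gap_at <- which.max(diff(mid))
  lo <- mid[gap_at] + 1e-9
  hi <- mid[gap_at + 1] - 1e-9
  skip_if(hi <= lo)
  narrow <- sampling_config(band_low = lo, band_high = hi,
                            high_conf_threshold = max(hi, 0.7),
                            uncertainty_budget = 5, seed = 1)
  expect_warning(
    new_st <- al_run_round(st, fx$x, oracle, narrow, clf = clf),
    "empty"
  )
  expect_equal(new_st$round, st$round + 1L)
  expect_identical(new_st$train_ml2, st$train_ml2)
  expect_identical(new_st$unlabeled, st$unlabeled)
  # refit on unchanged data reproduces the identical model
  expect_identical(
    predict_proba(new_st$models$ml2, fx$x[st$validation$doc_id, ]),
    predict_proba(st$models$ml2, fx$x[st$validation$doc_id, ])
  )
  expect_equal(oracle_query_count(oracle), 0L)
})

test_that("an oracle failure aborts the round leaving the state unchanged", {
  fx <- engine_fixture()
  bad_truth <- fx$syn$truth[1:10, ] # misses most pool docs
  oracle <- synthetic_oracle(bad_truth)
  st <- al_initialize(fx$syn$corpus, "dual_model", small_sizes(), seed = 8)
  st$models <- altriage:::fit_state_models(st, fx$x, clf_spec("logistic", seed = 4))
  expect_warning(
    out <- al_run_round(st, fx$x, oracle, sampling_config(seed = 1),
                        clf = clf_spec("logistic", seed = 4)),
    "aborted"
  )
  expect_identical(out$round, st$round)
  expect_identical(out$train_ml1, st$train_ml1)
})

test_that("random-negative variants grow their positive stratum from hidden positives", {
  # a corpus whose random pool surely hides positives
  syn <- generate_corpus(synthetic_spec(
    vocab_size = 800L, n_pos = 150L, n_labeled_neg = 100L, n_random = 500L,
    doc_length_mean = 80, hidden_positive_rate = 0.04, seed = 17
  ))
  f <- select_features(build_tdm(syn$corpus))
  x <- vectorize_corpus(syn$corpus, f)
  oracle <- synthetic_oracle(syn$truth)
  run <- al_run(syn$corpus, "traditional_random_neg", oracle,
                clf = clf_spec("logistic", seed = 2),
                sampling = sampling_config(uncertainty_budget = 80, seed = 3),
                sizes = small_sizes(), rounds = 2, features = f, x = x,
                seed = 19)
  n_hidden_in_pool <- sum(
    syn$truth$doc_id %in% run$final_state$unlabeled &
      syn$truth$true_class == "positive"
  ) + sum(run$acquisitions$oracle_label == "positive")
  skip_if(n_hidden_in_pool == 0)
  tr <- run$final_state$train_ml1
  expect_gt(sum(tr$label == "positive"), small_sizes()$n_train_pos)
})

test_that("combined retrieval is the intersection of the per-model decisions", {
  fx <- engine_fixture()
  st <- al_initialize(fx$syn$corpus, "dual_model", small_sizes(), seed = 3)
  models <- altriage:::fit_state_models(st, fx$x, clf_spec("logistic", seed = 5))
  batch <- fx$x[st$unlabeled[1:50], , drop = FALSE]
  got <- combined_retrieve(models$ml1, models$ml2, batch, threshold = 0.5)
  p1 <- predict_proba(models$ml1, batch)
  p2 <- predict_proba(models$ml2, batch)
  expect_equal(got$retrieved, p1 >= 0.5 & p2 >= 0.5)
  # threshold 0 retrieves everything
  expect_true(all(combined_retrieve(models$ml1, models$ml2, batch, 0)$retrieved))

  m_other <- fit_classifier(clf_spec("logistic", seed = 1),
                            batch[, 1:10], rep(c("positive", "negative"), 25))
  expect_error(combined_retrieve(models$ml1, m_other, batch),
               class = "altriage_feature_space")
})

test_that("runs are reproducible and tidy accessors expose the results", {
  fx <- engine_fixture()
  mk <- function() {
    al_run(fx$syn$corpus, "dual_model_val_update",
           synthetic_oracle(fx$syn$truth),
           clf = clf_spec("logistic", seed = 1),
           sampling = sampling_config(uncertainty_budget = 40, seed = 2),
           sizes = small_sizes(), rounds = 2,
           features = fx$features, x = fx$x, seed = 47)
  }
  r1 <- mk()
  r2 <- mk()
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$acquisitions, r2$acquisitions)

  td <- tidy(r1)
  expect_true(all(c("variant", "round", "model", "recall", "precision",
                    "f1", "p_at_r") %in% names(td)))
  expect_equal(nrow(td), 4) # 2 rounds x 2 models
  g <- glance(r1)
  expect_equal(g$rounds, 2)
  expect_s3_class(autoplot(r1), "ggplot")
})
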