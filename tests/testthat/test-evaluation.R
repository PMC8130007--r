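test_that("confusion cells match hand tallies", {
  pred <- rep(c("positive", "negative"), each = 10)
  expect_equal(unclass(confusion(pred, pred))[c("tp", "fp", "tn", "fn")],
               list(tp = 10L, fp = 0L, tn = 10L, fn = 0L))
  inv <- ifelse(pred == "positive", "negative", "positive")
  expect_equal(unclass(confusion(inv, pred))[c("tp", "fp", "tn", "fn")],
               list(tp = 0L, fp = 10L, tn = 0L, fn = 10L))

  withr::with_seed(5, {
    p <- sample(c("positive", "negative"), 30, TRUE)
    t <- sample(c("positive", "negative"), 30, TRUE)
  })
  cm <- confusion(p, t)
  expect_equal(cm$tp, sum(p == "positive" & t == "positive"))
  expect_equal(cm$fp, sum(p == "positive" & t == "negative"))
  expect_equal(cm$tn, sum(p == "negative" & t == "negative"))
  expect_equal(cm$fn, sum(p == "negative" & t == "positive"))
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 30)
  expect_error(confusion(p[-1], t), class = "altriage_shape")
})

test_that("metric formulas reproduce printed worked examples", {
  m <- compute_metrics(list(tp = 190, fp = 2, tn = 198, fn = 10))
  expect_equal(round_half_up(c(m$recall, m$precision, m$f1)),
               c(0.95, 0.99, 0.97))
  m <- compute_metrics(list(tp = 199, fp = 98, tn = 510, fn = 10))
  expect_equal(round_half_up(c(m$recall, m$precision, m$f1)),
               c(0.95, 0.67, 0.79))
  # no positives at all: degenerate flag, metrics reported as 0
  m0 <- compute_metrics(list(tp = 0, fp = 0, tn = 25, fn = 0))
  expect_true(m0$degenerate)
  expect_equal(c(m0$recall, m0$precision, m0$f1), c(0, 0, 0))
})

test_that("precision at fixed recall handles separable and degenerate rankings", {
  truth <- rep(c("positive", "negative"), each = 20)
  sep <- c(runif(20, 0.8, 1), runif(20, 0, 0.2))
  expect_equal(precision_at_recall(sep, truth, 0.99), 1)
  # all scores equal: the single feasible threshold retrieves everything
  expect_equal(precision_at_recall(rep(0.5, 40), truth, 0.99), 0.5)
  expect_error(precision_at_recall(runif(10), rep("negative", 10)),
               class = "altriage_no_positives")
})

test_that("precision at recall equals exhaustive threshold enumeration", {
  withr::with_seed(77, {
    for (rep in 1:100) {
      n <- sample(10:200, 1)
      truth01 <- rbinom(n, 1, runif(1, 0.2, 0.8))
      if (sum(truth01) == 0) truth01[1] <- 1
      scores <- round(runif(n), sample(c(1, 2, 6), 1)) # force ties sometimes
      target <- sample(c(0.5, 0.8, 0.9, 0.99, 1), 1)
      expect_equal(
        precision_at_recall(scores, truth01, target),
        bf_precision_at_recall(scores, truth01, target)
      )
    }
  })
})

test_that("raising the recall target lowers the operating threshold", {
  # the chosen operating point retrieves at least as many documents as any
  # lower target's: reconstruct the implied retrieved counts via the same
  # brute-force sweep used for the equality oracle
  withr::with_seed(42, {
    scores <- runif(150)
    truth01 <- rbinom(150, 1, 0.4)
  })
  targets <- c(0.2, 0.5, 0.7, 0.9, 0.95, 0.99, 1)
  n_ret <- vapply(targets, function(tg) {
    cand <- c(sort(unique(scores), decreasing = TRUE), min(scores) - 1)
    for (t in cand) {
      if (sum(truth01 == 1 & scores >= t) / sum(truth01 == 1) >= tg) {
        return(sum(scores >= t))
      }
    }
  }, numeric(1))
  expect_true(all(diff(n_ret) >= 0))
  # and the reported precision matches the implied operating point each time
  for (i in seq_along(targets)) {
    expect_equal(precision_at_recall(scores, truth01, targets[i]),
                 bf_precision_at_recall(scores, truth01, targets[i]))
  }
})

test_that("uncertainty-subset evaluation is deterministic and flags one-class sets", {
  fix <- separable_xy(n = 40, seed = 3)
  m <- fit_classifier(clf_spec("logistic", seed = 1), fix$x, fix$y)
  acq <- tibble::tibble(doc_id = rownames(fix$x)[c(1:5, 25:30)],
                        label = fix$y[c(1:5, 25:30)])
  e1 <- evaluate_uncertainty_subset(m, acq, fix$x)
  e2 <- evaluate_uncertainty_subset(m, acq, fix$x)
  expect_identical(e1, e2)
  expect_false(e1$degenerate)

  one <- tibble::tibble(doc_id = rownames(fix$x)[1:4], label = fix$y[1:4])
  expect_true(evaluate_uncertainty_subset(m, one, fix$x)$degenerate)
  expect_error(evaluate_uncertainty_subset(m, one[0, ], fix$x),
               class = "altriage_empty_subset")
})

test_that("PCA diagnostics agree with prcomp and separate distinct groups", {
  withr::with_seed(21, {
    g1 <- matrix(rpois(40 * 6, 6), 40, 6)
    g2 <- matrix(rpois(40 * 6, 1), 40, 6)
    x <- rbind(g1, g2)
    colnames(x) <- paste0("t", 1:6)
    rownames(x) <- paste0("d", 1:80)
  })
  groups <- rep(c("a", "b"), each = 40)
  d <- distribution_diagnostics(x, groups)

  # cross-check scores against prcomp up to per-component sign
  ref <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  for (j in 1:2) {
    got <- d$projection[[paste0("pc", j)]]
    expect_gt(abs(stats::cor(got, ref$x[, j])), 0.9999)
  }

  # separated groups: between-centroid distance exceeds mean within-group
  # distance to the own centroid
  within <- d$projection |>
    dplyr::left_join(d$centroids, by = "group", suffix = c("", "_c")) |>
    dplyr::mutate(r = sqrt((pc1 - pc1_c)^2 + (pc2 - pc2_c)^2)) |>
    dplyr::pull(r)
  expect_gt(d$centroid_distances$distance[1], mean(within))

  # identical groups: centroid distance near zero relative to spread
  xx <- rbind(g1, g1)
  rownames(xx) <- paste0("e", 1:80)
  d2 <- distribution_diagnostics(xx, groups)
  expect_lt(d2$centroid_distances$distance[1], mean(within))
  expect_warning(distribution_diagnostics(x, c("solo", groups[-1])), "fewer than 2")
})
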