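# Evaluation: confusion matrices, recall/precision/F1, precision at fixed
# recall, model evaluation on acquired uncertainty subsets, and PCA-based
# distribution diagnostics.

#' Round half away from zero
#'
#' Display rounding used in the metric reports (2 decimals by default).
#' Unlike [round()], which rounds half to even, halves round up -- the
#' convention of printed results tables (e.g. 0.805 -> 0.81).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Confusion matrix for binary retrieval
#'
#' `"positive"` is the event class (a retrieved DDI-relevant abstract).
#'
#' @param predicted,truth Equal-length label vectors
#'   (`"positive"`/`"negative"`, logical, or 0/1).
#' @return An object of class `altriage_confusion`: list with integer `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
confusion <- function(predicted, truth) {
  p <- as_label01(predicted)
  t <- as_label01(truth)
  if (length(p) != length(t)) {
    stop_altriage("predicted and truth must have equal length", "shape")
  }
  structure(
    list(
      tp = sum(p == 1 & t == 1),
      fp = sum(p == 1 & t == 0),
      tn = sum(p == 0 & t == 0),
      fn = sum(p == 0 & t == 1)
    ),
    class = "altriage_confusion"
  )
}

#' @export
print.altriage_confusion <- function(x, ...) {
  cat("<altriage_confusion> TP=", x$tp, " FP=", x$fp,
      " TN=", x$tn, " FN=", x$fn, "\n", sep = "")
  invisible(x)
}

#' Recall, precision and F1 from a confusion matrix
#'
#' recall = TP/(TP+FN), precision = TP/(TP+FP), F1 = 2PR/(P+R). A zero
#' denominator reports the metric as 0 and raises the `degenerate` flag.
#'
#' @param cm An [confusion()] result, or a list/tibble with `tp`, `fp`, `tn`,
#'   `fn` fields.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `recall`, `precision`,
#'   `f1`, `degenerate`.
#' @export
compute_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  degenerate <- FALSE
  if (tp + fn > 0) r <- tp / (tp + fn) else { r <- 0; degenerate <- TRUE }
  if (tp + fp > 0) p <- tp / (tp + fp) else { p <- 0; degenerate <- TRUE }
  if (p + r > 0) f1 <- 2 * p * r / (p + r) else { f1 <- 0; degenerate <- TRUE }
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         recall = r, precision = p, f1 = f1, degenerate = degenerate)
}

#' Precision at a fixed recall target
#'
#' Sweeps decision thresholds over the observed score values (retrieval rule:
#' score >= threshold). Among thresholds whose recall reaches
#' `recall_target`, the highest threshold -- the most conservative feasible
#' operating point, retrieving the fewest documents -- is chosen, and its
#' precision returned; ties break toward higher precision. Retrieving
#' everything always attains recall 1, so a feasible threshold exists
#' whenever positives do.
#'
#' @param scores Numeric vector of positive-class scores or probabilities.
#' @param truth Labels aligned with `scores`.
#' @param recall_target Required recall (default 0.99).
#' @return Precision (scalar in `[0, 1]`) at the selected threshold.
#' @export
precision_at_recall <- function(scores, truth, recall_target = 0.99) {
  t01 <- as_label01(truth)
  if (length(scores) != length(t01)) {
    stop_altriage("scores and truth must have equal length", "shape")
  }
  n_pos <- sum(t01 == 1)
  if (n_pos == 0) stop_altriage("no positives in truth", "no_positives")

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- t01[ord]
  cum_tp <- cumsum(y)
  cum_ret <- seq_along(y)
  # candidate cuts: after the last occurrence of each distinct score value
  last_of_value <- which(c(s[-1] != s[-length(s)], TRUE))
  recall <- cum_tp[last_of_value] / n_pos
  precision <- cum_tp[last_of_value] / cum_ret[last_of_value]
  feasible <- which(recall >= recall_target)
  # first feasible cut = highest threshold; with tied precisions at the same
  # threshold value the cut is unique, so prefer the max precision among the
  # minimal-cut candidates (identical cut index)
  best <- feasible[1]
  precision[best]
}

#' Evaluate a model on an acquired uncertainty subset
#'
#' Restricts evaluation to the documents acquired (and oracle-labeled) in a
#' given round -- the "hard" samples -- so that a later-round model can be
#' compared with the model that selected them.
#'
#' @param model An `altriage_model`.
#' @param acquired A data frame with `doc_id` and `label` columns (oracle
#'   labels) for the acquired documents.
#' @param x Feature matrix containing (at least) the acquired documents as
#'   rows named by `doc_id`, in the model's feature space.
#' @param threshold Probability cut for the positive call (default 0.5).
#' @return A one-row metrics tibble as from [compute_metrics()];
#'   `degenerate` is `TRUE` when the subset has a single class.
#' @export
evaluate_uncertainty_subset <- function(model, acquired, x, threshold = 0.5) {
  if (NROW(acquired) == 0) stop_altriage("acquired subset is empty", "empty_subset")
  acquired <- as_tibble(acquired)
  missing <- setdiff(acquired$doc_id, rownames(x))
  if (length(missing)) {
    stop_altriage(paste0("acquired doc(s) absent from x: ",
                         paste(head(missing, 3), collapse = ", ")), "shape")
  }
  xs <- x[acquired$doc_id, , drop = FALSE]
  p <- predict_proba(model, xs)
  pred <- ifelse(p >= threshold, "positive", "negative")
  out <- compute_metrics(confusion(pred, acquired$label))
  if (length(unique(acquired$label)) < 2) out$degenerate <- TRUE
  out
}

# Top-k principal components by orthogonal (subspace) iteration on the
# centred matrix; works on sparse input without densifying and is
# deterministic (fixed initial basis).
pca_topk <- function(x, k = 2, max_iter = 200, tol = 1e-9) {
  n <- nrow(x)
  p <- ncol(x)
  mu <- Matrix::colMeans(x)
  # centred products: (X - 1 mu')' (X - 1 mu') v = X'(Xv) - mu (1'Xv) ...
  cp <- function(v) {
    xv <- as.numeric(x %*% v) - sum(mu * v) # centred scores
    as.numeric(Matrix::crossprod(x, xv)) - mu * sum(xv)
  }
  withr::with_seed(20561, q <- qr.Q(qr(matrix(stats::rnorm(p * k), p, k))))
  ev_old <- rep(0, k)
  for (it in seq_len(max_iter)) {
    z <- vapply(seq_len(k), function(j) cp(q[, j]), numeric(p))
    qr_z <- qr(z)
    q <- qr.Q(qr_z)
    ev <- abs(diag(qr.R(qr_z)))
    if (max(abs(ev - ev_old) / (ev + 1e-12)) < tol) break
    ev_old <- ev
  }
  # order by eigenvalue, fix sign so the largest-magnitude loading is positive
  ord <- order(ev, decreasing = TRUE)
  q <- q[, ord, drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(q[, j]))
    if (q[i_max, j] < 0) q[, j] <- -q[, j]
  }
  scores <- (as.matrix(x %*% q))
  scores <- sweep(scores, 2, as.numeric(crossprod(mu, q)))
  list(rotation = q, scores = scores)
}

#' Distribution diagnostics by principal component analysis
#'
#' Projects documents onto the top two principal components of the feature
#' matrix and reports per-group centroids and pairwise centroid distances.
#' Purely diagnostic: no decision in the workflow is made from it. Groups
#' with fewer than 2 documents are kept with a warning.
#'
#' @param x Documents x features matrix (rows named by doc_id).
#' @param groups Character vector of group labels, one per row of `x`
#'   (e.g. sample types: positive / labeled negative / random background).
#' @return An object of class `altriage_diagnostics`: list with `projection`
#'   (tibble: doc_id, pc1, pc2, group), `centroids` (tibble: group, pc1,
#'   pc2), and `centroid_distances` (tibble: group_a, group_b, distance).
#' @export
distribution_diagnostics <- function(x, groups) {
  if (nrow(x) != length(groups)) {
    stop_altriage("groups must have one entry per row of x", "shape")
  }
  if (length(unique(groups)) < 2) stop_altriage("need at least 2 groups", "shape")
  if (nrow(x) < 3) stop_altriage("need at least 3 documents", "shape")
  small <- names(which(table(groups) < 2))
  if (length(small)) {
    warn(paste0("group(s) with fewer than 2 documents: ",
                paste(small, collapse = ", ")))
  }
  pc <- pca_topk(x, k = 2)
  proj <- tibble(
    doc_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    pc1 = pc$scores[, 1], pc2 = pc$scores[, 2], group = groups
  )
  centroids <- proj |>
    group_by(.data$group) |>
    summarise(pc1 = mean(.data$pc1), pc2 = mean(.data$pc2), .groups = "drop")
  gs <- centroids$group
  pairs <- utils::combn(seq_along(gs), 2)
  centroid_distances <- tibble(
    group_a = gs[pairs[1, ]],
    group_b = gs[pairs[2, ]],
    distance = sqrt((centroids$pc1[pairs[1, ]] - centroids$pc1[pairs[2, ]])^2 +
                      (centroids$pc2[pairs[1, ]] - centroids$pc2[pairs[2, ]])^2)
  )
  structure(
    list(projection = proj, centroids = centroids,
         centroid_distances = centroid_distances),
    class = "altriage_diagnostics"
  )
}

#' @export
print.altriage_diagnostics <- function(x, ...) {
  cat("<altriage_diagnostics> ", nrow(x$projection), " documents, ",
      nrow(x$centroids), " groups\n", sep = "")
  print(x$centroid_distances)
  invisible(x)
}

#' @describeIn distribution_diagnostics Scatter plot of the 2-D projection
#'   colored by group.
#' @param object An `altriage_diagnostics` object.
#' @param ... Unused.
#' @export
autoplot.altriage_diagnostics <- function(object, ...) {
  ggplot2::ggplot(object$projection,
                  ggplot2::aes(x = .data$pc1, y = .data$pc2,
                               colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "sample type") +
    ggplot2::theme_minimal()
}
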