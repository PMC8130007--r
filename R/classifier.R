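# Probabilistic binary classifiers behind a single contract:
#   clf_spec()  -- family, regularization, calibration, seed
#   fit_classifier(spec, x, y) -> altriage_model
#   predict_proba(model, x)    -> P(positive) per row
#
# Two families:
#   "max_margin" -- linear hinge-loss SVM solved by dual coordinate descent
#                   (compiled, see src/), probabilities via seeded 3-fold
#                   Platt scaling of the decision values.
#   "logistic"   -- ridge-penalized logistic regression via glmnet; its
#                   outputs are probabilities already, so no calibration.

#' Specify a binary classifier
#'
#' @param family `"max_margin"` (linear hinge-loss SVM) or `"logistic"`
#'   (ridge logistic regression).
#' @param regularization Positive regularization strength. For the logistic
#'   family this is the glmnet `lambda`; for the max-margin family the SVM
#'   cost is `1 / regularization` (larger strength = smaller margin-violation
#'   penalty).
#' @param calibration `"platt"` or `"none"`. Max-margin scores must be Platt
#'   calibrated before they can be read as probabilities; `"none"` is only
#'   legal for families whose raw outputs are probabilities.
#' @param seed Integer seed driving every stochastic step of fitting
#'   (solver visiting order, calibration folds); fits are bit-reproducible.
#' @return An object of class `altriage_clf_spec`.
#' @export
clf_spec <- function(family = c("logistic", "max_margin"),
                     regularization = NULL,
                     calibration = NULL,
                     seed = 1L) {
  family <- match.arg(family)
  regularization <- regularization %||% switch(family, logistic = 0.05, max_margin = 1)
  if (!is_scalar_number(regularization) || regularization <= 0) {
    stop_altriage("regularization must be a positive scalar", "bad_spec")
  }
  calibration <- calibration %||% switch(family, logistic = "none", max_margin = "platt")
  calibration <- match.arg(calibration, c("none", "platt"))
  if (family == "max_margin" && calibration != "platt") {
    stop_altriage(
      "max_margin scores are not probabilities; calibration = \"platt\" is required",
      "bad_spec"
    )
  }
  structure(
    list(family = family, regularization = regularization,
         calibration = calibration, seed = as.integer(seed)),
    class = "altriage_clf_spec"
  )
}

as_label01 <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), c("positive", "negative"))
    if (length(bad)) {
      stop_altriage(paste0("labels must be positive/negative, got: ",
                           paste(bad, collapse = ", ")), "bad_labels")
    }
    return(as.integer(y == "positive"))
  }
  if (is.logical(y)) return(as.integer(y))
  if (is.numeric(y) && all(y %in% c(0, 1))) return(as.integer(y))
  stop_altriage("labels must be positive/negative, logical, or 0/1", "bad_labels")
}

as_dgc <- function(x) {
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

# Platt (1999) sigmoid fit on decision values, with the prior-corrected
# targets; deterministic BFGS on the negative log-likelihood.
platt_fit <- function(dv, y01) {
  n_pos <- sum(y01 == 1)
  n_neg <- sum(y01 == 0)
  t_pos <- (n_pos + 1) / (n_pos + 2)
  t_neg <- 1 / (n_neg + 2)
  targ <- ifelse(y01 == 1, t_pos, t_neg)
  nll <- function(par) {
    z <- par[1] * dv + par[2]
    # log(1 + exp(z)) computed stably
    lse <- ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
    sum(targ * lse + (1 - targ) * (lse - z))
  }
  init <- c(A = -1, B = log((n_neg + 1) / (n_pos + 1)))
  fit <- optim(init, nll, method = "BFGS", control = list(maxit = 200))
  list(A = unname(fit$par[1]), B = unname(fit$par[2]))
}

platt_apply <- function(platt, dv) {
  1 / (1 + exp(platt$A * dv + platt$B))
}

svm_fit_raw <- function(x, y01, cost, seed) {
  xt <- Matrix::t(x)
  # bias handled as an augmented constant feature
  xt <- rbind(xt, rep(1, ncol(xt)))
  w <- .svm_dcd(as_dgc(xt), ifelse(y01 == 1, 1, -1), cost,
                tol = 1e-4, max_epochs = 300L, seed = seed)
  list(w = w[-length(w)], b = w[length(w)])
}

svm_decision <- function(raw, x) {
  as.numeric(x %*% raw$w) + raw$b
}

# stratified fold assignment, deterministic for a seed
make_folds <- function(y01, k, seed) {
  fold <- integer(length(y01))
  withr::with_seed(seed, {
    for (cls in unique(y01)) {
      idx <- sample(which(y01 == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Fit a binary classifier
#'
#' @param spec An [clf_spec()].
#' @param x Documents x features count matrix (dense or sparse) with column
#'   names identifying the feature space.
#' @param y Labels: `"positive"`/`"negative"` strings or factor, logical, or
#'   0/1 numeric. Both classes must be present.
#' @return An object of class `altriage_model` bound to the feature space of
#'   `x`; identical inputs and seed give bit-identical models.
#' @export
fit_classifier <- function(spec, x, y) {
  stopifnot(inherits(spec, "altriage_clf_spec"))
  x <- as_dgc(x)
  y01 <- as_label01(y)
  if (nrow(x) != length(y01)) {
    stop_altriage("number of rows of x must match length of y", "shape")
  }
  if (nrow(x) < 2) stop_altriage("need at least 2 training rows", "shape")
  if (length(unique(y01)) < 2) {
    stop_altriage("degenerate training set: only one class present", "one_class")
  }
  if (is.null(colnames(x))) {
    stop_altriage("x must carry feature (column) names", "shape")
  }

  model <- list(spec = spec, feature_terms = colnames(x))
  if (spec$family == "logistic") {
    fit <- glmnet::glmnet(x, factor(y01, levels = c(0, 1)),
                          family = "binomial", alpha = 0,
                          lambda = spec$regularization, standardize = FALSE)
    model$glmnet <- fit
  } else {
    cost <- 1 / spec$regularization
    raw <- svm_fit_raw(x, y01, cost, derive_seed(spec$seed, "svm_fit"))
    model$svm <- raw
    if (spec$calibration == "platt") {
      k <- 3L
      fold <- make_folds(y01, k, derive_seed(spec$seed, "platt_folds"))
      dv_cv <- numeric(length(y01))
      for (f in seq_len(k)) {
        tr <- fold != f
        if (length(unique(y01[tr])) < 2) {
          # fall back to in-sample decision values for pathological folds
          dv_cv[fold == f] <- svm_decision(raw, x[fold == f, , drop = FALSE])
        } else {
          rf <- svm_fit_raw(x[tr, , drop = FALSE], y01[tr], cost,
                            derive_seed(spec$seed, paste0("svm_fold", f)))
          dv_cv[fold == f] <- svm_decision(rf, x[fold == f, , drop = FALSE])
        }
      }
      model$platt <- platt_fit(dv_cv, y01)
    }
  }
  structure(model, class = "altriage_model")
}

#' @export
print.altriage_model <- function(x, ...) {
  cat("<altriage_model> family=", x$spec$family,
      " calibration=", x$spec$calibration,
      " features=", length(x$feature_terms), "\n", sep = "")
  invisible(x)
}

check_feature_space <- function(model, x) {
  if (is.null(colnames(x)) || !identical(colnames(x), model$feature_terms)) {
    stop_altriage("feature space of x does not match the fitted model", "feature_space")
  }
}

#' Predict positive-class probabilities
#'
#' @param model An `altriage_model`.
#' @param x Matrix whose columns match the model's feature space exactly.
#' @return Numeric vector of P(positive) in `[0, 1]`, one per row of `x`, in
#'   input order.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "altriage_model"))
  x <- as_dgc(x)
  check_feature_space(model, x)
  if (model$spec$family == "logistic") {
    p <- as.numeric(predict(model$glmnet, x, type = "response"))
  } else {
    if (is.null(model$platt)) {
      stop_altriage("max_margin probabilities require Platt calibration", "bad_spec")
    }
    p <- platt_apply(model$platt, svm_decision(model$svm, x))
  }
  pmin(pmax(p, 0), 1)
}

#' Raw decision scores (margin or linear predictor)
#'
#' @inheritParams predict_proba
#' @return Numeric vector of uncalibrated decision values.
#' @export
decision_values <- function(model, x) {
  stopifnot(inherits(model, "altriage_model"))
  x <- as_dgc(x)
  check_feature_space(model, x)
  if (model$spec$family == "logistic") {
    as.numeric(predict(model$glmnet, x, type = "link"))
  } else {
    svm_decision(model$svm, x)
  }
}

#' Save / load a fitted model
#'
#' Round-trip is exact: a reloaded model reproduces predictions bit for bit.
#'
#' @param model An `altriage_model`.
#' @param path File path.
#' @return `save_model()`: `model` invisibly; `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "altriage_model"))
  saveRDS(model, path)
  invisible(model)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "altriage_model"))
  model
}
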