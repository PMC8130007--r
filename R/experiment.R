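# Multi-seed comparison study: the package's headline experiment. Runs
# chosen workflow variants and classifier families across replicate
# synthetic corpora and collects per-round validation metrics plus the
# round-1-uncertainty-subset evaluation, so directional questions ("does the
# validation-update variant improve precision at recall 0.99 from round 1 to
# round 2?") can be answered across seeds.

#' Run a multi-seed variant comparison study
#'
#' For each replicate seed a fresh synthetic corpus is generated from
#' `spec`, features are selected once per corpus, and every requested
#' (variant, family) combination is run for `rounds` rounds with its own
#' ground-truth oracle. Per-round validation metrics and the evaluation of
#' round-1 acquired uncertainty samples under the round-1 and round-2 models
#' are collected.
#'
#' @param n_seeds Number of replicate corpora (default 20).
#' @param variants Character vector of variant names to compare.
#' @param families Classifier families to compare.
#' @param spec An [synthetic_spec()] describing the corpus conditions; its
#'   own seed is replaced by a per-replicate derived seed.
#' @param sizes An [al_sizes()].
#' @param sampling An [sampling_config()].
#' @param ratios An [split_ratios()].
#' @param rounds Rounds per run (default 2).
#' @param sd_threshold Feature-selection threshold.
#' @param recall_target Recall for precision-at-recall (default 0.99).
#' @param seed Master seed; every corpus, draw and fit derives from it.
#' @param progress Print one line per replicate (default `FALSE`).
#' @return An object of class `altriage_study`: `metrics` (per seed /
#'   variant / family / model / round validation metrics),
#'   `uncertainty_eval` (per seed / variant / family / model F1 of the
#'   round-1 and round-2 models on round-1 acquired samples), and
#'   `acquisition_counts` (per run: acquisitions and hidden positives
#'   recovered).
#' @export
al_variant_study <- function(n_seeds = 20L,
                             variants = c("dual_model_val_update", "traditional"),
                             families = c("max_margin", "logistic"),
                             spec = paper_like_spec(n_random = 2000L),
                             sizes = al_sizes(),
                             sampling = sampling_config(),
                             ratios = split_ratios(),
                             rounds = 2L,
                             sd_threshold = 0.03,
                             recall_target = 0.99,
                             seed = 1L,
                             progress = FALSE) {
  metrics <- list()
  unc_eval <- list()
  acq_counts <- list()
  for (i in seq_len(n_seeds)) {
    spec_i <- spec
    spec_i$seed <- derive_seed(seed, paste0("corpus", i))
    syn <- generate_corpus(spec_i)
    tdm <- build_tdm(syn$corpus)
    features <- select_features(tdm, sd_threshold)
    x <- vectorize_corpus(syn$corpus, features)
    hidden_ids <- syn$truth$doc_id[syn$truth$true_class == "positive" &
                                     syn$corpus$pool == "random"]
    for (fam in families) {
      for (v in variants) {
        oracle <- synthetic_oracle(syn$truth,
                                   seed = derive_seed(seed, paste0("oracle", i)))
        run_seed <- derive_seed(seed, paste0("run", i, fam, v))
        run <- al_run(
          syn$corpus, v, oracle,
          clf = clf_spec(fam, seed = run_seed),
          sampling = sampling, sizes = sizes, ratios = ratios,
          rounds = rounds, features = features, x = x,
          recall_target = recall_target, seed = run_seed
        )
        m <- run$metrics
        m$seed_index <- i
        m$family <- fam
        metrics[[length(metrics) + 1]] <- m

        acq1 <- run$acquisitions[run$acquisitions$round == 1, ]
        acq_counts[[length(acq_counts) + 1]] <- tibble(
          seed_index = i, family = fam, variant = v,
          n_acquired = nrow(run$acquisitions),
          n_hidden_total = length(hidden_ids),
          n_hidden_recovered = sum(run$acquisitions$doc_id %in% hidden_ids &
                                     run$acquisitions$oracle_label == "positive")
        )
        if (nrow(acq1) > 0 && length(unique(acq1$oracle_label)) == 2 &&
            rounds >= 2) {
          acq_lab <- tibble(doc_id = acq1$doc_id, label = acq1$oracle_label)
          for (mname in names(run$models_by_round[[1]])) {
            for (r in 1:2) {
              ev <- evaluate_uncertainty_subset(
                run$models_by_round[[r]][[mname]], acq_lab, x
              )
              unc_eval[[length(unc_eval) + 1]] <- tibble(
                seed_index = i, family = fam, variant = v, model = mname,
                model_round = r, f1 = ev$f1, recall = ev$recall,
                precision = ev$precision
              )
            }
          }
        }
      }
    }
    if (progress) {
      message("replicate ", i, "/", n_seeds, " done")
    }
  }
  structure(
    list(
      metrics = bind_rows(metrics),
      uncertainty_eval = bind_rows(unc_eval),
      acquisition_counts = bind_rows(acq_counts),
      n_seeds = n_seeds, rounds = rounds, recall_target = recall_target,
      spec = spec, seed = seed
    ),
    class = "altriage_study"
  )
}

#' Summarize a variant study
#'
#' Per (variant, family, model): mean round-1 and round-2 precision at the
#' recall target, and the fraction of seeds where round 2 met or beat
#' round 1 (`improved_frac`); plus, where available, the fraction of seeds
#' where the round-2 model met or beat the round-1 model's F1 on the
#' round-1 acquired uncertainty samples (`unc_f1_improved_frac`).
#'
#' @param study An `altriage_study`.
#' @return A tibble with one row per variant / family / model.
#' @export
study_summary <- function(study) {
  stopifnot(inherits(study, "altriage_study"))
  wide <- study$metrics |>
    filter(.data$round %in% c(1, max(study$metrics$round))) |>
    mutate(round = ifelse(.data$round == 1, "r1", "r2")) |>
    select("seed_index", "family", "variant", "model", "round", "p_at_r") |>
    tidyr::pivot_wider(names_from = "round", values_from = "p_at_r")
  par_sum <- wide |>
    group_by(.data$variant, .data$family, .data$model) |>
    summarise(
      n_seeds = n(),
      p_at_r_round1 = mean(.data$r1),
      p_at_r_round2 = mean(.data$r2),
      improved_frac = mean(.data$r2 >= .data$r1),
      .groups = "drop"
    )
  if (nrow(study$uncertainty_eval) > 0) {
    unc_wide <- study$uncertainty_eval |>
      mutate(model_round = paste0("r", .data$model_round)) |>
      select("seed_index", "family", "variant", "model", "model_round", "f1") |>
      tidyr::pivot_wider(names_from = "model_round", values_from = "f1")
    unc_sum <- unc_wide |>
      group_by(.data$variant, .data$family, .data$model) |>
      summarise(
        unc_f1_round1 = mean(.data$r1),
        unc_f1_round2 = mean(.data$r2),
        unc_f1_improved_frac = mean(.data$r2 >= .data$r1),
        .groups = "drop"
      )
    par_sum <- left_join(par_sum, unc_sum,
                         by = c("variant", "family", "model"))
  }
  par_sum
}

#' @export
print.altriage_study <- function(x, ...) {
  cat("<altriage_study> ", x$n_seeds, " seeds, ",
      length(unique(x$metrics$variant)), " variant(s), ",
      length(unique(x$metrics$family)), " family(ies)\n", sep = "")
  print(study_summary(x))
  invisible(x)
}

#' @describeIn al_variant_study Round-1 vs round-2 precision-at-recall per
#'   seed, one panel per variant/family.
#' @param object An `altriage_study`.
#' @param ... Unused.
#' @export
autoplot.altriage_study <- function(object, ...) {
  d <- object$metrics |>
    filter(.data$model == ifelse("ml2" %in% object$metrics$model, "ml2", "ml1"))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$round), y = .data$p_at_r,
                                  group = .data$seed_index)) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::geom_point(size = 0.8, alpha = 0.5) +
    ggplot2::facet_grid(family ~ variant) +
    ggplot2::labs(x = "round",
                  y = paste0("precision at recall ", object$recall_target)) +
    ggplot2::theme_minimal()
}
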