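# Run configuration files (YAML) for the command-line workflow: one file
# captures variant, classifier, sampling, sizes, ratios, rounds and the
# master seed, so runs are reproducible from the config alone.

#' Assemble a run configuration
#'
#' @param variant Variant name (see [al_variant()]).
#' @param family Classifier family (see [clf_spec()]).
#' @param regularization,calibration Passed to [clf_spec()]; `NULL` uses the
#'   family defaults.
#' @param sampling An [sampling_config()].
#' @param sizes An [al_sizes()].
#' @param ratios An [split_ratios()].
#' @param rounds Number of rounds.
#' @param sd_threshold Feature-selection SD threshold.
#' @param recall_target Recall for precision-at-recall reporting.
#' @param seed Master seed.
#' @return A list of class `altriage_run_config`.
#' @export
run_config <- function(variant = "dual_model_val_update",
                       family = "logistic",
                       regularization = NULL,
                       calibration = NULL,
                       sampling = sampling_config(),
                       sizes = al_sizes(),
                       ratios = split_ratios(),
                       rounds = 2L,
                       sd_threshold = 0.03,
                       recall_target = 0.99,
                       seed = 1L) {
  variant <- al_variant(variant)$name # validates the name
  clf <- clf_spec(family, regularization, calibration, seed)
  structure(
    list(variant = variant,
         classifier = list(family = clf$family,
                           regularization = clf$regularization,
                           calibration = clf$calibration),
         sampling = unclass(sampling)[c("band_low", "band_high",
                                        "high_conf_threshold",
                                        "uncertainty_budget")],
         sizes = sizes,
         ratios = unclass(ratios),
         rounds = as.integer(rounds),
         sd_threshold = sd_threshold,
         recall_target = recall_target,
         seed = as.integer(seed)),
    class = "altriage_run_config"
  )
}

#' Write / read a run configuration as YAML
#'
#' The round trip is lossless: `read_run_config(write_run_config(cfg, p))`
#' reproduces every field.
#'
#' @param config An [run_config()].
#' @param path File path.
#' @return `write_run_config()`: `config`, invisibly; `read_run_config()`:
#'   the configuration.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "altriage_run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  needed <- c("variant", "classifier", "sampling", "sizes", "ratios",
              "rounds", "sd_threshold", "recall_target", "seed")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop_altriage(paste0("run config is missing field(s): ",
                         paste(missing, collapse = ", ")), "bad_config")
  }
  run_config(
    variant = raw$variant,
    family = raw$classifier$family,
    regularization = raw$classifier$regularization,
    calibration = raw$classifier$calibration,
    sampling = do.call(sampling_config, c(raw$sampling, list(seed = raw$seed))),
    sizes = do.call(al_sizes, raw$sizes),
    ratios = do.call(split_ratios, raw$ratios),
    rounds = raw$rounds,
    sd_threshold = raw$sd_threshold,
    recall_target = raw$recall_target,
    seed = raw$seed
  )
}

#' Execute a configured run and write its artifacts
#'
#' Runs the configured experiment on a corpus (with a synthetic ground-truth
#' oracle) and writes a run directory: `metrics.tsv`, `set_sizes.tsv`,
#' `acquisitions.tsv` and a copy of the configuration.
#'
#' @param config An [run_config()].
#' @param corpus A corpus tibble.
#' @param truth Ground-truth tibble for the oracle (see
#'   [synthetic_oracle()]).
#' @param out_dir Output directory (created if needed).
#' @return The `altriage_al_run`, invisibly.
#' @export
execute_run <- function(config, corpus, truth, out_dir) {
  stopifnot(inherits(config, "altriage_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  oracle <- synthetic_oracle(truth, seed = derive_seed(config$seed, "oracle"))
  tdm <- build_tdm(corpus)
  features <- select_features(tdm, config$sd_threshold)
  run <- al_run(
    corpus, config$variant, oracle,
    clf = clf_spec(config$classifier$family, config$classifier$regularization,
                   config$classifier$calibration, config$seed),
    sampling = do.call(sampling_config,
                       c(config$sampling, list(seed = config$seed))),
    sizes = do.call(al_sizes, config$sizes),
    ratios = do.call(split_ratios, config$ratios),
    rounds = config$rounds,
    features = features,
    recall_target = config$recall_target,
    seed = config$seed
  )
  write_tsv_plain(run$metrics, file.path(out_dir, "metrics.tsv"))
  write_tsv_plain(run$set_sizes, file.path(out_dir, "set_sizes.tsv"))
  write_tsv_plain(run$acquisitions, file.path(out_dir, "acquisitions.tsv"))
  write_run_config(config, file.path(out_dir, "config.yaml"))
  invisible(run)
}

# plain TSV writer for simple (no embedded tab/newline) tables
write_tsv_plain <- function(df, path) {
  lines <- c(
    paste(names(df), collapse = "\t"),
    do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col)) format(col, digits = 15, trim = TRUE) else as.character(col)
    }), sep = "\t"))
  )
  if (nrow(df) == 0) lines <- lines[1]
  writeLines(lines, path, useBytes = TRUE)
  invisible(df)
}
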