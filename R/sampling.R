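# Sample-acquisition mechanisms: uncertainty sampling in a probability band,
# high-confidence positive mining from the random pool, and seeded random
# pool construction.

#' Sampling configuration
#'
#' @param band_low,band_high Inclusive bounds of the uncertainty band on the
#'   positive-class probability (defaults 0.4 and 0.6): documents scored
#'   inside the band are the low-confidence candidates.
#' @param high_conf_threshold Probability above which (strictly) a random-pool
#'   document is treated as a candidate mislabeled positive and sent to the
#'   oracle (default 0.7).
#' @param uncertainty_budget Maximum number of band documents drawn per round
#'   (default 400).
#' @param seed Integer seed for the band subsampling.
#' @return An object of class `altriage_sampling_config`.
#' @export
sampling_config <- function(band_low = 0.4, band_high = 0.6,
                            high_conf_threshold = 0.7,
                            uncertainty_budget = 400L, seed = 1L) {
  ok <- is_scalar_number(band_low) && is_scalar_number(band_high) &&
    is_scalar_number(high_conf_threshold) &&
    band_low >= 0 && band_low < band_high && band_high <= 1 &&
    band_high <= high_conf_threshold && high_conf_threshold <= 1
  if (!ok) {
    stop_altriage(
      "need 0 <= band_low < band_high <= high_conf_threshold <= 1",
      "bad_sampling_config"
    )
  }
  if (!is_scalar_number(uncertainty_budget) || uncertainty_budget < 1) {
    stop_altriage("uncertainty_budget must be a positive integer", "bad_sampling_config")
  }
  structure(
    list(band_low = band_low, band_high = band_high,
         high_conf_threshold = high_conf_threshold,
         uncertainty_budget = as.integer(uncertainty_budget),
         seed = as.integer(seed)),
    class = "altriage_sampling_config"
  )
}

check_scores <- function(scores) {
  if (!is.data.frame(scores) || !all(c("doc_id", "prob") %in% names(scores))) {
    stop_altriage("scores must be a data frame with doc_id and prob columns", "shape")
  }
  as_tibble(scores)
}

#' Uncertainty sampling within a probability band
#'
#' Selects a uniformly random (seeded) subset of at most
#' `cfg$uncertainty_budget` documents whose predicted positive probability
#' lies inside the closed band `[band_low, band_high]`.
#'
#' @param scores A data frame with columns `doc_id` and `prob`, one row per
#'   pool document.
#' @param cfg An [sampling_config()].
#' @param seed Optional seed override (defaults to `cfg$seed`); the engine
#'   passes a per-round derived seed.
#' @return A tibble (`doc_id`, `prob`) of the selected documents. An empty
#'   band yields an empty tibble with a warning.
#' @export
uncertainty_sample <- function(scores, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "altriage_sampling_config"))
  scores <- check_scores(scores)
  band <- scores[scores$prob >= cfg$band_low & scores$prob <= cfg$band_high, ]
  if (nrow(band) == 0) {
    warn("uncertainty band is empty; nothing sampled")
    return(band)
  }
  n_take <- min(cfg$uncertainty_budget, nrow(band))
  idx <- withr::with_seed(seed %||% cfg$seed, sample.int(nrow(band), n_take))
  band[sort(idx), ]
}

#' High-confidence positive mining from the random pool
#'
#' Returns every random-pool document whose predicted positive probability
#' strictly exceeds `cfg$high_conf_threshold`. These are candidate positives
#' hiding among the presumed negatives; all of them are sent to the oracle
#' (no subsampling).
#'
#' @inheritParams uncertainty_sample
#' @return A tibble (`doc_id`, `prob`) of the mined documents.
#' @export
high_confidence_positives <- function(scores, cfg) {
  stopifnot(inherits(cfg, "altriage_sampling_config"))
  scores <- check_scores(scores)
  scores[scores$prob > cfg$high_conf_threshold, ]
}

#' Draw a random document pool
#'
#' Seeded uniform sample without replacement from a source corpus; the drawn
#' documents form the unreviewed "random" pool, so their labels are cleared
#' to `"unlabeled"` and their pool set to `"random"`.
#'
#' @param source A corpus tibble to draw from.
#' @param n Number of documents to draw (`n <= nrow(source)`).
#' @param seed Integer seed.
#' @return A corpus tibble of `n` documents.
#' @export
draw_random_pool <- function(source, n, seed = 1L) {
  source <- as_corpus(source)
  if (n > nrow(source)) {
    stop_altriage(paste0("cannot draw ", n, " documents from a source of ",
                         nrow(source)), "pool_too_small")
  }
  idx <- withr::with_seed(seed, sample.int(nrow(source), n))
  out <- source[idx, ]
  out$label <- "unlabeled"
  out$pool <- "random"
  out
}
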