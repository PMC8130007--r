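# broom-style accessors and plots for fitted AL runs.

#' @describeIn al_run Tidy per-round, per-model metrics of a fitted run.
#' @param x An `altriage_al_run`.
#' @param ... Unused.
#' @export
tidy.altriage_al_run <- function(x, ...) {
  x$metrics
}

#' @describeIn al_run One-row summary of a fitted run: variant, rounds,
#'   oracle effort, and the final round's headline metrics.
#' @export
glance.altriage_al_run <- function(x, ...) {
  last <- x$metrics[x$metrics$round == max(x$metrics$round), ]
  headline <- last[last$model == ifelse("ml2" %in% last$model, "ml2", "ml1"), ]
  tibble(
    variant = x$variant$name,
    rounds = max(x$metrics$round),
    n_acquired = nrow(x$acquisitions),
    final_model = headline$model,
    final_f1 = headline$f1,
    final_p_at_r = headline$p_at_r,
    recall_target = x$recall_target
  )
}

#' @describeIn al_run Metric trajectories by round, faceted per model.
#' @param object An `altriage_al_run`.
#' @export
autoplot.altriage_al_run <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$metrics,
    cols = c("recall", "precision", "f1", "p_at_r"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$round, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~model) +
    ggplot2::scale_x_continuous(breaks = unique(long$round)) +
    ggplot2::labs(x = "round", y = NULL, colour = NULL,
                  title = paste0("Active-learning run (", object$variant$name, ")")) +
    ggplot2::theme_minimal()
}

#' Plot the score distribution with sampling bands
#'
#' Histogram of pool probabilities with the uncertainty band and the
#' high-confidence mining threshold marked.
#'
#' @param scores Data frame with a `prob` column (pool scores).
#' @param cfg An [sampling_config()].
#' @return A ggplot object.
#' @export
plot_score_bands <- function(scores, cfg = sampling_config()) {
  scores <- check_scores(scores)
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$prob)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70") +
    ggplot2::annotate("rect", xmin = cfg$band_low, xmax = cfg$band_high,
                      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "orange") +
    ggplot2::geom_vline(xintercept = cfg$high_conf_threshold,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "P(positive)", y = "documents") +
    ggplot2::theme_minimal()
}
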