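#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-fold results of a cross-validated fit
#'
#' @param x A `vrt_cv` object from [cv_classify()].
#' @param ... Unused.
#' @return Tibble with one row per fold: confusion counts, `f1`,
#'   `accuracy` and the chosen hyperparameters as a list-column.
#' @export
tidy.vrt_cv <- function(x, ...) {
  dplyr::select(x$folds, -"scaling")
}

#' One-row summary of a cross-validated fit
#'
#' @param x A `vrt_cv` object.
#' @param ... Unused.
#' @return One-row tibble: `algorithm`, `k`, `mean_f1`, `mean_accuracy`.
#' @export
glance.vrt_cv <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm, k = x$k,
    mean_f1 = x$mean_f1, mean_accuracy = x$mean_accuracy
  )
}

#' Tidy feature importances
#'
#' @param x A `vrt_cv` object fitted with `importance = TRUE`.
#' @return Tibble `feature`, `importance`, sorted decreasing; scores sum
#'   to 1.
#' @export
importance_table <- function(x) {
  stopifnot(inherits(x, "vrt_cv"), !is.null(x$importance))
  tibble::tibble(
    feature = names(x$importance),
    importance = unname(x$importance)
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Plot per-trial F1 by feature set
#'
#' Line plot of the best mean F1 per trial for each feature set, the shape
#' of the study's model-comparison figure.
#'
#' @param object A `vrt_summary` from [classify_trials()].
#' @param metric `"mean_f1"` or `"mean_accuracy"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vrt_summary <- function(object, metric = c("mean_f1", "mean_accuracy"), ...) {
  metric <- match.arg(metric)
  best <- object |>
    dplyr::group_by(.data$trial_id, .data$feature_set) |>
    dplyr::summarise(value = max(.data[[metric]]), .groups = "drop")
  ggplot2::ggplot(
    best,
    ggplot2::aes(.data$trial_id, .data$value, colour = .data$feature_set)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:9) +
    ggplot2::labs(
      x = "Trial", colour = "Feature set",
      y = if (metric == "mean_f1") "Best mean F1" else "Best mean accuracy"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bubble plot of feature importances per trial
#'
#' Circle diameter encodes the normalised importance (in `[0, 1]`) of each
#' feature for the best model of each trial.
#'
#' @param summary A `vrt_summary` with an `importance` list-column.
#' @param feature_set Which feature set panel to plot.
#' @param top_n Keep the `top_n` features by mean importance.
#' @return A ggplot object.
#' @export
plot_importance <- function(summary, feature_set = "all", top_n = 12) {
  fs <- feature_set
  best <- summary |>
    dplyr::filter(.data$feature_set == fs, .data$best_f1) |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  long <- purrr::map_dfr(seq_len(nrow(best)), function(i) {
    imp <- best$importance[[i]]
    if (is.null(imp)) return(NULL)
    tibble::tibble(
      trial_id = best$trial_id[i],
      feature = names(imp), importance = unname(imp)
    )
  })
  keep <- long |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(m = mean(.data$importance), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$m)) |>
    dplyr::slice_head(n = top_n)
  long <- dplyr::semi_join(long, keep, by = "feature")
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$trial_id, .data$feature, size = .data$importance)
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_continuous(breaks = 1:9) +
    ggplot2::scale_size_area(max_size = 8, limits = c(0, 1)) +
    ggplot2::labs(x = "Trial", y = NULL, size = "Importance") +
    ggplot2::theme_minimal()
}

#' Plot one sensor stream
#'
#' Heading (raw and unwrapped, if present) and accelerometer channels
#' against time; a quick visual check of simulated or preprocessed
#' streams.
#'
#' @param stream A sensor-stream tibble.
#' @return A ggplot object.
#' @export
plot_stream <- function(stream) {
  keep <- intersect(
    c("heading", "heading_unwrapped", "ax", "ay", "az"), names(stream)
  )
  long <- stream |>
    dplyr::select("t", dplyr::all_of(keep)) |>
    tidyr::pivot_longer(-"t", names_to = "channel")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
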