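#' Plot learning curves
#'
#' One panel per metric (windowed reaching error, inverse-model error,
#' change in the inverse model, and the model-truth curves when present),
#' against trial number.
#'
#' @param object A `bomi_curves` tibble from [learning_curves()].
#' @param metrics Character vector of columns to show (default: all present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bomi_curves <- function(object,
                                 metrics = intersect(c("re", "ime", "dg",
                                                       "ime_model", "fme", "pe"),
                                                     names(object)),
                                 ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object)[, c("n", metrics)],
                              -"n", names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, levels = metrics)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "trial n", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an exponential learning-curve fit
#'
#' @param object A `bomi_expfit` from [fit_exponential()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bomi_expfit <- function(object, ...) {
  if (is.null(object$data)) stop("degenerate fit has no curve to plot", call. = FALSE)
  df <- object$data
  df$fit <- object$a * exp(-object$lambda * df$n) + object$c
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$y), colour = "grey40", linewidth = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "steelblue", linewidth = 0.8) +
    ggplot2::labs(x = "trial n", y = "series",
                  subtitle = sprintf("a=%.3g, lambda=%.3g, c=%.3g, R2=%.3f",
                                     object$a, object$lambda, object$c, object$r2)) +
    ggplot2::theme_minimal()
}

#' Plot cohort reaching-error curves
#'
#' Windowed reaching-error curves for each subject of a cohort, the
#' many-subjects learning figure.
#'
#' @param cohort A list of `bomi_subject`s from [make_cohort()].
#' @param metric Curve column to show.
#' @param r Window length.
#' @return A ggplot object.
#' @export
plot_cohort_curves <- function(cohort, metric = "re", r = 12) {
  long <- purrr::imap_dfr(cohort, function(s, i) {
    cv <- learning_curves(s$session, r = r)
    tibble::tibble(subject = paste0("S", i), n = cv$n, value = cv[[metric]])
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$value,
                                     colour = .data$subject)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "trial n", y = metric) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
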