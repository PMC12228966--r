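# autoplot methods for the package's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot GAN training history
#'
#' Critic and generator losses per generator step (critic losses averaged
#' over the 5 within-step updates), with the gradient-penalty term shown
#' separately.
#'
#' @param object a `utr_gan`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.utr_gan <- function(object, ...) {
  h <- object$history
  per_step <- dplyr::bind_rows(
    h |>
      dplyr::filter(.data$phase == "critic") |>
      dplyr::group_by(.data$step) |>
      dplyr::summarise(value = mean(.data$critic_loss),
                       .groups = "drop") |>
      dplyr::mutate(series = "critic loss"),
    h |>
      dplyr::filter(.data$phase == "critic") |>
      dplyr::group_by(.data$step) |>
      dplyr::summarise(value = mean(.data$gp_term), .groups = "drop") |>
      dplyr::mutate(series = "gradient penalty"),
    h |>
      dplyr::filter(.data$phase == "generator") |>
      dplyr::transmute(.data$step, value = .data$generator_loss,
                       series = "generator loss")
  )
  ggplot2::ggplot(per_step,
                  ggplot2::aes(x = .data$step, y = .data$value,
                               colour = .data$series)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "generator step", y = "loss", colour = NULL,
                  title = "WGAN-GP training history") +
    ggplot2::theme_minimal()
}

#' Plot an optimization trace
#'
#' Per-element score trajectories over iterations with the batch mean
#' overlaid.
#'
#' @param object a `utr_opt_trace`.
#' @param alpha per-element line transparency.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.utr_opt_trace <- function(object, alpha = 0.3, ...) {
  td <- tidy(object)
  mean_td <- td |>
    dplyr::group_by(.data$iteration) |>
    dplyr::summarise(score = mean(.data$score, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$iteration, y = .data$score)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$element), alpha = alpha,
                       colour = "grey40") +
    ggplot2::geom_line(data = mean_td, colour = "firebrick",
                       linewidth = 0.9) +
    ggplot2::labs(x = "iteration", y = "score",
                  title = paste("latent ascent:", object$config$objective)) +
    ggplot2::theme_minimal()
}

#' Plot metric distributions of an evaluation report
#'
#' Histogram per numeric metric (length, GC, nearest-neighbour distances,
#' MFE, motif counts).
#'
#' @param object a `utr_eval`.
#' @param bins histogram bins.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.utr_eval <- function(object, bins = 30, ...) {
  long <- object$per_seq |>
    dplyr::select(-dplyr::any_of(c("id", "seq"))) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "sequences",
                  title = "per-sequence metric distributions") +
    ggplot2::theme_minimal()
}
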