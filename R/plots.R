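# ggplot2 quick-look figures.

#' Plot a simulated time course
#'
#' One panel per state variable plus the stimulation signal.
#'
#' @param object a `reg1_timecourse`.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.reg1_timecourse <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                              names_to = "variable", values_to = "value")
  labels <- c(x1 = "Il6 mRNA", x2 = "Zc3h12a mRNA", x3 = "free Reg1",
              x4 = "14-3-3-bound Reg1", signal = "signal")
  long$variable <- factor(labels[long$variable], levels = unname(labels))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "abundance (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a synthetic observation table
#'
#' Replicate points and replicate means per genotype over time, one
#' panel per observable — the layout of the study's immunoblot and
#' RT-qPCR summaries.
#'
#' @param object a `reg1_observations` tibble.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.reg1_observations <- function(object, ...) {
  means <- object |>
    dplyr::group_by(.data$genotype, .data$time, .data$observable) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value,
                                       colour = .data$genotype)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = means) +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "value (a.u.)", colour = "genotype") +
    ggplot2::theme_minimal()
}

#' Plot a discrimination verdict
#'
#' Bar chart of predicted mRNA fixed points by genotype under the
#' matched free-Regnase-1 constraint.
#'
#' @param object a `reg1_verdict`.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.reg1_verdict <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("wt", "s513a"), names_to = "genotype",
                        values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observable, y = .data$value,
                                  fill = .data$genotype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      title = paste0(object$model, ": ",
                     if (object$consistent_with_no_difference)
                       "consistent with no genotype difference"
                     else "predicts a genotype difference"),
      x = NULL, y = "predicted fixed point (a.u.)") +
    ggplot2::theme_minimal()
}
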