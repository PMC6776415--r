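# ggplot2 figure methods

#' Plot metric curves
#'
#' One panel per metric, one line per subject, metric value against the
#' threshold axis. With a covariate table the lines are coloured by group.
#'
#' @param object A [metric_curves()] tibble.
#' @param covariates Optional covariate tibble with `id` and `group`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metric_curves <- function(object, covariates = NULL, ...) {
  df <- object
  if (!is.null(covariates)) {
    df <- dplyr::left_join(df, covariates[, c("id", "group")],
                           by = c(subject = "id"))
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$threshold, .data$value,
                                          group = .data$subject,
                                          colour = .data$group))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$threshold, .data$value,
                                          group = .data$subject))
  }
  p +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "network threshold", y = "global metric value") +
    ggplot2::theme_minimal()
}

#' Plot an MTPC result
#'
#' Absolute group t statistic along the threshold axis with the FWE-adjusted
#' critical value and any supra-critical clusters shaded.
#'
#' @param object An [mtpc()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mtpc_result <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$threshold, abs(.data$statistic))) +
    ggplot2::geom_hline(yintercept = object$t_crit, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$supra_critical)) +
    ggplot2::labs(x = "network threshold", y = "|t|",
                  colour = "supra-critical") +
    ggplot2::theme_minimal()
  if (nrow(object$clusters)) {
    shade <- object$clusters |>
      dplyr::mutate(xmin = object$thresholds[.data$start],
                    xmax = object$thresholds[.data$end])
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
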