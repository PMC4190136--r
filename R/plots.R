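km_step_data <- function(curve, label = NULL) {
  df <- tibble::tibble(
    time = c(0, curve$time),
    survival = c(1, curve$survival),
    surv_lo = c(1, pmax(curve$survival - qnorm(0.975) * curve$std_err, 0)),
    surv_hi = c(1, pmin(curve$survival + qnorm(0.975) * curve$std_err, 1))
  )
  if (!is.null(label)) df$group <- label
  df
}

#' Plot a Kaplan-Meier curve
#'
#' Step plot of the product-limit estimate with a pointwise 95% Greenwood
#' band and tick marks at censoring times.
#'
#' @param object A [km_estimate()] curve.
#' @param conf_band Draw the Greenwood confidence band?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, conf_band = TRUE, ...) {
  df <- km_step_data(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(time, survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months from start of reirradiation",
                  y = "Survival probability") +
    ggplot2::theme_minimal()
  if (conf_band) {
    p <- p + ggplot2::geom_step(ggplot2::aes(y = surv_lo), linetype = "dotted") +
      ggplot2::geom_step(ggplot2::aes(y = surv_hi), linetype = "dotted")
  }
  cens <- attr(object, "censor_times")
  if (length(cens)) {
    surv_at_cens <- km_surv_at(object, cens)
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(time = cens, survival = surv_at_cens),
      shape = 3, size = 1.5)
  }
  p
}

#' Plot per-group survival for a stratification
#'
#' One Kaplan-Meier step per risk group.
#'
#' @param object An [evaluate_stratification()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rerad_strat <- function(object, ...) {
  df <- dplyr::bind_rows(purrr::imap(object$curves, function(cv, lab) {
    km_step_data(cv, label = lab)
  }))
  ggplot2::ggplot(df, ggplot2::aes(time, survival, colour = group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months from start of reirradiation",
                  y = "Survival probability", colour = "Risk group") +
    ggplot2::theme_minimal()
}

#' Plot a point table
#'
#' Column chart of the points contributed by each factor level, annotated
#' with the underlying death rates.
#'
#' @param object A `point_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.point_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$level_label <- paste(df$factor_name, df$level, sep = ": ")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(level_label, points),
                                   y = points, fill = adverse)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f%%", rate_percent)),
                       hjust = -0.2, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Points (death rate / 10)",
      title = sprintf("Score variant %s (%g-month horizon)",
                      attr(object, "variant"), attr(object, "horizon"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
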