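# ggplot2 graphics --------------------------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot PVs stratified by a drug group label
#'
#' Jittered replicate PVs with group mean and standard-error bars, the layout
#' used to compare permeable vs impermeable or rule-compliant vs
#' non-compliant drugs.
#'
#' @param pv_table Tibble with `drug_id`, `pv`.
#' @param labels Tibble `drug_id`, `label` (logical) or named logical vector.
#' @param label_name Axis label for the grouping.
#' @return A ggplot object.
#' @export
plot_pv_groups <- function(pv_table, labels, label_name = "group") {
  if (is.logical(labels) && !is.null(names(labels))) {
    labels <- tibble::tibble(drug_id = names(labels), label = unname(labels))
  }
  data <- dplyr::inner_join(pv_table, labels, by = "drug_id")
  data <- data[!is.na(data$label), ]
  data$group <- ifelse(data$label, "pass", "fail")
  summ <- data |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean = mean(.data$pv),
                     se = sd(.data$pv) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(data, ggplot2::aes(x = .data$group, y = .data$pv)) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, colour = "grey40") +
    ggplot2::geom_pointrange(
      data = summ,
      ggplot2::aes(x = .data$group, y = .data$mean,
                   ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      colour = "firebrick", linewidth = 0.8
    ) +
    ggplot2::labs(x = label_name, y = "permeability value (PV)") +
    ggplot2::theme_classic()
}

#' Observed-vs-predicted plot for a QSAR fit
#'
#' @param object A `qsar_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qsar_fit <- function(object, ...) {
  data <- tibble::tibble(observed = object$observed, predicted = object$fitted)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "experimental PV", y = "predicted PV",
      subtitle = sprintf("r2 = %.3f, rmse = %.4f, n = %d",
                         object$r2, object$rmse, object$n_obs)
    ) +
    ggplot2::theme_classic()
}

#' Per-fold metric plot for a cross-validation result
#'
#' @param object A `qsar_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qsar_cv <- function(object, ...) {
  long <- object$per_fold |>
    tidyr::pivot_longer(c("r2_train", "r2_validation", "rmse_train", "rmse_validation"),
                        names_to = c("metric", "partition"), names_sep = "_",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$fold), y = .data$value,
                                     colour = .data$partition)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "fold", y = NULL, colour = NULL) +
    ggplot2::theme_classic()
}
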