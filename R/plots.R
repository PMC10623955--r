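#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve plot
#'
#' @param object A `ba_roc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ba_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_path(colour = "#2166AC", linewidth = 0.8) +
    ggplot2::annotate("point",
                      x = 1 - object$spec_at_cut, y = object$sens_at_cut,
                      colour = "#B2182B", size = 2) +
    ggplot2::labs(
      title = sprintf("AUC = %.3f (95%% CI %.3f-%.3f)",
                      object$auc, object$ci[1], object$ci[2]),
      subtitle = sprintf("Youden cutpoint %.4g (sens %.2f, spec %.2f)",
                         object$cutpoint, object$sens_at_cut, object$spec_at_cut),
      x = "1 - specificity", y = "Sensitivity") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' PCA score plot
#'
#' @param object A `ba_pca` object.
#' @param ... Unused.
#' @return A ggplot of the first two components, coloured by group when
#'   group labels were attached.
#' @export
autoplot.ba_pca <- function(object, ...) {
  ev <- object$explained_variance$proportion
  aes <- if ("group" %in% names(object$scores)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot2::ggplot(object$scores, aes) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ev[2])) +
    ggplot2::theme_minimal()
}

#' OPLS-DA score / VIP plot
#'
#' Predictive vs first orthogonal scores (when present), or a VIP bar chart
#' with `which = "vip"`.
#'
#' @param object A `ba_oplsda` model.
#' @param which "scores" (default) or "vip".
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ba_oplsda <- function(object, which = c("scores", "vip"), ...) {
  which <- match.arg(which)
  if (which == "vip") {
    d <- tidy.ba_oplsda(object) |> dplyr::arrange(.data$vip)
    d$ba <- factor(d$ba, levels = d$ba)
    return(
      ggplot2::ggplot(d, ggplot2::aes(x = .data$vip, y = .data$ba,
                                      fill = .data$vip > 1)) +
        ggplot2::geom_col(show.legend = FALSE) +
        ggplot2::geom_vline(xintercept = 1, linetype = 2) +
        ggplot2::scale_fill_manual(values = c(`TRUE` = "#B2182B",
                                              `FALSE` = "grey70")) +
        ggplot2::labs(x = "VIP (predictive component)", y = NULL) +
        ggplot2::theme_minimal()
    )
  }
  d <- tibble::tibble(
    t = object$t,
    t_o = if (object$n_orthogonal > 0) object$t_o[, 1] else 0,
    group = object$group
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$t_o,
                                  colour = .data$group)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "Predictive score t",
                  y = if (object$n_orthogonal > 0) "Orthogonal score t_o" else "") +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential features
#'
#' @param diff A tibble from [differential_bas()] or
#'   [differential_features()] (needs `log2_fc` and `p_value`).
#' @param p_threshold Significance line (default 0.05).
#' @return A ggplot.
#' @export
plot_volcano <- function(diff, p_threshold = 0.05) {
  stopifnot(all(c("log2_fc", "p_value") %in% names(diff)))
  label_col <- names(diff)[1]
  d <- diff |>
    dplyr::mutate(
      neglog10_p = -log10(.data$p_value),
      status = dplyr::case_when(
        .data$p_value >= p_threshold ~ "ns",
        .data$log2_fc > 0 ~ "up-in-AF",
        .data$log2_fc < 0 ~ "down-in-AF",
        TRUE ~ "ns"
      )
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc, y = .data$neglog10_p,
                                  colour = .data$status)) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey80") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      "up-in-AF" = "#B2182B", "down-in-AF" = "#2166AC", ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (AF / control, medians)",
                  y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}
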