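#' Shrinkage plot: posterior mean versus apparent log fold change
#'
#' Every gene's shrinkage estimate against its raw (floored) log10 fold
#' change, shaded by average log10 rpm; the identity line marks "no
#' shrinkage". Low-count genes sit well inside the line.
#'
#' @param object An `asc_fit` from [run_asc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.asc_fit <- function(object, ...) {
  d <- object$results[object$results$flag == "", ]
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$apparent_lfc, y = .data$delta_hat, colour = .data$avg_log_rpm
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_gradient(low = "grey80", high = "black") +
    ggplot2::labs(
      x = "apparent log10 fold change",
      y = "shrinkage estimate (posterior mean log10 fold change)",
      colour = "avg log10 rpm"
    ) +
    ggplot2::theme_minimal()
}

#' Posterior density of the log fold change for one gene
#'
#' @param object An `asc_posterior` from [compute_posterior()].
#' @param ... Unused.
#' @return A ggplot of the delta marginal with the posterior mean marked.
#' @export
autoplot.asc_posterior <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$delta_hat, linetype = 2) +
    ggplot2::labs(x = "log10 fold change", y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Two-sample expression scatter with selected genes highlighted
#'
#' log10 rpm in sample 2 against sample 1 (0.5-floored counts), with the
#' genes selected at the fit's posterior-probability cutoff drawn on top.
#'
#' @param fit An `asc_fit`.
#' @return A ggplot.
#' @export
plot_sample_scatter <- function(fit) {
  stopifnot(inherits(fit, "asc_fit"))
  d <- fit$results
  d$l1 <- log10(pmax(d$x1, 0.5) * 1e6 / fit$n1)
  d$l2 <- log10(pmax(d$x2, 0.5) * 1e6 / fit$n2)
  d$status <- ifelse(d$selected == 1, "selected", "other")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$l1, y = .data$l2,
                                  colour = .data$status)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(other = "grey70", selected = "red3")
    ) +
    ggplot2::labs(x = "log10 rpm, sample 1", y = "log10 rpm, sample 2",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Binned-SD diagnostic plot
#'
#' @param binned Output of [binned_sd_log_rpm()].
#' @return A ggplot of per-bin SD of the log rpm difference against mean
#'   expression.
#' @export
plot_binned_sd <- function(binned) {
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$mean_avg_log_rpm,
                                       y = .data$sd_log_ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "mean average log10 rpm (bin)",
                  y = "SD of log10 rpm difference") +
    ggplot2::theme_minimal()
}
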