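#' Plot a rejection table
#'
#' For a [run_scenario()] table: one panel per covariate, rejection
#' proportion by method with 2-SE Monte-Carlo error bars and the nominal
#' level marked. For a [sweep_imputations()] table (which carries an `m`
#' column): rejection proportion against the number of imputations, one
#' line per method.
#'
#' @param object A `rejection_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rejection_table
#' @export
autoplot.rejection_table <- function(object, ...) {
  cfg <- attr(object, "config")
  alpha <- if (!is.null(cfg)) cfg$alpha else 0.05
  if ("m" %in% names(object)) {
    p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$m, y = .data$rate,
                                              colour = .data$method)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "number of imputations (m)")
  } else {
    p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$method, y = .data$rate)) +
      ggplot2::geom_col(fill = "grey35") +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = pmax(.data$rate - 2 * .data$mc_se, 0),
                     ymax = pmin(.data$rate + 2 * .data$mc_se, 1)),
        width = 0.3
      ) +
      ggplot2::labs(x = NULL) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  }
  p +
    ggplot2::facet_wrap(~term) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::labs(y = "proportion of tests rejected",
                  title = "Rejection proportions by pooling method",
                  subtitle = "power for x1-x5, type-I error for x6; dashed line = nominal level") +
    ggplot2::ylim(0, 1)
}

#' Plot per-imputation p-values against the pooled summaries
#'
#' Shows the spread of the `m` per-imputation p-values for each covariate
#' together with every pooled p-value, mirroring the way heterogeneity
#' across imputations is usually displayed.
#'
#' @param tests Long per-imputation test results (columns `term`,
#'   `p.value`, one row per imputation x covariate).
#' @param pooled Output of [pool_tests()] on the same tests.
#' @return A ggplot object.
#' @export
plot_pooled_pvalues <- function(tests, pooled) {
  ggplot2::ggplot(tests, ggplot2::aes(x = .data$term, y = .data$p.value)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.4, size = 1) +
    ggplot2::geom_point(data = pooled,
                        ggplot2::aes(colour = .data$method), size = 2.5) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "p-value",
                  title = "Per-imputation p-values and pooled summaries")
}
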