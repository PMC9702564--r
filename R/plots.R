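# ggplot2 visualisations: effect scatter with fitted slopes, funnel plot,
# leave-one-out forest, and the report-level forest plot.

#' @importFrom ggplot2 ggplot aes geom_point geom_errorbar geom_errorbarh
#'   geom_abline geom_vline geom_hline geom_segment labs theme_bw
#'   scale_colour_brewer facet_grid
NULL

#' Scatter plot of harmonized effects with fitted causal slopes
#'
#' Outcome effects against exposure effects (oriented to positive exposure
#' effects, as in the Egger fit), one fitted line per estimator.
#'
#' @param object An `mr_result` from [mr_all()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_result
#' @export
autoplot.mr_result <- function(object, ...) {
  rec <- object$data$records
  flip <- sign(rec$gamma)
  flip[flip == 0] <- 1
  pts <- tibble(
    gamma = rec$gamma * flip, Gamma = rec$Gamma * flip,
    sigma_x = rec$sigma_x, sigma_y = rec$sigma_y
  )
  fits <- bind_rows(lapply(object$estimates, function(e) {
    tibble(
      method = e$method, slope = e$beta_hat,
      intercept = e$intercept$estimate %||% 0
    )
  }))
  ggplot(pts, aes(x = .data$gamma, y = .data$Gamma)) +
    geom_errorbar(
      aes(
        ymin = .data$Gamma - Z95 * .data$sigma_y,
        ymax = .data$Gamma + Z95 * .data$sigma_y
      ),
      width = 0, colour = "grey70"
    ) +
    geom_errorbarh(
      aes(
        xmin = .data$gamma - Z95 * .data$sigma_x,
        xmax = .data$gamma + Z95 * .data$sigma_x
      ),
      height = 0, colour = "grey70"
    ) +
    geom_point(size = 1.8) +
    geom_abline(
      data = fits,
      aes(slope = .data$slope, intercept = .data$intercept, colour = .data$method)
    ) +
    scale_colour_brewer(palette = "Dark2") +
    labs(
      x = "SNP effect on exposure", y = "SNP effect on outcome",
      colour = NULL,
      title = paste0(object$data$exposure_name, " → ", object$data$outcome_name)
    ) +
    theme_bw()
}

#' Funnel plot of per-SNP ratios against precision
#'
#' @param object An `mr_funnel` tibble from [funnel_data()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_funnel
#' @export
autoplot.mr_funnel <- function(object, ...) {
  full <- attr(object, "full")
  ggplot(object, aes(x = .data$ratio, y = .data$precision)) +
    geom_vline(xintercept = full$beta_hat, linetype = 2, colour = "steelblue") +
    geom_point() +
    labs(
      x = "Per-SNP causal estimate (Wald ratio)",
      y = expression(Precision ~ (1 / SE)),
      caption = paste0(
        "weighted sign-symmetry = ",
        formatC(attr(object, "symmetry"), digits = 3, format = "fg")
      )
    ) +
    theme_bw()
}

#' Leave-one-out forest plot
#'
#' @param object An `mr_loo` tibble from [mr_leave_one_out()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_loo
#' @export
autoplot.mr_loo <- function(object, ...) {
  full <- attr(object, "full")
  df <- as_tibble(object)
  df$omitted_variant_id <- factor(df$omitted_variant_id,
    levels = rev(df$omitted_variant_id)
  )
  ggplot(df, aes(x = .data$estimate, y = .data$omitted_variant_id)) +
    geom_vline(xintercept = full$beta_hat, linetype = 2, colour = "steelblue") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    geom_point() +
    labs(x = "IVW estimate with SNP omitted", y = "Omitted SNP") +
    theme_bw()
}

#' Forest plot of report rows
#'
#' Odds ratios with 95% confidence intervals, grouped by exposure, on a log
#' scale with the null at OR = 1. Rows reaching Bonferroni significance are
#' marked `**`, nominal significance `*`.
#'
#' @param rows Report rows or an `mr_forest` table (see [forest_table()]).
#' @param methods Methods to display (default `"ivw"`).
#' @return A ggplot object.
#' @export
plot_forest <- function(rows, methods = "ivw") {
  if (!inherits(rows, "mr_forest")) rows <- forest_table(rows, methods = methods)
  df <- as_tibble(rows)
  df$label <- factor(df$label, levels = rev(unique(df$label)))
  ggplot(df, aes(x = .data$OR, y = .data$label)) +
    geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$CI_low, xmax = .data$CI_high), height = 0.2) +
    geom_point(aes(colour = .data$marker != ""), show.legend = FALSE) +
    ggplot2::geom_text(aes(label = .data$marker),
      nudge_y = 0.25, size = 3, colour = "black"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick")) +
    labs(x = "Odds ratio (95% CI)", y = NULL) +
    theme_bw()
}

#' @rdname plot_forest
#' @param object An `mr_forest` table.
#' @param ... Unused.
#' @method autoplot mr_forest
#' @export
autoplot.mr_forest <- function(object, ...) plot_forest(object)
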