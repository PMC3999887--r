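#' Plot a latent class fit
#'
#' Point estimates with central 95% credible intervals for `theta` and each
#' source's false-positive (`alpha`) and false-negative (`beta`) rate, on a
#' log10 scale (rates span orders of magnitude).
#'
#' @param object An `lca_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lca_fit
#' @export
autoplot.lca_fit <- function(object, ...) {
  s <- tidy(object)
  s$label <- ifelse(is.na(s$source), s$parameter,
                    paste0(sub("[0-9]+$", "", s$parameter), "[", s$source, "]"))
  s$group <- sub("[0-9]+$", "", s$parameter)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$mean, y = .data$label,
                                  xmin = .data$lower, xmax = .data$upper,
                                  colour = .data$group)) +
    ggplot2::geom_pointrange() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "posterior mean (95% interval)", y = NULL,
                  colour = "parameter",
                  title = "Latent class model estimates") +
    ggplot2::theme_minimal()
}

#' Barplot of agreement between evidence sources
#'
#' The concordance view of the union call set: one bar per observed agreement
#' pattern, labelled by the combination of sources, with counts and the
#' percentage of the union -- the standard way to display how much (or
#' little) callers agree.
#'
#' @inheritParams site_patterns
#' @return A ggplot object.
#' @export
plot_concordance <- function(sites, sources = NULL,
                             match_by = c("allele", "position")) {
  cs <- concordance_summary(sites, sources = sources, match_by = match_by)
  cs$sources <- factor(cs$sources, levels = rev(cs$sources))
  ggplot2::ggplot(cs, ggplot2::aes(x = .data$n, y = .data$sources)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$pct)),
                       hjust = -0.1, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, .15))) +
    ggplot2::labs(x = "sites", y = "agreeing sources",
                  title = "Agreement among evidence sources") +
    ggplot2::theme_minimal()
}

#' Plot a detection-error-tradeoff curve
#'
#' Sensitivity against the Ti/Tv specificity proxy across posterior cutoffs,
#' each point labelled with its cutoff.
#'
#' @param curve A tibble from [det_curve()].
#' @return A ggplot object.
#' @export
plot_det_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$titv, y = .data$sensitivity)) +
    ggplot2::geom_path(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = format(.data$cutoff)),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "Ti/Tv (specificity proxy)", y = "sensitivity (%)",
                  title = "Detection error tradeoff across posterior cutoffs") +
    ggplot2::theme_minimal()
}
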