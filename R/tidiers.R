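# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_line geom_point
#'   geom_col geom_errorbarh geom_vline labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' @export
tidy.hpl_logistic_fit <- function(x, ...) {
  tibble(term = x$terms, estimate = unname(x$coefficients))
}

#' @export
tidy.hpl_cox_fit <- tidy.hpl_logistic_fit

#' @export
tidy.hpl_cv <- function(x, ...) {
  x$coefficients
}

#' @export
glance.hpl_cv <- function(x, ...) {
  agg <- x$metrics %>% group_by(split, metric) %>%
    summarise(value = mean(value), .groups = "drop") %>%
    tidyr::unite("name", split, metric) %>%
    tidyr::pivot_wider(names_from = name, values_from = value)
  bind_cols(tibble(family = x$family, alpha = x$alpha,
                   l1_ratio = x$l1_ratio,
                   n_folds = dplyr::n_distinct(x$metrics$fold)), agg)
}

#' @export
tidy.hpl_bt_loss <- function(x, ...) {
  tibble(term = c("on_diag", "off_diag", "total"),
         value = c(x$on_diag_term, x$off_diag_term, x$total))
}

#' @export
tidy.hpl_shap <- function(x, ...) {
  tidyr::pivot_longer(x$values, dplyr::starts_with("hpc_"),
                      names_to = "term", values_to = "shap")
}

#' @export
autoplot.hpl_risk_groups <- function(object, ...) {
  ggplot(object$km, aes(time, surv, colour = group)) +
    geom_step() +
    labs(x = "Disease-free survival (months)", y = "S(t)",
         colour = "Risk group",
         subtitle = if (!is.null(object$logrank)) {
           sprintf("log-rank p = %.3g", object$logrank$p_value)
         } else NULL) +
    theme_minimal()
}

#' @export
autoplot.hpl_cv <- function(object, ...) {
  ggplot(object$metrics, aes(factor(fold), value, colour = split)) +
    geom_point(size = 2) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "Fold", y = NULL) +
    theme_minimal()
}

#' @export
autoplot.hpl_encoder <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$loss_trace, -epoch,
                            names_to = "term", values_to = "value")
  ggplot(tr, aes(epoch, value, colour = term)) +
    geom_line() +
    labs(x = "Epoch", y = "Loss component") +
    theme_minimal()
}

#' @export
autoplot.hpl_shap <- function(object, ...) {
  df <- tidy.hpl_shap(object) %>% group_by(term) %>%
    summarise(mean_abs = mean(abs(shap)), .groups = "drop") %>%
    arrange(mean_abs)
  df$term <- factor(df$term, levels = df$term)
  ggplot(df, aes(mean_abs, term)) +
    geom_col() +
    labs(x = "mean |SHAP|", y = NULL) +
    theme_minimal()
}

utils::globalVariables(c("shap", "mean_abs", "term", "mean_log_hr",
                         "combined_p", "presence_pct", "epoch"))

#' Forest plot of cross-validated Cox coefficients
#'
#' @param forest Output of [forest_summary()].
#' @param p_threshold Highlighting threshold for the combined p-value.
#' @return A ggplot object.
#' @export
plot_forest <- function(forest, p_threshold = 0.05) {
  df <- arrange(forest, mean_log_hr)
  df$term <- factor(df$term, levels = df$term)
  ggplot(df, aes(mean_log_hr, term,
                 colour = !is.na(combined_p) & combined_p < p_threshold)) +
    geom_point(aes(size = presence_pct)) +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = "Mean log hazard ratio (across folds)", y = NULL,
         colour = sprintf("p < %.2g", p_threshold),
         size = "% patients present") +
    theme_minimal()
}

#' Heatmap of the tile-adjacency interaction matrix
#'
#' Bi-hierarchically ordered via [cluster_interaction_heatmap()]; requires the
#' `pheatmap` package for drawing, otherwise returns the ordered matrix
#' silently.
#'
#' @param interactions Matrix from [adjacency_interactions()].
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return The ordered matrix (invisibly when drawn).
#' @export
plot_interactions <- function(interactions, ...) {
  ord <- cluster_interaction_heatmap(interactions)
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(ord$matrix, cluster_rows = ord$row_hclust,
                       cluster_cols = ord$col_hclust, ...)
    return(invisible(ord$matrix))
  }
  ord$matrix
}
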