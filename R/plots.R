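# Plotting helpers. Cosmetic layer only: nothing downstream depends on it.

matrix_long <- function(M, value_name) {
  ids <- rownames(M)
  tibble(row = factor(rep(ids, times = ncol(M)), levels = ids),
         col = factor(rep(ids, each = nrow(M)), levels = ids),
         value = as.vector(unclass(M))) |>
    setNames(c("row", "col", value_name))
}

#' Heatmap of a similarity or correlation matrix
#'
#' @param M a [cosine_similarity_matrix()] or [score_correlation_matrix()].
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_matrix_heatmap <- function(M, title = NULL) {
  df <- matrix_long(M, "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026", limits = c(-1, 1)) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$row))) +
    ggplot2::labs(x = NULL, y = NULL, title = title, fill = "value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Scatter of semantic similarity against score correlation
#'
#' One point per item pair (strict upper triangle): the package's central
#' empirical claim is that these points fall on an increasing trend.
#'
#' @param object an `alignment_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot alignment_report
#' @export
autoplot.alignment_report <- function(object, ...) {
  df <- tibble(similarity = upper_vec(unclass(object$S)),
               correlation = upper_vec(unclass(object$C)))
  r <- object$matrix_cor$estimate[object$matrix_cor$method == "pearson"]
  ggplot2::ggplot(df, ggplot2::aes(.data$similarity, .data$correlation)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "semantic similarity (cosine)",
                  y = "score correlation",
                  title = sprintf("Semantic-empirical alignment (r = %.2f)",
                                  r)) +
    ggplot2::theme_minimal()
}

#' Loading heatmap of a factor solution
#'
#' @param object a `factor_solution`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot factor_solution
#' @export
autoplot.factor_solution <- function(object, ...) {
  df <- tidy(object)
  df$item_id <- factor(df$item_id, levels = rev(rownames(object$loadings)))
  ggplot2::ggplot(df, ggplot2::aes(.data$factor, .data$item_id,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-item metric curve of an evaluation result
#'
#' @param object a `psychollm_eval`.
#' @param metric which per-item metric to draw.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot psychollm_eval
#' @export
autoplot.psychollm_eval <- function(object, metric = c("mae", "mape",
                                                       "exact_match_rate"),
                                    ...) {
  metric <- match.arg(metric)
  df <- object$per_item
  df$item_id <- factor(df$item_id, levels = df$item_id)
  ggplot2::ggplot(df, ggplot2::aes(.data$item_id, .data[[metric]],
                                   group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = metric,
                  title = sprintf("%s per item (%s)", toupper(metric),
                                  object$protocol)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
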