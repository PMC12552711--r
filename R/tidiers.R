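#' Tidy an alignment report
#'
#' @param x an `alignment_report` from [semantic_alignment()].
#' @param what which table: the per-item neighbor table, the Top-K
#'   accuracies, the matrix correlations, or the per-factor coefficients.
#' @param ... unused.
#' @return A tibble.
#' @method tidy alignment_report
#' @export
tidy.alignment_report <- function(x, what = c("neighbors", "top_k",
                                              "matrix_cor", "per_factor"),
                                  ...) {
  what <- match.arg(what)
  out <- x[[what]]
  if (is.null(out)) {
    abort(sprintf("This report has no `%s` component.", what),
          class = "psychollm_validation_error")
  }
  as_tibble(out)
}

#' @rdname tidy.alignment_report
#' @method glance alignment_report
#' @export
glance.alignment_report <- function(x, ...) {
  wide_acc <- setNames(as.list(x$top_k$accuracy),
                       sprintf("top_%d_accuracy", x$top_k$k))
  pear <- x$matrix_cor[x$matrix_cor$method == "pearson", ]
  spear <- x$matrix_cor[x$matrix_cor$method == "spearman", ]
  as_tibble(c(list(questionnaire = x$questionnaire_name,
                   n_respondents = x$n_respondents,
                   n_items = nrow(x$S)),
              wide_acc,
              list(pearson_r = pear$estimate, pearson_p = pear$p.value,
                   spearman_rho = spear$estimate, spearman_p = spear$p.value)))
}

#' Tidy a factor solution
#'
#' @param x a `factor_solution` from [factor_analyze()].
#' @param ... unused.
#' @return Long tibble: `item_id`, `factor`, `loading`, `assigned`.
#' @method tidy factor_solution
#' @export
tidy.factor_solution <- function(x, ...) {
  L <- x$loadings
  tibble(item_id = rep(rownames(L), ncol(L)),
         factor = rep(colnames(L), each = nrow(L)),
         loading = as.vector(L),
         assigned = rep(seq_len(ncol(L)), each = nrow(L)) ==
           rep(x$assignment, ncol(L)))
}

#' @rdname tidy.factor_solution
#' @method glance factor_solution
#' @export
glance.factor_solution <- function(x, ...) {
  tibble(n_items = nrow(x$loadings), n_factors = x$n_factors,
         rotation = x$rotation, criterion = x$criterion,
         mean_uniqueness = mean(x$uniquenesses))
}

#' Tidy a fitted PsychoLLM model
#'
#' @param x a `psychollm` model.
#' @param ... unused.
#' @return The learned per-item neighbor weight table
#'   (see [neighbor_weights()]).
#' @method tidy psychollm
#' @export
tidy.psychollm <- function(x, ...) neighbor_weights(x)

#' @rdname tidy.psychollm
#' @method glance psychollm
#' @export
glance.psychollm <- function(x, ...) {
  tibble(n_train_items = length(x$train_item_ids),
         n_respondents = nrow(x$train_scores),
         n_neighbors = x$config$n_neighbors,
         epochs = x$config$epochs,
         initial_mse = x$training_log$loss[1],
         final_mse = x$training_log$loss[nrow(x$training_log)])
}

#' Tidy an evaluation result
#'
#' @param x a `psychollm_eval`.
#' @param ... unused.
#' @return `tidy()`: the per-item metric tibble; `glance()`: one aggregate
#'   row (unweighted mean over items) with protocol metadata.
#' @method tidy psychollm_eval
#' @export
tidy.psychollm_eval <- function(x, ...) x$per_item

#' @rdname tidy.psychollm_eval
#' @method glance psychollm_eval
#' @export
glance.psychollm_eval <- function(x, ...) {
  dplyr::bind_cols(tibble(protocol = x$protocol, predictor = x$predictor,
                          n_items = nrow(x$per_item)),
                   x$aggregate)
}
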