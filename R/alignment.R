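#' Top-K semantic-empirical alignment accuracy
#'
#' For every item, find its most correlated partner (by absolute score
#' correlation) and ask whether that partner is among the item's K most
#' semantically similar items. The accuracy is the fraction of items for
#' which it is. Argmax ties in the correlation row are broken by ascending
#' item index with a warning.
#'
#' @param S a [cosine_similarity_matrix()].
#' @param C a [score_correlation_matrix()] computed with `absolute = TRUE`.
#' @param k neighborhood size, `1 <= k <= p - 1`.
#' @return A fraction in `[0, 1]`.
#' @export
top_k_accuracy <- function(S, C, k) {
  check_matched_items(S, C)
  if (!isTRUE(attr(C, "absolute"))) {
    abort("top_k_accuracy requires a correlation matrix with absolute = TRUE.",
          class = "psychollm_validation_error")
  }
  C <- subset_square(C, rownames(S))
  p <- nrow(S)
  if (k < 1 || k > p - 1) {
    abort(sprintf("k must be in [1, %d].", p - 1),
          class = "psychollm_validation_error")
  }
  nbrs <- neighbor_index_matrix(S, k)
  hits <- vapply(seq_len(p), function(j) {
    row <- C[j, ]
    row[j] <- -Inf
    mx <- max(row)
    cand <- which(row == mx)
    if (length(cand) > 1) {
      warn(sprintf(
        "Tied most-correlated partner for item %s; using the lowest index.",
        rownames(C)[j]))
    }
    m <- cand[1]
    m %in% nbrs[j, ]
  }, logical(1))
  mean(hits)
}

#' Correlation between a similarity matrix and a correlation matrix
#'
#' Vectorizes the strict upper triangles of both matrices (the unit
#' diagonals are excluded — including them would inflate the coefficient)
#' and correlates the two vectors. The default p-value comes from the usual
#' t statistic on `p(p-1)/2 - 2` degrees of freedom, which treats triangle
#' entries as independent; `test = "mantel"` gives a permutation test that
#' respects the matrix structure (one-sided, greater).
#'
#' @param S,C matrices over the same items.
#' @param method `"pearson"` or `"spearman"`.
#' @param test `"parametric"` (t-test) or `"mantel"` (permutation).
#' @param n_perm permutations for the Mantel test.
#' @param seed seed for the Mantel permutations.
#' @return A one-row tibble: `method`, `estimate`, `statistic`, `p.value`,
#'   `n_pairs`, `test`.
#' @export
matrix_correlation <- function(S, C, method = c("pearson", "spearman"),
                               test = c("parametric", "mantel"),
                               n_perm = 9999, seed = NULL) {
  method <- match.arg(method)
  test <- match.arg(test)
  check_matched_items(S, C)
  C <- C[rownames(S), rownames(S)]
  p <- nrow(S)
  if (p < 3) {
    abort("Need at least 3 items for a matrix correlation.",
          class = "psychollm_validation_error")
  }
  x <- upper_vec(unclass(S))
  y <- upper_vec(unclass(C))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Constant upper triangle: matrix correlation is undefined.",
          class = "psychollm_validation_error")
  }
  r <- cor(x, y, method = method)
  m <- length(x)
  if (test == "parametric") {
    denom <- max(1 - r^2, 0)
    tstat <- r * sqrt((m - 2) / denom) # Inf (p = 0) at |r| = 1
    pval <- 2 * pt(-abs(tstat), df = m - 2)
    stat <- tstat
  } else {
    seed <- seed %||% 1L
    perms <- withr::with_seed(as.integer(seed), {
      replicate(n_perm, sample.int(p), simplify = FALSE)
    })
    Cu <- unclass(C)
    null <- vapply(perms, function(pp) {
      cor(x, upper_vec(Cu[pp, pp]), method = method)
    }, numeric(1))
    pval <- (1 + sum(null >= r)) / (n_perm + 1)
    stat <- r
  }
  tibble(method = method, estimate = r, statistic = stat, p.value = pval,
         n_pairs = m, test = test)
}

#' Per-factor matrix correlation, averaged
#'
#' Restricts `S` and `C` to each factor's item block, computes the matrix
#' correlation within every block, and averages the coefficients without
#' weighting. Conditioning on factors avoids the coefficient being driven
#' by the coarse within/between-factor contrast alone.
#'
#' @inheritParams matrix_correlation
#' @param questionnaire a [questionnaire()] whose factor labels partition
#'   the items; every factor needs at least 3 items.
#' @return A list: `mean_estimate` and `by_factor` (tibble with one row per
#'   factor as from [matrix_correlation()]).
#' @export
per_factor_matrix_correlation <- function(S, C, questionnaire,
                                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  fac <- item_factors(questionnaire)
  if (anyNA(fac)) {
    abort(sprintf("Unlabeled item(s): %s.",
                  paste(names(fac)[is.na(fac)], collapse = ", ")),
          class = "psychollm_validation_error")
  }
  small <- names(which(table(fac) < 3))
  if (length(small)) {
    abort(sprintf("Factor(s) with fewer than 3 items: %s.",
                  paste(small, collapse = ", ")),
          class = "psychollm_validation_error")
  }
  by_factor <- purrr::map_dfr(sort(unique(fac)), function(f) {
    ids <- names(fac)[fac == f]
    res <- matrix_correlation(subset_square(S, ids), subset_square(C, ids),
                              method = method)
    mutate(res, factor = f, .before = 1)
  })
  list(mean_estimate = mean(by_factor$estimate), by_factor = by_factor)
}

subset_square <- function(M, ids) {
  out <- unclass(M)[ids, ids]
  attr(out, "absolute") <- attr(M, "absolute")
  class(out) <- class(M)
  out
}

check_matched_items <- function(S, C) {
  if (is.null(rownames(S)) || is.null(rownames(C)) ||
      !setequal(rownames(S), rownames(C)) ||
      anyDuplicated(rownames(S)) || anyDuplicated(rownames(C))) {
    abort("S and C must carry the same item ids.",
          class = "psychollm_validation_error")
  }
  invisible(TRUE)
}

#' Full semantic-empirical alignment report
#'
#' The pipeline's first step in one call: build the cosine similarity matrix
#' `S` and the absolute score correlation matrix `C`, compute Top-K accuracy
#' for each `k`, Pearson and Spearman matrix correlations (with t-test
#' p-values), the per-item nearest-neighbor table, and — when the
#' questionnaire carries factor labels with at least 3 items each — the
#' per-factor matrix correlations and their mean.
#'
#' @param responses response tibble.
#' @param questionnaire a [questionnaire()].
#' @param embeddings an [embedding_matrix()] over the same items.
#' @param ks Top-K neighborhood sizes to evaluate.
#' @param absolute use absolute correlations (the default; signed analysis
#'   is available for sensitivity checks but Top-K always uses magnitudes).
#' @return An `alignment_report`: list with tibbles `top_k`, `matrix_cor`,
#'   `neighbors`, optional `per_factor`, plus the `S` and `C` matrices.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
semantic_alignment <- function(responses, questionnaire, embeddings,
                               ks = 1:3, absolute = TRUE) {
  E <- align_embeddings(embeddings, questionnaire)
  S <- cosine_similarity_matrix(E)
  C <- score_correlation_matrix(responses, questionnaire, absolute = TRUE)
  C_signed <- if (!absolute) {
    score_correlation_matrix(responses, questionnaire, absolute = FALSE)
  }
  top_k <- tibble(
    k = as.integer(ks),
    accuracy = vapply(ks, function(k) top_k_accuracy(S, C, k), numeric(1)))
  matrix_cor <- bind_rows(
    matrix_correlation(S, C, "pearson"),
    matrix_correlation(S, C, "spearman"))
  kmax <- max(ks)
  neighbors <- purrr::map_dfr(rownames(S), function(id) {
    nb <- top_k_neighbors(S, id, kmax)
    tibble(item_id = id, rank = seq_len(kmax),
           neighbor_id = nb$item_id, similarity = nb$similarity)
  })
  fac <- item_factors(questionnaire)
  per_factor <- NULL
  if (!anyNA(fac) && all(table(fac) >= 3)) {
    # degenerate blocks (constant triangles, e.g. duplicated items) simply
    # leave the per-factor table out rather than failing the whole report
    per_factor <- tryCatch(
      bind_rows(
        per_factor_matrix_correlation(S, C, questionnaire,
                                      "pearson")$by_factor,
        per_factor_matrix_correlation(S, C, questionnaire,
                                      "spearman")$by_factor),
      error = function(e) NULL)
  }
  structure(
    list(questionnaire_name = attr(questionnaire, "q_name"),
         n_respondents = nrow(responses),
         top_k = top_k, matrix_cor = matrix_cor, neighbors = neighbors,
         per_factor = per_factor, S = S,
         C = if (absolute) C else C_signed),
    class = "alignment_report")
}

# Subset/reorder embedding rows to questionnaire item order; E may cover a
# superset of the items (e.g. full-instrument embeddings in a LOIO fold).
align_embeddings <- function(E, questionnaire) {
  ids <- item_ids(questionnaire)
  missing <- setdiff(ids, rownames(E))
  if (length(missing)) {
    abort(sprintf("Embeddings lack item(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "psychollm_validation_error")
  }
  embedding_matrix(unclass(E)[ids, , drop = FALSE], ids,
                   provider_tag = attr(E, "provider_tag"))
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("<alignment_report> %s (n = %d respondents, p = %d items)\n",
              x$questionnaire_name, x$n_respondents, nrow(x$S)))
  acc <- paste(sprintf("Top-%d %.1f%%", x$top_k$k, 100 * x$top_k$accuracy),
               collapse = ", ")
  cat(" ", acc, "\n")
  for (i in seq_len(nrow(x$matrix_cor))) {
    cat(sprintf("  %s r = %.3f (p = %.3g)\n",
                x$matrix_cor$method[i], x$matrix_cor$estimate[i],
                x$matrix_cor$p.value[i]))
  }
  if (!is.null(x$per_factor)) {
    m <- x$per_factor |> group_by(.data$method) |>
      summarise(mean = mean(.data$estimate))
    cat(sprintf("  per-factor mean: %s\n",
                paste(sprintf("%s %.3f", m$method, m$mean), collapse = ", ")))
  }
  invisible(x)
}
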