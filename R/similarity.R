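#' Cosine similarity matrix between item embeddings
#'
#' `S[i, j] = (e_i . e_j) / (||e_i|| ||e_j||)`. The result is symmetric with
#' a unit diagonal; round-off is clamped into `[-1, 1]`.
#'
#' @param E an [embedding_matrix()] (or plain matrix with row names).
#' @return A `similarity_matrix`: p x p numeric matrix, item ids as dimnames.
#' @export
cosine_similarity_matrix <- function(E) {
  E <- as.matrix(E)
  ids <- rownames(E) %||% sprintf("item%02d", seq_len(nrow(E)))
  nrm <- sqrt(rowSums(E^2))
  if (any(nrm == 0)) {
    abort(sprintf("Zero-norm embedding for item(s): %s.",
                  paste(ids[nrm == 0], collapse = ", ")),
          class = "psychollm_validation_error")
  }
  N <- E / nrm
  S <- tcrossprod(N)
  S <- (S + t(S)) / 2
  S <- clamp(S, -1, 1)
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  structure(S, class = c("similarity_matrix", "matrix", "array"))
}

#' Inter-item correlation matrix of observed scores
#'
#' Pairwise item-item correlation across respondents, complete cases only
#' (respondents missing any analysed item are dropped). By default entries
#' are absolute-valued: reverse-keyed items make large negative correlations
#' as informative as positive ones, so alignment with semantic similarity is
#' assessed on magnitudes.
#'
#' @param responses response tibble (see [read_responses()]).
#' @param questionnaire a [questionnaire()]; when `NULL` all non-id numeric
#'   columns are used.
#' @param method `"pearson"` (raw Likert codes) or `"spearman"`.
#' @param absolute take absolute values of the off-diagonal entries.
#' @return A `correlation_matrix` with an `absolute` attribute.
#' @export
score_correlation_matrix <- function(responses, questionnaire = NULL,
                                     method = c("pearson", "spearman"),
                                     absolute = TRUE) {
  method <- match.arg(method)
  X <- if (is.null(questionnaire)) {
    cols <- setdiff(names(responses), "respondent_id")
    M <- as.matrix(as.data.frame(responses[cols]))
    storage.mode(M) <- "double"
    M[complete.cases(M), , drop = FALSE]
  } else {
    response_scores(responses, questionnaire)
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    abort(sprintf("Zero-variance item column(s): %s.",
                  paste(colnames(X)[sds == 0 | is.na(sds)], collapse = ", ")),
          class = "psychollm_validation_error")
  }
  C <- cor(X, method = method)
  if (absolute) C <- abs(C)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  structure(C, absolute = absolute, method = method,
            class = c("correlation_matrix", "matrix", "array"))
}

#' K most semantically similar items to a given item
#'
#' Returns the `k` other items with the largest similarity to `item`,
#' descending; ties are broken by ascending item index so results are
#' deterministic across platforms.
#'
#' @param S a [cosine_similarity_matrix()].
#' @param item item id (or index).
#' @param k number of neighbors, `1 <= k <= p - 1`.
#' @return A tibble with columns `item_id`, `similarity`, ordered.
#' @export
top_k_neighbors <- function(S, item, k) {
  p <- nrow(S)
  if (k < 1 || k > p - 1) {
    abort(sprintf("k must be in [1, %d].", p - 1),
          class = "psychollm_validation_error")
  }
  idx <- if (is.character(item)) match(item, rownames(S)) else as.integer(item)
  if (is.na(idx) || idx < 1 || idx > p) {
    abort(sprintf("Unknown item: %s", as.character(item)),
          class = "psychollm_validation_error")
  }
  sims <- S[idx, ]
  others <- setdiff(seq_len(p), idx)
  ord <- others[order(-sims[others], others)]
  sel <- ord[seq_len(k)]
  tibble(item_id = rownames(S)[sel], similarity = unname(sims[sel]))
}

# Internal: neighbor index matrix for all items at once (ties by index).
neighbor_index_matrix <- function(S, k) {
  p <- nrow(S)
  res <- vapply(seq_len(p), function(j) {
    others <- setdiff(seq_len(p), j)
    ord <- others[order(-S[j, others], others)]
    ord[seq_len(k)]
  }, integer(k))
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}
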