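# Shared fixtures and independent oracles, all built in code.

toy_questionnaire <- function(p = 4, scale_min = 1, scale_max = 4,
                              factors = NULL) {
  questionnaire(
    tibble::tibble(
      item_id = sprintf("Q%d", seq_len(p)),
      text = sprintf("toy statement number %d", seq_len(p)),
      factor = factors %||% rep(NA_character_, p)),
    name = "toy", scale_min = scale_min, scale_max = scale_max)
}

# random similarity matrix from random embeddings (valid by construction)
random_similarity <- function(p, d = 6, seed = 1) {
  E <- withr::with_seed(seed, matrix(rnorm(p * d), p, d))
  rownames(E) <- sprintf("Q%d", seq_len(p))
  cosine_similarity_matrix(E)
}

# random absolute correlation matrix from simulated scores
random_correlation <- function(p, n = 40, seed = 2, absolute = TRUE) {
  X <- withr::with_seed(seed, matrix(rnorm(n * p), n, p))
  colnames(X) <- sprintf("Q%d", seq_len(p))
  resp <- tibble::as_tibble(as.data.frame(X))
  resp$respondent_id <- sprintf("R%d", seq_len(n))
  score_correlation_matrix(resp, absolute = absolute)
}

# Independent plain-loop oracle for Top-K accuracy.
oracle_top_k_accuracy <- function(S, C, k) {
  p <- nrow(S)
  hits <- 0
  for (j in seq_len(p)) {
    best_cor <- -Inf
    best_idx <- NA
    for (i in seq_len(p)) {
      if (i != j && C[j, i] > best_cor) {
        best_cor <- C[j, i]
        best_idx <- i
      }
    }
    sims <- S[j, ]
    sims[j] <- -Inf
    ord <- order(-sims, seq_len(p))
    if (best_idx %in% ord[seq_len(k)]) hits <- hits + 1
  }
  hits / p
}

# Independent oracle for the triangle correlation and its t-test p-value.
oracle_matrix_correlation <- function(S, C, method) {
  x <- c()
  y <- c()
  p <- nrow(S)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      x <- c(x, S[i, j])
      y <- c(y, C[i, j])
    }
  }
  r <- cor(x, y, method = method)
  m <- length(x)
  tt <- r * sqrt((m - 2) / (1 - r^2))
  list(estimate = r, p.value = 2 * stats::pt(-abs(tt), df = m - 2))
}

# responses tibble from a plain matrix
as_responses <- function(X, ids = colnames(X)) {
  colnames(X) <- ids
  out <- tibble::as_tibble(as.data.frame(X))
  dplyr::bind_cols(
    tibble::tibble(respondent_id = sprintf("R%04d", seq_len(nrow(X)))),
    out)
}

upper_tri_vec <- function(M) {
  M <- unclass(M)
  M[upper.tri(M)]
}
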