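#' Configuration for the synthetic questionnaire simulator
#'
#' The simulator produces item embeddings with a known factor geometry and
#' Likert responses whose population correlation structure is an exact,
#' known function of the embedding cosine similarities: with unit-norm item
#' vectors `e_j`, latent respondent vectors `z_i` of iid standard normals
#' and noise level `sigma`, the continuous score `y_ij = e_j . z_i +
#' sigma * eps_ij` has `Corr(y_j, y_k) = S[j, k] / (1 + sigma^2)` exactly.
#' Every structural claim the package makes is therefore testable without
#' real data.
#'
#' @param n_factors number of latent factors.
#' @param items_per_factor items per factor (`p = n_factors *
#'   items_per_factor`).
#' @param embedding_dim embedding dimension (at least `n_factors`, plus one
#'   when `axis_cosine > 0`).
#' @param n_respondents simulated sample size.
#' @param within_factor_tightness in `[0, 1]`: angular concentration of item
#'   vectors around their factor axis (1 = items duplicate the axis).
#' @param axis_cosine in `[0, 1)`: pairwise cosine between factor axes
#'   (0 = orthogonal constructs; high values emulate strongly
#'   inter-correlated subscales such as depression/anxiety/stress).
#' @param noise_sigma non-negative response noise standard deviation.
#' @param scale_min,scale_max Likert bounds for discretized output.
#' @param thresholds optional increasing cut points for discretization;
#'   `NULL` uses equal-probability bins of the marginal normal so every
#'   category stays populated.
#' @param seed integer; all randomness flows from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_factors = 3L, items_per_factor = 5L,
                             embedding_dim = 16L, n_respondents = 1000L,
                             within_factor_tightness = 0.8,
                             axis_cosine = 0,
                             noise_sigma = 0.3,
                             scale_min = 1L, scale_max = 4L,
                             thresholds = NULL, seed = 1L) {
  stopifnot(n_factors >= 1, items_per_factor >= 1, n_respondents >= 2,
            within_factor_tightness >= 0, within_factor_tightness <= 1,
            axis_cosine >= 0, axis_cosine < 1,
            noise_sigma >= 0, scale_min < scale_max)
  need <- n_factors + as.integer(axis_cosine > 0)
  if (embedding_dim < need) {
    abort(sprintf("embedding_dim must be at least %d for this config.", need),
          class = "psychollm_validation_error")
  }
  structure(list(n_factors = as.integer(n_factors),
                 items_per_factor = as.integer(items_per_factor),
                 embedding_dim = as.integer(embedding_dim),
                 n_respondents = as.integer(n_respondents),
                 within_factor_tightness = within_factor_tightness,
                 axis_cosine = axis_cosine,
                 noise_sigma = noise_sigma,
                 scale_min = as.integer(scale_min),
                 scale_max = as.integer(scale_max),
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate factor-structured item embeddings
#'
#' Builds `n_factors` unit factor axes (orthonormal, or mutually oblique at
#' `axis_cosine`) and places each item at
#' `normalize(t * axis + (1 - t) * u)` with `t` the within-factor tightness
#' and `u` a random unit direction. Returns the embeddings together with a
#' questionnaire carrying the ground-truth factor labels.
#'
#' @param cfg a [synthetic_config()].
#' @return A list: `embeddings` ([embedding_matrix()]), `questionnaire`
#'   ([questionnaire()] with factor labels `G1..Gm`).
#' @export
generate_embeddings <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  p <- cfg$n_factors * cfg$items_per_factor
  d <- cfg$embedding_dim
  t_ <- cfg$within_factor_tightness
  withr::with_seed(cfg$seed, {
    axes <- factor_axes(cfg$n_factors, d, cfg$axis_cosine)
    vecs <- matrix(0, p, d)
    for (j in seq_len(p)) {
      f <- ((j - 1) %/% cfg$items_per_factor) + 1
      u <- rnorm(d)
      u <- u / sqrt(sum(u^2))
      v <- t_ * axes[f, ] + (1 - t_) * u
      vecs[j, ] <- v / sqrt(sum(v^2))
    }
  })
  ids <- sprintf("S%02d", seq_len(p))
  fac <- sprintf("G%d", ((seq_len(p) - 1) %/% cfg$items_per_factor) + 1)
  q <- questionnaire(
    tibble(item_id = ids,
           text = sprintf("synthetic item %02d (factor %s)", seq_len(p), fac),
           factor = fac),
    name = "synthetic", scale_min = cfg$scale_min, scale_max = cfg$scale_max)
  list(embeddings = embedding_matrix(vecs, ids, provider_tag = "synthetic"),
       questionnaire = q)
}

factor_axes <- function(m, d, axis_cosine) {
  Q <- qr.Q(qr(matrix(rnorm(d * (m + 1)), d, m + 1)))
  if (axis_cosine <= 0) return(t(Q[, seq_len(m), drop = FALSE]))
  shared <- Q[, m + 1]
  t(vapply(seq_len(m), function(f) {
    sqrt(axis_cosine) * shared + sqrt(1 - axis_cosine) * Q[, f]
  }, numeric(d)))
}

#' Simulate Likert (or continuous) responses from embeddings
#'
#' Respondent `i` draws a latent vector `z_i` of iid standard normals; the
#' continuous score is `y_ij = e_j . z_i + sigma * eps_ij`, so the
#' population correlation between any two items equals their cosine
#' similarity shrunk by `1 / (1 + sigma^2)`. With `continuous = FALSE` the
#' scores are discretized by fixed monotone thresholds (equal-probability
#' bins of the marginal by default) into the configured Likert range.
#'
#' @param E an [embedding_matrix()] with unit-norm rows.
#' @param cfg a [synthetic_config()].
#' @param continuous return raw continuous scores instead of Likert codes.
#' @return A tibble: `respondent_id` plus one column per item (integer codes,
#'   or doubles when `continuous`).
#' @export
generate_responses <- function(E, cfg, continuous = FALSE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  Em <- unclass(E)
  nrm <- sqrt(rowSums(Em^2))
  if (max(abs(nrm - 1)) > 1e-8) {
    abort("generate_responses needs unit-norm embedding rows.",
          class = "psychollm_validation_error")
  }
  n <- cfg$n_respondents
  d <- ncol(Em)
  sigma <- cfg$noise_sigma
  Y <- withr::with_seed(cfg$seed + 1L, {
    Z <- matrix(rnorm(n * d), n, d)
    Z %*% t(Em) + sigma * matrix(rnorm(n * nrow(Em)), n, nrow(Em))
  })
  colnames(Y) <- rownames(Em)
  out <- dplyr::bind_cols(
    tibble(respondent_id = sprintf("R%05d", seq_len(n))),
    as_tibble(as.data.frame(Y)))
  if (continuous) return(out)
  discretize_responses(out, cfg, marginal_sd = sqrt(1 + sigma^2))
}

discretize_responses <- function(responses, cfg, marginal_sd = 1) {
  levels <- cfg$scale_max - cfg$scale_min + 1L
  th <- cfg$thresholds %||%
    qnorm(seq_len(levels - 1L) / levels, mean = 0, sd = marginal_sd)
  if (is.unsorted(th, strictly = TRUE)) {
    abort("Discretization thresholds must be strictly increasing.",
          class = "psychollm_validation_error")
  }
  cols <- setdiff(names(responses), "respondent_id")
  for (cl in cols) {
    responses[[cl]] <- cfg$scale_min +
      as.integer(findInterval(responses[[cl]], th))
  }
  responses
}

#' Anchor-layout embeddings for planted-weights experiments
#'
#' A deliberately identifiable geometry: `n_anchors` mutually similar
#' "anchor" items (pairwise cosine 0.75), and all remaining items placed at
#' one fixed convex position over the first three anchors (cosines ~0.69 /
#' 0.66 / 0.65) plus an item-unique orthogonal component. By construction
#' every non-anchor item's three nearest neighbors are anchors 1-3 (in that
#' order) and every anchor's nearest neighbors are the other anchors, with
#' similarity gaps of at least 0.02 — so neighbor sets are stable and a
#' planted convex combination over the anchors is exactly recoverable.
#'
#' @param n_items total items (> `n_anchors`).
#' @param n_anchors number of anchor items (default 4).
#' @param embedding_dim at least `n_anchors + 1 + (n_items - n_anchors)`.
#' @param scale_min,scale_max Likert bounds carried by the questionnaire.
#' @param seed integer seed (orientation of the basis only; similarities
#'   are deterministic by construction).
#' @return A list: `embeddings`, `questionnaire` (anchors labelled factor
#'   `"anchor"`, the rest `"derived"`).
#' @export
generate_anchor_embeddings <- function(n_items = 42L, n_anchors = 4L,
                                       embedding_dim = 64L,
                                       scale_min = 1L, scale_max = 4L,
                                       seed = 1L) {
  stopifnot(n_anchors >= 4, n_items > n_anchors)
  n_derived <- n_items - n_anchors
  need <- n_anchors + 1L + n_derived
  if (embedding_dim < need) {
    abort(sprintf("embedding_dim must be at least %d.", need),
          class = "psychollm_validation_error")
  }
  rho <- 0.75                       # anchor-anchor cosine
  alpha <- 0.45                     # pull of derived items toward anchors
  cvec <- c(0.7, 0.5, 0.4, 0.2)     # convex position over anchors 1..4
  basis <- withr::with_seed(as.integer(seed),
    qr.Q(qr(matrix(rnorm(embedding_dim * need), embedding_dim, need))))
  shared <- basis[, 1]
  anchors <- t(vapply(seq_len(n_anchors), function(a) {
    sqrt(rho) * shared + sqrt(1 - rho) * basis[, 1 + a]
  }, numeric(embedding_dim)))
  centroid <- alpha * drop(cvec %*% anchors)
  beta <- sqrt(1 - sum(centroid^2))
  derived <- t(vapply(seq_len(n_derived), function(j) {
    centroid + beta * basis[, 1 + n_anchors + j]
  }, numeric(embedding_dim)))
  vecs <- rbind(anchors, derived)
  ids <- c(sprintf("A%02d", seq_len(n_anchors)),
           sprintf("D%02d", seq_len(n_derived)))
  fac <- c(rep("anchor", n_anchors), rep("derived", n_derived))
  q <- questionnaire(
    tibble(item_id = ids,
           text = sprintf("synthetic %s item %s", fac, ids),
           factor = fac),
    name = "anchor-layout", scale_min = scale_min, scale_max = scale_max)
  list(embeddings = embedding_matrix(vecs, ids, provider_tag = "synthetic"),
       questionnaire = q)
}

#' Responses with planted neighbor weights
#'
#' An oracle for the predictor: scores are built from an initial independent
#' draw followed by one smoothing pass in which each *non-source* item's
#' column is replaced by the planted convex combination of its k nearest
#' neighbors' columns plus noise. Items that appear in any other item's
#' neighbor list ("sources") keep their initial draw, so the planted
#' relation holds exactly in the returned matrix — with arbitrary
#' embeddings most items are someone's neighbor and little gets smoothed;
#' pair this generator with [generate_anchor_embeddings()], whose layout
#' makes all non-anchor items smoothable.
#'
#' @param E an [embedding_matrix()] with unit-norm rows.
#' @param cfg a [synthetic_config()] (uses `n_respondents`, `noise_sigma`,
#'   scale bounds, `seed`).
#' @param weights non-negative k-vector summing to 1: the planted neighbor
#'   weights, in descending-similarity neighbor order.
#' @param continuous return continuous scores instead of Likert codes.
#' @return A response tibble with attributes `planted_weights`,
#'   `smoothed_items` (ids whose columns carry the planted relation) and
#'   `neighbor_table` (tibble item, rank, neighbor).
#' @export
generate_planted_weights_data <- function(E, cfg, weights = c(0.7, 0.2, 0.1),
                                          continuous = FALSE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    abort("`weights` must be a non-negative vector summing to 1.",
          class = "psychollm_validation_error")
  }
  k <- length(weights)
  Em <- unclass(E)
  if (max(abs(sqrt(rowSums(Em^2)) - 1)) > 1e-8) {
    abort("generate_planted_weights_data needs unit-norm embedding rows.",
          class = "psychollm_validation_error")
  }
  p <- nrow(Em)
  ids <- rownames(Em)
  S <- cosine_similarity_matrix(E)
  nbrs <- neighbor_index_matrix(S, k)
  sources <- sort(unique(as.vector(nbrs)))
  smoothed <- setdiff(seq_len(p), sources)
  n <- cfg$n_respondents
  sigma <- cfg$noise_sigma
  Y <- withr::with_seed(cfg$seed + 2L, {
    Y0 <- matrix(rnorm(n * p), n, p)
    Y1 <- Y0
    for (j in smoothed) {
      Y1[, j] <- Y0[, nbrs[j, ], drop = FALSE] %*% weights +
        sigma * rnorm(n)
    }
    Y1
  })
  colnames(Y) <- ids
  out <- dplyr::bind_cols(
    tibble(respondent_id = sprintf("R%05d", seq_len(n))),
    as_tibble(as.data.frame(Y)))
  if (!continuous) {
    out <- discretize_responses(out, cfg, marginal_sd = 1)
  }
  attr(out, "planted_weights") <- weights
  attr(out, "smoothed_items") <- ids[smoothed]
  attr(out, "neighbor_table") <- tibble(
    item_id = rep(ids, each = k),
    rank = rep(seq_len(k), p),
    neighbor_id = ids[as.vector(t(nbrs))])
  out
}

#' Paired questionnaires sharing latent factors
#'
#' Emulates two related instruments (e.g. an anxiety and a depression scale)
#' answered by the same respondents on the same Likert range: both item sets
#' load on one shared set of factor axes, and one shared latent sample
#' generates both response matrices. With `duplicate_items = TRUE` the test
#' instrument's item vectors duplicate the training instrument's (ids stay
#' disjoint), the degenerate case in which cross-instrument prediction
#' should be near-perfect.
#'
#' @param cfg a [synthetic_config()]; `items_per_factor` applies to each
#'   instrument separately.
#' @param duplicate_items copy the training item vectors into the test
#'   instrument.
#' @return A list with elements `train` and `test`, each a list
#'   `questionnaire`, `embeddings`, `responses`; respondent ids are shared.
#' @export
generate_paired_questionnaires <- function(cfg, duplicate_items = FALSE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  p <- cfg$n_factors * cfg$items_per_factor
  d <- cfg$embedding_dim
  t_ <- cfg$within_factor_tightness
  sigma <- cfg$noise_sigma
  n <- cfg$n_respondents

  withr::with_seed(cfg$seed, {
    axes <- factor_axes(cfg$n_factors, d, cfg$axis_cosine)
    make_vecs <- function() {
      vecs <- matrix(0, p, d)
      for (j in seq_len(p)) {
        f <- ((j - 1) %/% cfg$items_per_factor) + 1
        u <- rnorm(d)
        u <- u / sqrt(sum(u^2))
        v <- t_ * axes[f, ] + (1 - t_) * u
        vecs[j, ] <- v / sqrt(sum(v^2))
      }
      vecs
    }
    vec_a <- make_vecs()
    vec_b <- if (duplicate_items) vec_a else make_vecs()
    Z <- matrix(rnorm(n * d), n, d)
    Ya <- Z %*% t(vec_a) + sigma * matrix(rnorm(n * p), n, p)
    Yb <- Z %*% t(vec_b) + sigma * matrix(rnorm(n * p), n, p)
  })

  fac <- sprintf("G%d", ((seq_len(p) - 1) %/% cfg$items_per_factor) + 1)
  mk <- function(prefix, vecs, Y) {
    ids <- sprintf("%s%02d", prefix, seq_len(p))
    q <- questionnaire(
      tibble(item_id = ids,
             text = sprintf("instrument %s item %02d (factor %s)",
                            prefix, seq_len(p), fac),
             factor = fac),
      name = paste0("synthetic-", prefix),
      scale_min = cfg$scale_min, scale_max = cfg$scale_max)
    colnames(Y) <- ids
    resp <- dplyr::bind_cols(
      tibble(respondent_id = sprintf("R%05d", seq_len(n))),
      as_tibble(as.data.frame(Y)))
    resp <- discretize_responses(resp, cfg, marginal_sd = sqrt(1 + sigma^2))
    list(questionnaire = q,
         embeddings = embedding_matrix(vecs, ids, provider_tag = "synthetic"),
         responses = resp)
  }
  list(train = mk("A", vec_a, Ya), test = mk("B", vec_b, Yb))
}
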