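#' Configuration for the PsychoLLM predictor
#'
#' PsychoLLM predicts a respondent's score on a target item as a weighted
#' sum of that respondent's scores on the target's `n_neighbors` most
#' semantically similar training items. The weights are produced by a small
#' network — two fully connected layers mapping the target's neighbor
#' similarity profile to softmax-normalized weights — trained
#' self-supervised: every training item in turn plays the target, and the
#' network minimizes mean squared error over all (respondent, item) pairs.
#'
#' @param n_neighbors neighbors per target item (default 3: the most
#'   correlated item typically sits within the top three semantic
#'   neighbors).
#' @param hidden_units width of the hidden layer.
#' @param activation `"relu"` or `"tanh"`.
#' @param epochs full-batch training epochs.
#' @param batch_size reserved; `NULL` means full batch (the default and the
#'   only mode currently implemented — the whole design matrix is tiny).
#' @param learning_rate Adam step size.
#' @param seed integer seed; training is deterministic given it.
#' @param clip_to_scale clamp predictions into the Likert bounds.
#' @param round_predictions round predictions half-away-from-zero to integer
#'   codes (needed for exact-match scoring).
#' @return A `psychollm_config` list.
#' @export
psychollm_config <- function(n_neighbors = 3L, hidden_units = 16L,
                             activation = c("relu", "tanh"),
                             epochs = 500L, batch_size = NULL,
                             learning_rate = 0.02, seed = 1L,
                             clip_to_scale = TRUE, round_predictions = TRUE) {
  activation <- match.arg(activation)
  stopifnot(n_neighbors >= 1, hidden_units >= 1, epochs >= 1,
            learning_rate > 0)
  structure(list(n_neighbors = as.integer(n_neighbors),
                 hidden_units = as.integer(hidden_units),
                 activation = activation, epochs = as.integer(epochs),
                 batch_size = batch_size,
                 learning_rate = learning_rate, seed = as.integer(seed),
                 clip_to_scale = isTRUE(clip_to_scale),
                 round_predictions = isTRUE(round_predictions)),
            class = "psychollm_config")
}

# forward pass: similarity features (q x k) -> softmax weights (q x k)
nn_forward <- function(params, F_, activation) {
  A <- sweep(F_ %*% t(params$W1), 2, params$b1, `+`)
  H <- if (activation == "relu") pmax(A, 0) else tanh(A)
  G <- sweep(H %*% t(params$W2), 2, params$b2, `+`)
  Gs <- G - apply(G, 1, max)
  Wgt <- exp(Gs)
  Wgt <- Wgt / rowSums(Wgt)
  list(A = A, H = H, W = Wgt)
}

#' Fit the PsychoLLM neighbor-weighting model
#'
#' Self-supervised training: for every training item `j`, the model predicts
#' each respondent's score on `j` from that respondent's scores on `j`'s
#' `n_neighbors` most similar *other* training items, with weights given by
#' the network applied to `j`'s neighbor-similarity profile. The held-out
#' target of a later prediction is never part of this — only training item
#' columns are read.
#'
#' @param responses response tibble covering the training items (extra
#'   columns are ignored; incomplete respondents are dropped).
#' @param questionnaire the training [questionnaire()] (subset allowed).
#' @param embeddings an [embedding_matrix()] covering the training items.
#' @param config a [psychollm_config()].
#' @return A `psychollm` model: network parameters, neighbor tables, the
#'   training scores it conditions on, and a per-epoch `training_log`.
#' @export
fit_psychollm <- function(responses, questionnaire, embeddings,
                          config = psychollm_config()) {
  k <- config$n_neighbors
  ids <- item_ids(questionnaire)
  p <- length(ids)
  if (p < k + 1) {
    abort(sprintf("Need at least n_neighbors + 1 = %d training items, got %d.",
                  k + 1, p),
          class = "psychollm_validation_error")
  }
  E <- align_embeddings(embeddings, questionnaire)
  X <- response_scores(responses, questionnaire)
  n <- nrow(X)
  S <- cosine_similarity_matrix(E)
  nbrs <- neighbor_index_matrix(S, k)
  F_ <- matrix(S[cbind(rep(seq_len(p), k), as.vector(nbrs))], p, k)

  # sufficient statistics: the loss and its weight-gradient only need the
  # neighbor Gram blocks, not the raw n x p matrix, so epochs cost O(p k^2)
  Marr <- array(0, c(p, k, k))
  Cmat <- matrix(0, p, k)
  yty <- numeric(p)
  for (j in seq_len(p)) {
    Yn <- X[, nbrs[j, ], drop = FALSE]
    Marr[j, , ] <- crossprod(Yn)
    Cmat[j, ] <- crossprod(Yn, X[, j])
    yty[j] <- sum(X[, j]^2)
  }

  h <- config$hidden_units
  params <- withr::with_seed(config$seed, list(
    W1 = matrix(rnorm(h * k, sd = 0.3), h, k),
    b1 = numeric(h),
    # zero output layer => initial weights exactly uniform (= neighbor mean)
    W2 = matrix(0, k, h),
    b2 = numeric(k)))

  adam <- lapply(params, function(p_) list(m = p_ * 0, v = p_ * 0))
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  scale <- 2 / (n * p)
  log_loss <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    fw <- nn_forward(params, F_, config$activation)
    Wgt <- fw$W
    Mw <- matrix(0, p, k)
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        Mw[, a] <- Mw[, a] + Marr[, a, b] * Wgt[, b]
      }
    }
    loss <- sum(rowSums(Wgt * Mw) - 2 * rowSums(Wgt * Cmat) + yty) / (n * p)
    if (!is.finite(loss)) {
      abort(sprintf("Non-finite training loss at epoch %d (lr = %g).",
                    epoch, lr),
            class = "psychollm_numeric_error")
    }
    log_loss[epoch] <- loss

    gW <- scale * (Mw - Cmat)                      # dL/d(weights)
    gG <- Wgt * (gW - rowSums(gW * Wgt))           # through softmax
    gH <- gG %*% params$W2
    gA <- if (config$activation == "relu") {
      gH * (fw$A > 0)
    } else {
      gH * (1 - fw$H^2)
    }
    grads <- list(W1 = t(gA) %*% F_, b1 = colSums(gA),
                  W2 = t(gG) %*% fw$H, b2 = colSums(gG))
    for (nm in names(params)) {
      adam[[nm]]$m <- beta1 * adam[[nm]]$m + (1 - beta1) * grads[[nm]]
      adam[[nm]]$v <- beta2 * adam[[nm]]$v + (1 - beta2) * grads[[nm]]^2
      mhat <- adam[[nm]]$m / (1 - beta1^epoch)
      vhat <- adam[[nm]]$v / (1 - beta2^epoch)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }

  structure(
    list(config = config,
         params = params,
         train_item_ids = ids,
         train_scores = X,
         train_embeddings = E,
         neighbor_index = nbrs,
         features = F_,
         scale_min = scale_bounds(questionnaire)[1],
         scale_max = scale_bounds(questionnaire)[2],
         training_log = tibble(epoch = seq_len(config$epochs),
                               loss = log_loss)),
    class = "psychollm")
}

#' @export
print.psychollm <- function(x, ...) {
  cat(sprintf(
    "<psychollm> %d training items, %d respondents, k = %d neighbors\n",
    length(x$train_item_ids), nrow(x$train_scores), x$config$n_neighbors))
  cat(sprintf("  training MSE: %.4f (epoch 1) -> %.4f (epoch %d)\n",
              x$training_log$loss[1],
              x$training_log$loss[nrow(x$training_log)],
              nrow(x$training_log)))
  invisible(x)
}

#' Predict scores for unseen items
#'
#' For each target item: find its `n_neighbors` most similar training items
#' by cosine similarity, run the trained network on the similarity profile
#' to get softmax weights, and output each respondent's weighted neighbor
#' score sum. Target items must not be training items (leakage guard); the
#' target's own observed scores are never read.
#'
#' @param object a fitted [fit_psychollm()] model.
#' @param questionnaire target items: a [questionnaire()] or tibble with
#'   `item_id`, `text`.
#' @param embeddings an [embedding_matrix()] covering the target items.
#' @param responses tibble of the respondents' scores on the *training*
#'   items (defaults to the scores the model was fitted on).
#' @param round round predictions half-away-from-zero to integer codes.
#' @param clip clamp into the training Likert bounds.
#' @param ... unused.
#' @return A tibble: `respondent_id` plus one column per target item, with
#'   a `weights` attribute (tibble: target item, neighbor, similarity,
#'   weight).
#' @export
predict.psychollm <- function(object, questionnaire, embeddings,
                              responses = NULL,
                              round = object$config$round_predictions,
                              clip = object$config$clip_to_scale, ...) {
  target_ids <- if (inherits(questionnaire, "questionnaire")) {
    item_ids(questionnaire)
  } else {
    as.character(as_tibble(questionnaire)$item_id)
  }
  leak <- intersect(target_ids, object$train_item_ids)
  if (length(leak)) {
    abort(sprintf("Target item(s) present in the training set: %s.",
                  paste(leak, collapse = ", ")),
          class = "psychollm_leakage_error")
  }
  Et <- unclass(embeddings)[target_ids, , drop = FALSE]
  X <- if (is.null(responses)) {
    object$train_scores
  } else {
    ids <- object$train_item_ids
    missing_cols <- setdiff(ids, names(responses))
    if (length(missing_cols)) {
      abort(sprintf("Responses lack training item column(s): %s.",
                    paste(missing_cols, collapse = ", ")),
            class = "psychollm_schema_error")
    }
    M <- as.matrix(as.data.frame(responses[ids]))
    storage.mode(M) <- "double"
    rownames(M) <- if ("respondent_id" %in% names(responses)) {
      as.character(responses$respondent_id)
    } else {
      sprintf("R%05d", seq_len(nrow(M)))
    }
    M
  }

  k <- object$config$n_neighbors
  Etr <- unclass(object$train_embeddings)
  Nt <- Et / sqrt(rowSums(Et^2))
  Ntr <- Etr / sqrt(rowSums(Etr^2))
  Sx <- clamp(tcrossprod(Nt, Ntr), -1, 1)  # targets x train items

  q <- length(target_ids)
  nbrs <- matrix(0L, q, k)
  F_ <- matrix(0, q, k)
  for (t_ in seq_len(q)) {
    ord <- order(-Sx[t_, ], seq_len(ncol(Sx)))
    nbrs[t_, ] <- ord[seq_len(k)]
    F_[t_, ] <- Sx[t_, nbrs[t_, ]]
  }
  Wgt <- nn_forward(object$params, F_, object$config$activation)$W

  preds <- matrix(0, nrow(X), q)
  for (t_ in seq_len(q)) {
    preds[, t_] <- X[, nbrs[t_, ], drop = FALSE] %*% Wgt[t_, ]
  }
  if (clip) preds <- clamp(preds, object$scale_min, object$scale_max)
  if (round) {
    preds <- round_half_away(preds)
    if (clip) preds <- clamp(preds, object$scale_min, object$scale_max)
  }
  colnames(preds) <- target_ids
  out <- as_tibble(as.data.frame(preds))
  out <- dplyr::bind_cols(tibble(respondent_id = rownames(X)), out)
  attr(out, "weights") <- tibble(
    item_id = rep(target_ids, each = k),
    rank = rep(seq_len(k), q),
    neighbor_id = object$train_item_ids[as.vector(t(nbrs))],
    similarity = as.vector(t(F_)),
    weight = as.vector(t(Wgt)))
  out
}

#' Learned neighbor weights
#'
#' The softmax weights the trained network assigns to each item's semantic
#' neighbors — for the training items themselves (default) or for new items
#' given their embeddings.
#'
#' @param model a fitted [fit_psychollm()] model.
#' @param questionnaire,embeddings optional new items and their embeddings.
#' @return A tibble: `item_id`, `rank`, `neighbor_id`, `similarity`,
#'   `weight`.
#' @export
neighbor_weights <- function(model, questionnaire = NULL, embeddings = NULL) {
  if (!is.null(questionnaire)) {
    pr <- predict(model, questionnaire, embeddings,
                  responses = model_responses_stub(model))
    return(attr(pr, "weights"))
  }
  k <- model$config$n_neighbors
  Wgt <- nn_forward(model$params, model$features, model$config$activation)$W
  p <- length(model$train_item_ids)
  tibble(
    item_id = rep(model$train_item_ids, each = k),
    rank = rep(seq_len(k), p),
    neighbor_id = model$train_item_ids[as.vector(t(model$neighbor_index))],
    similarity = as.vector(t(model$features)),
    weight = as.vector(t(Wgt)))
}

model_responses_stub <- function(model) {
  df <- as.data.frame(model$train_scores[1, , drop = FALSE])
  dplyr::bind_cols(tibble(respondent_id = "stub"), as_tibble(df))
}

#' Save / load a fitted PsychoLLM model
#'
#' One self-contained JSON archive: configuration, network parameters, the
#' training item index, embeddings and the training scores the model
#' conditions on (a trained model cannot predict without them). Numeric
#' values are written at full double precision; a reloaded model reproduces
#' predictions to within ~1e-15 relative error (JSON text round-trip).
#'
#' @param model a fitted [fit_psychollm()] model.
#' @param path archive path (conventionally `.json`).
#' @return `save_psychollm()` returns `path` invisibly; `load_psychollm()`
#'   the reconstructed `psychollm` model.
#' @export
save_psychollm <- function(model, path) {
  arch <- list(
    format = "psychollm-model",
    version = as.character(packageVersion("psychollm")),
    config = unclass(model$config),
    params = lapply(model$params, function(p_) {
      if (is.matrix(p_)) {
        list(dim = dim(p_), values = as.vector(p_))
      } else {
        list(dim = NULL, values = as.vector(p_))
      }
    }),
    train_item_ids = model$train_item_ids,
    respondent_ids = rownames(model$train_scores),
    train_scores = as.vector(model$train_scores),
    embeddings = list(values = as.vector(unclass(model$train_embeddings)),
                      d = ncol(model$train_embeddings),
                      provider_tag = attr(model$train_embeddings,
                                          "provider_tag")),
    neighbor_index = as.vector(model$neighbor_index),
    features = as.vector(model$features),
    scale_min = model$scale_min, scale_max = model$scale_max,
    training_log = model$training_log)
  jsonlite::write_json(arch, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname save_psychollm
#' @export
load_psychollm <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("No such file: %s", path), class = "psychollm_io_error")
  }
  arch <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(arch$format, "psychollm-model")) {
    abort("Not a psychollm model archive.", class = "psychollm_io_error")
  }
  cfg <- do.call(psychollm_config, as.list(arch$config))
  params <- lapply(arch$params, function(p_) {
    if (length(p_$dim) == 2) {
      matrix(p_$values, p_$dim[1], p_$dim[2])
    } else {
      as.numeric(p_$values)
    }
  })
  p <- length(arch$train_item_ids)
  k <- cfg$n_neighbors
  X <- matrix(arch$train_scores, ncol = p,
              dimnames = list(arch$respondent_ids, arch$train_item_ids))
  E <- embedding_matrix(matrix(arch$embeddings$values, nrow = p,
                               ncol = arch$embeddings$d),
                        arch$train_item_ids,
                        provider_tag = arch$embeddings$provider_tag)
  structure(
    list(config = cfg, params = params,
         train_item_ids = arch$train_item_ids,
         train_scores = X, train_embeddings = E,
         neighbor_index = matrix(as.integer(arch$neighbor_index), p, k),
         features = matrix(arch$features, p, k),
         scale_min = arch$scale_min, scale_max = arch$scale_max,
         training_log = as_tibble(arch$training_log)),
    class = "psychollm")
}
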