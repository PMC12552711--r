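test_that("error metrics match hand arithmetic and enforce their guards", {
  expect_equal(mae(c(2, 4), c(1, 5)), 1.0)
  expect_equal(mae(1:5, 1:5), 0)
  expect_equal(mae(c(2, 4) + 10, c(1, 5) + 10), 1.0)  # translation invariant
  expect_equal(mape(c(2, 4), c(1, 5)), 0.375)
  expect_equal(mape(c(3, 3), c(3, 3)), 0)
  expect_equal(exact_match_rate(1:4, c(1L, 2L, 4L, 4L)), 0.75)
  expect_equal(exact_match_rate(1:3, 1:3), 1)
  expect_equal(exact_match_rate(1:3, c(2L, 3L, 1L)), 0)
  expect_error(mae(numeric(0), numeric(0)),
               class = "psychollm_validation_error")
  expect_error(mape(c(0, 2), c(1, 2)), "1-based",
               class = "psychollm_validation_error")
  expect_error(exact_match_rate(1:3, c(1, 2.5, 3)),
               class = "psychollm_validation_error")
})

test_that("LOIO on constant data is perfect and bookkeeping is complete", {
  q <- toy_questionnaire(6)
  E <- embed_items(q, hash_test_provider(8, seed = 2))
  r <- as_responses(matrix(2, 25, 6), item_ids(q))
  ev <- loio_evaluate(r, q, E, psychollm_config(seed = 1, epochs = 5))
  expect_equal(nrow(ev$per_item), 6)
  expect_equal(ev$aggregate$mae, 0)
  expect_equal(ev$aggregate$exact_match_rate, 1)
  # aggregate is the unweighted mean of per-item metrics
  expect_equal(ev$aggregate$mae, mean(ev$per_item$mae), tolerance = 1e-12)
  expect_equal(glance(ev)$protocol, "LOIO")
  expect_s3_class(autoplot(ev), "ggplot")
})

test_that("the neighbor-mean baseline reproduces hand-computed means", {
  # orthogonal pairs: Q1-Q2 similar, Q3-Q4 similar; with k = 2 the
  # neighbors of Q1 are Q2 then (tie by index) Q3
  E <- embedding_matrix(rbind(c(1, 0, 0.1), c(1, 0, 0), c(0, 1, 0.1),
                              c(0, 1, 0)) /
                          sqrt(rowSums(rbind(c(1, 0, 0.1), c(1, 0, 0),
                                             c(0, 1, 0.1),
                                             c(0, 1, 0))^2)),
                        sprintf("Q%d", 1:4))
  q <- toy_questionnaire(4)
  X <- cbind(c(1, 2, 3), c(2, 3, 4), c(4, 4, 4), c(1, 1, 1))
  r <- as_responses(X, item_ids(q))
  cfg <- psychollm_config(n_neighbors = 2, seed = 1,
                          round_predictions = FALSE, clip_to_scale = FALSE)
  bl <- loio_evaluate(r, q, E, cfg, predictor = "neighbor_mean",
                      round = FALSE, clip = FALSE)
  # Q1's neighbors: Q2 (0.995) and Q3 (~0.0995 > Q4's 0) -> mean of Q2, Q3
  hand_q1 <- mean(abs(X[, 1] - rowMeans(X[, c(2, 3)])))
  expect_equal(bl$per_item$mae[bl$per_item$item_id == "Q1"], hand_q1,
               tolerance = 1e-12)
  # baseline equals PsychoLLM when the learned weights are uniform
  m_frozen <- fit_psychollm(r, q, E,
                            psychollm_config(n_neighbors = 2, seed = 1,
                                             epochs = 1,
                                             learning_rate = 1e-12))
  w <- neighbor_weights(m_frozen)
  expect_equal(w$weight, rep(0.5, nrow(w)), tolerance = 1e-9)
})

test_that("LOSO holds out whole factors and covers each item once", {
  cfg <- synthetic_config(n_factors = 3, items_per_factor = 4,
                          embedding_dim = 12, n_respondents = 300,
                          within_factor_tightness = 0.7, axis_cosine = 0.6,
                          noise_sigma = 0.2, seed = 3)
  gen <- generate_embeddings(cfg)
  r <- generate_responses(gen$embeddings, cfg)
  pcfg <- psychollm_config(seed = 4, epochs = 60)
  evs <- lapply(c("G1", "G2", "G3"), function(f)
    loso_evaluate(r, gen$questionnaire, gen$embeddings, f, pcfg))
  covered <- unlist(lapply(evs, function(e) e$per_item$item_id))
  expect_setequal(covered, item_ids(gen$questionnaire))
  expect_equal(anyDuplicated(covered), 0L)
  fac <- item_factors(gen$questionnaire)
  # held-out items never appear among prediction neighbors
  for (i in seq_along(evs)) {
    held <- names(fac)[fac == c("G1", "G2", "G3")[i]]
    expect_length(intersect(evs[[i]]$per_item$item_id, held),
                  length(held))
  }
  expect_error(
    loso_evaluate(r, gen$questionnaire, gen$embeddings, "G9", pcfg),
    class = "psychollm_validation_error")
  q_nofac <- toy_questionnaire(4)
  E4 <- embed_items(q_nofac, hash_test_provider(6, seed = 2))
  r4 <- as_responses(matrix(sample(1:4, 80, TRUE), 20, 4), item_ids(q_nofac))
  expect_error(loso_evaluate(r4, q_nofac, E4, "A", pcfg),
               class = "psychollm_validation_error")
})

test_that("cross-questionnaire evaluation guards scales and respondents", {
  cfg <- synthetic_config(n_factors = 2, items_per_factor = 2,
                          embedding_dim = 8, n_respondents = 150,
                          within_factor_tightness = 0.9, noise_sigma = 0.1,
                          seed = 6)
  pair <- generate_paired_questionnaires(cfg)
  pcfg <- psychollm_config(n_neighbors = 2, seed = 5, epochs = 40)
  fwd <- cross_evaluate(pair$train$responses, pair$train$questionnaire,
                        pair$train$embeddings, pair$test$responses,
                        pair$test$questionnaire, pair$test$embeddings,
                        pcfg, n_runs = 2)
  bwd <- cross_evaluate(pair$test$responses, pair$test$questionnaire,
                        pair$test$embeddings, pair$train$responses,
                        pair$train$questionnaire, pair$train$embeddings,
                        pcfg, n_runs = 2)
  expect_equal(fwd$protocol, "CROSS")
  expect_equal(nrow(fwd$per_item), 4)
  expect_equal(nrow(bwd$per_item), 4)
  expect_equal(nrow(fwd$runs), 2)

  # scale mismatch
  q_wide <- questionnaire(as.data.frame(pair$test$questionnaire),
                          name = "wide", scale_min = 0, scale_max = 4)
  expect_error(
    cross_evaluate(pair$train$responses, pair$train$questionnaire,
                   pair$train$embeddings, pair$test$responses, q_wide,
                   pair$test$embeddings, pcfg),
    "identical Likert", class = "psychollm_validation_error")
  # respondent mismatch
  shrunk <- pair$test$responses[1:100, ]
  expect_error(
    cross_evaluate(pair$train$responses, pair$train$questionnaire,
                   pair$train$embeddings, shrunk,
                   pair$test$questionnaire, pair$test$embeddings, pcfg),
    class = "psychollm_validation_error")
})

test_that("aggregate MAE does not decrease as response noise grows", {
  sigmas <- c(0, 0.5, 1.5)
  for (seed in 1:3) {
    maes <- vapply(sigmas, function(s) {
      cfg <- synthetic_config(n_factors = 2, items_per_factor = 3,
                              embedding_dim = 8, n_respondents = 400,
                              within_factor_tightness = 0.8,
                              noise_sigma = s, seed = 100 + seed)
      gen <- generate_embeddings(cfg)
      r <- generate_responses(gen$embeddings, cfg)
      ev <- loio_evaluate(r, gen$questionnaire, gen$embeddings,
                          psychollm_config(seed = 1, epochs = 80))
      ev$aggregate$mae
    }, numeric(1))
    expect_true(all(diff(maes) >= -1e-9),
                info = sprintf("seed %d: %s", seed,
                               paste(round(maes, 3), collapse = " ")))
  }
})

test_that("the supervised adapter runs the same protocol and metrics", {
  q <- toy_questionnaire(5)
  z <- withr::with_seed(12, rnorm(80))
  X <- withr::with_seed(13,
    pmin(pmax(round(2.5 + cbind(z, z, z, z, z) +
                      matrix(rnorm(400, sd = 0.4), 80, 5)), 1), 4))
  r <- as_responses(X, item_ids(q))
  ev <- supervised_loio_evaluate(r, q, engine = "linear", seed = 2)
  expect_equal(nrow(ev$per_item), 5)
  expect_equal(ev$predictor, "supervised_linear")
  # one shared latent: regression on the other items must beat chance
  expect_lt(ev$aggregate$mae, 0.8)
  expect_equal(ev$aggregate$mae, mean(ev$per_item$mae), tolerance = 1e-12)
  skip_if_not_installed("randomForest")
  # randomForest warns about regression on few unique values; expected here
  rf <- suppressWarnings(
    supervised_loio_evaluate(r, q, engine = "random_forest", seed = 2,
                             ntree = 50))
  expect_equal(nrow(rf$per_item), 5)
  expect_true(all(rf$per_item$mae >= 0))
})
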