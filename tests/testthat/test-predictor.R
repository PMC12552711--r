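test_that("constant responses train to zero loss and reproduce the constant", {
  q <- toy_questionnaire(5)
  E <- embed_items(q, hash_test_provider(8, seed = 1))
  r <- as_responses(matrix(3, 40, 5), item_ids(q))
  cfg <- psychollm_config(seed = 2, epochs = 30)
  m <- fit_psychollm(r, q, E, cfg)
  expect_equal(m$training_log$loss, rep(0, 30), tolerance = 1e-20)
  target <- questionnaire(tibble::tibble(item_id = c("T1", "Zpad"),
                                         text = c("new statement", "pad")))
  Et <- embed_items(target, hash_test_provider(8, seed = 1))
  pr <- predict(m, target, Et, responses = r)
  expect_true(all(pr$T1 == 3))
})

test_that("interchangeable columns give near-zero training error", {
  # every item's score is (trivially) an exact convex combination of its
  # neighbors' because all columns are identical across items
  q <- toy_questionnaire(6)
  E <- embed_items(q, hash_test_provider(8, seed = 4))
  z <- withr::with_seed(8, rnorm(80))
  r <- as_responses(matrix(z, 80, 6), item_ids(q))
  cfg <- psychollm_config(seed = 3, epochs = 20, clip_to_scale = FALSE,
                          round_predictions = FALSE)
  m <- fit_psychollm(r, q, E, cfg)
  expect_lte(m$training_log$loss[20], 1e-2)
})

test_that("training is bit-deterministic given the seed", {
  cfgd <- synthetic_config(n_factors = 2, items_per_factor = 3,
                           embedding_dim = 8, n_respondents = 200, seed = 9)
  gen <- generate_embeddings(cfgd)
  r <- generate_responses(gen$embeddings, cfgd)
  cfg <- psychollm_config(seed = 11, epochs = 50)
  m1 <- fit_psychollm(r, gen$questionnaire, gen$embeddings, cfg)
  m2 <- fit_psychollm(r, gen$questionnaire, gen$embeddings, cfg)
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$params, m2$params)
  m3 <- fit_psychollm(r, gen$questionnaire, gen$embeddings,
                      psychollm_config(seed = 12, epochs = 50))
  expect_false(identical(m1$params, m3$params))
})

test_that("training loss decreases on structured data", {
  cfgd <- synthetic_config(n_factors = 2, items_per_factor = 4,
                           embedding_dim = 8, n_respondents = 500,
                           within_factor_tightness = 0.7,
                           noise_sigma = 0.3, seed = 19)
  gen <- generate_embeddings(cfgd)
  r <- generate_responses(gen$embeddings, cfgd)
  m <- fit_psychollm(r, gen$questionnaire, gen$embeddings,
                     psychollm_config(seed = 5, epochs = 200))
  expect_lt(m$training_log$loss[200], m$training_log$loss[1])
  expect_true(all(is.finite(m$training_log$loss)))
})

test_that("softmax weights are convex and predictions stay in neighbor range", {
  cfgd <- synthetic_config(n_factors = 2, items_per_factor = 4,
                           embedding_dim = 8, n_respondents = 300,
                           seed = 23)
  gen <- generate_embeddings(cfgd)
  r <- generate_responses(gen$embeddings, cfgd)
  m <- fit_psychollm(r, gen$questionnaire, gen$embeddings,
                     psychollm_config(seed = 7, epochs = 80))
  w <- neighbor_weights(m)
  sums <- tapply(w$weight, w$item_id, sum)
  expect_equal(as.numeric(sums), rep(1, 8), tolerance = 1e-12)
  expect_true(all(w$weight >= 0))

  # predictions are convex combinations, hence within the neighbor range
  target <- questionnaire(tibble::tibble(item_id = c("N1", "N2"),
                                         text = c("another statement a",
                                                  "another statement b")))
  Et <- embed_items(target, hash_test_provider(8, seed = 23))
  pr <- predict(m, target, Et, responses = r, round = FALSE, clip = FALSE)
  wts <- attr(pr, "weights")
  X <- as.matrix(as.data.frame(r[item_ids(gen$questionnaire)]))
  for (t_ in c("N1", "N2")) {
    nb <- wts$neighbor_id[wts$item_id == t_]
    lo <- apply(X[, nb], 1, min)
    hi <- apply(X[, nb], 1, max)
    expect_true(all(pr[[t_]] >= lo - 1e-9 & pr[[t_]] <= hi + 1e-9))
  }
})

test_that("at a symmetric initialization the prediction is the neighbor mean", {
  cfgd <- synthetic_config(n_factors = 2, items_per_factor = 3,
                           embedding_dim = 8, n_respondents = 100, seed = 31)
  gen <- generate_embeddings(cfgd)
  r <- generate_responses(gen$embeddings, cfgd)
  # vanishing learning rate freezes the zero-initialized output layer,
  # whose softmax is exactly uniform
  m <- fit_psychollm(r, gen$questionnaire, gen$embeddings,
                     psychollm_config(seed = 3, epochs = 1,
                                      learning_rate = 1e-12))
  w <- neighbor_weights(m)
  expect_equal(w$weight, rep(1 / 3, nrow(w)), tolerance = 1e-9)
})

test_that("a duplicated target item is predicted near-exactly", {
  # three training items share one embedding and one score column; the
  # target duplicates that embedding, so all its neighbors carry the answer
  d <- 8
  base <- withr::with_seed(41, rnorm(d))
  base <- base / sqrt(sum(base^2))
  others <- withr::with_seed(42, matrix(rnorm(3 * d), 3, d))
  others <- others / sqrt(rowSums(others^2))
  E <- embedding_matrix(rbind(base, base, base, others),
                        c("C1", "C2", "C3", "O1", "O2", "O3"))
  q <- questionnaire(tibble::tibble(
    item_id = c("C1", "C2", "C3", "O1", "O2", "O3"),
    text = sprintf("item %d", 1:6)))
  col <- withr::with_seed(43, sample(1:4, 150, replace = TRUE))
  other_scores <- withr::with_seed(44,
                                   matrix(sample(1:4, 450, replace = TRUE),
                                          150, 3))
  r <- as_responses(cbind(col, col, col, other_scores), item_ids(q))
  m <- fit_psychollm(r, q, E, psychollm_config(seed = 1, epochs = 100))
  Et <- embedding_matrix(matrix(base, 1), "TARGET")
  pr <- predict(m, tibble::tibble(item_id = "TARGET", text = "dup"),
                Et, responses = r, round = FALSE)
  expect_lte(mean(abs(pr$TARGET - col)), 0.05)
})

test_that("predictions are clipped and rounded onto the Likert grid", {
  q <- toy_questionnaire(5)
  E <- embed_items(q, hash_test_provider(8, seed = 6))
  r <- as_responses(matrix(4.7, 30, 5), item_ids(q))  # continuous scores
  m <- fit_psychollm(r, q, E, psychollm_config(seed = 2, epochs = 5))
  Et <- embed_items(tibble::tibble(item_id = "T", text = "t"),
                    hash_test_provider(8, seed = 6))
  raw <- predict(m, tibble::tibble(item_id = "T", text = "t"), Et,
                 responses = r, round = FALSE, clip = FALSE)
  expect_equal(raw$T[1], 4.7, tolerance = 1e-12)
  cooked <- predict(m, tibble::tibble(item_id = "T", text = "t"), Et,
                    responses = r, round = TRUE, clip = TRUE)
  expect_true(all(cooked$T == 4))
})

test_that("the leakage guard refuses targets in the training set", {
  q <- toy_questionnaire(5)
  E <- embed_items(q, hash_test_provider(8, seed = 1))
  r <- as_responses(matrix(sample(1:4, 200, replace = TRUE), 40, 5),
                    item_ids(q))
  m <- fit_psychollm(r, q, E, psychollm_config(seed = 2, epochs = 5))
  expect_error(predict(m, tibble::tibble(item_id = "Q2", text = "x"), E,
                       responses = r),
               class = "psychollm_leakage_error")
  # too few training items
  q3 <- questionnaire(as.data.frame(q)[1:3, ], name = "toy3")
  expect_error(fit_psychollm(r, q3, E, psychollm_config(seed = 1)),
               class = "psychollm_validation_error")
})

test_that("a saved model archive reloads and predicts bit-identically", {
  cfgd <- synthetic_config(n_factors = 2, items_per_factor = 4,
                           embedding_dim = 8, n_respondents = 150,
                           within_factor_tightness = 0.8,
                           noise_sigma = 0.2, seed = 71)
  gen <- generate_embeddings(cfgd)
  r <- generate_responses(gen$embeddings, cfgd)
  m <- fit_psychollm(r, gen$questionnaire, gen$embeddings,
                     psychollm_config(seed = 6, epochs = 50))
  f <- withr::local_tempfile(fileext = ".json")
  save_psychollm(m, f)
  m2 <- load_psychollm(f)
  expect_equal(m2$params, m$params, tolerance = 1e-12)
  expect_identical(m2$train_item_ids, m$train_item_ids)
  expect_equal(unclass(m2$train_embeddings), unclass(m$train_embeddings),
               tolerance = 1e-14, ignore_attr = TRUE)
  target <- tibble::tibble(item_id = "NEW", text = "a new statement")
  Et <- embed_items(target, hash_test_provider(8, seed = 71))
  p1 <- predict(m, target, Et, responses = r, round = FALSE)
  p2 <- predict(m2, target, Et, responses = r, round = FALSE)
  expect_equal(p1$NEW, p2$NEW, tolerance = 1e-12)
})
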