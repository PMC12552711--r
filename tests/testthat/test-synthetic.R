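test_that("factor-structured embeddings honor tightness extremes", {
  cfg1 <- synthetic_config(n_factors = 3, items_per_factor = 3,
                           embedding_dim = 8,
                           within_factor_tightness = 1, seed = 1)
  S <- cosine_similarity_matrix(generate_embeddings(cfg1)$embeddings)
  fac <- rep(1:3, each = 3)
  same <- outer(fac, fac, "==") & upper.tri(S)
  diff_ <- outer(fac, fac, "!=") & upper.tri(S)
  expect_equal(unclass(S)[same], rep(1, sum(same)), tolerance = 1e-12)
  expect_equal(unclass(S)[diff_], rep(0, sum(diff_)), tolerance = 1e-12)

  # tightness 0 in high dimension: mean signed similarity near zero
  cfg0 <- synthetic_config(n_factors = 3, items_per_factor = 3,
                           embedding_dim = 256,
                           within_factor_tightness = 0, seed = 2)
  S0 <- cosine_similarity_matrix(generate_embeddings(cfg0)$embeddings)
  expect_lt(abs(mean(S0[upper.tri(S0)])), 0.05)

  # determinism and dimension guard
  g1 <- generate_embeddings(cfg1)
  g2 <- generate_embeddings(cfg1)
  expect_identical(unclass(g1$embeddings), unclass(g2$embeddings))
  expect_error(synthetic_config(n_factors = 5, embedding_dim = 4),
               class = "psychollm_validation_error")
})

test_that("simulated responses live on the Likert grid and are seeded", {
  cfg <- synthetic_config(n_factors = 2, items_per_factor = 3,
                          embedding_dim = 8, n_respondents = 500,
                          noise_sigma = 0.4, seed = 5)
  gen <- generate_embeddings(cfg)
  r1 <- generate_responses(gen$embeddings, cfg)
  r2 <- generate_responses(gen$embeddings, cfg)
  expect_identical(r1, r2)
  X <- as.matrix(r1[item_ids(gen$questionnaire)])
  expect_true(all(X >= 1 & X <= 4))
  expect_true(all(X == round(X)))
  # all categories populated under equal-probability thresholds
  expect_setequal(sort(unique(as.vector(X))), 1:4)
  # unit-norm precondition
  bad <- embedding_matrix(unclass(gen$embeddings) * 2,
                          rownames(gen$embeddings))
  expect_error(generate_responses(bad, cfg),
               class = "psychollm_validation_error")
})

test_that("anchor-layout geometry is exactly as designed", {
  anc <- generate_anchor_embeddings(n_items = 12, seed = 4,
                                    embedding_dim = 16)
  S <- cosine_similarity_matrix(anc$embeddings)
  # anchors prefer anchors
  for (a in 1:4) {
    nb <- top_k_neighbors(S, rownames(S)[a], 3)
    expect_setequal(nb$item_id, setdiff(sprintf("A%02d", 1:4),
                                        rownames(S)[a]))
  }
  # every derived item's neighbors are anchors 1-3, in order
  for (j in 5:12) {
    nb <- top_k_neighbors(S, rownames(S)[j], 3)
    expect_equal(nb$item_id, c("A01", "A02", "A03"))
    expect_true(all(diff(nb$similarity) < -0.01))
  }
  expect_equal(unclass(S)[1, 2], 0.75, tolerance = 1e-9)
})

test_that("planted-weights data realizes the planted relation exactly", {
  anc <- generate_anchor_embeddings(n_items = 10, seed = 7,
                                    embedding_dim = 16)
  cfg <- synthetic_config(n_respondents = 60, noise_sigma = 0, seed = 8)

  # degenerate weights: each smoothed column duplicates its nearest neighbor
  d1 <- generate_planted_weights_data(anc$embeddings, cfg,
                                      weights = c(1, 0, 0),
                                      continuous = TRUE)
  nb <- attr(d1, "neighbor_table")
  for (id in attr(d1, "smoothed_items")) {
    n1 <- nb$neighbor_id[nb$item_id == id & nb$rank == 1]
    expect_equal(d1[[id]], d1[[n1]], tolerance = 1e-12)
  }

  # uniform weights: each smoothed column is its 3-neighbor mean
  d2 <- generate_planted_weights_data(anc$embeddings, cfg,
                                      weights = rep(1, 3) / 3,
                                      continuous = TRUE)
  nb2 <- attr(d2, "neighbor_table")
  for (id in attr(d2, "smoothed_items")) {
    nbs <- nb2$neighbor_id[nb2$item_id == id]
    expect_equal(d2[[id]], rowMeans(cbind(d2[[nbs[1]]], d2[[nbs[2]]],
                                          d2[[nbs[3]]])),
                 tolerance = 1e-12)
  }

  # Likert output stays on the grid; invalid simplex rejected
  d3 <- generate_planted_weights_data(anc$embeddings, cfg)
  X <- as.matrix(d3[item_ids(anc$questionnaire)])
  expect_true(all(X >= 1 & X <= 4))
  expect_error(
    generate_planted_weights_data(anc$embeddings, cfg, weights = c(2, -1)),
    class = "psychollm_validation_error")
})

test_that("paired questionnaires share respondents and latent structure", {
  cfg <- synthetic_config(n_factors = 2, items_per_factor = 2,
                          embedding_dim = 8, n_respondents = 400,
                          within_factor_tightness = 0.9, noise_sigma = 0,
                          seed = 9)
  pair <- generate_paired_questionnaires(cfg, duplicate_items = TRUE)
  expect_identical(pair$train$responses$respondent_id,
                   pair$test$responses$respondent_id)
  # identical item vectors, sigma = 0: cross-instrument twins correlate 1
  ids_a <- item_ids(pair$train$questionnaire)
  ids_b <- item_ids(pair$test$questionnaire)
  expect_length(intersect(ids_a, ids_b), 0)
  for (i in seq_along(ids_a)) {
    expect_equal(cor(pair$train$responses[[ids_a[i]]],
                     pair$test$responses[[ids_b[i]]]), 1)
  }

  # orthogonal constructs give near-zero cross-construct correlations
  cfg0 <- synthetic_config(n_factors = 2, items_per_factor = 2,
                           embedding_dim = 8, n_respondents = 10000,
                           within_factor_tightness = 1, noise_sigma = 0,
                           axis_cosine = 0, seed = 10)
  p0 <- generate_paired_questionnaires(cfg0)
  fac_a <- item_factors(p0$train$questionnaire)
  fac_b <- item_factors(p0$test$questionnaire)
  for (ia in names(fac_a)) {
    for (ib in names(fac_b)) {
      if (fac_a[ia] != fac_b[ib]) {
        expect_lt(abs(cor(p0$train$responses[[ia]],
                          p0$test$responses[[ib]])), 0.05)
      }
    }
  }
})
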