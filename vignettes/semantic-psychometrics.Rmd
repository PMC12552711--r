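---
title: "Semantic structure, score structure, and neighbor-based imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic structure, score structure, and neighbor-based imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psychollm)
library(dplyr)
```

## The model

A questionnaire is two datasets in one. Each item is a short statement whose
meaning can be embedded as a vector $e_j \in \mathbb{R}^d$ by a language
model; and each item carries a column of integer Likert scores across
respondents. The package quantifies, and then exploits, the hypothesis that
the two structures mirror each other:

$$\mathrm{sim}(e_i, e_j) \;\approx\; \rho(y_i, y_j),$$

where $\mathrm{sim}$ is cosine similarity,
$\mathrm{sim}(e_i,e_j) = e_i \cdot e_j / (\lVert e_i\rVert\,\lVert
e_j\rVert)$, collected in the $p \times p$ matrix $S$, and $\rho$ is the
inter-item score correlation, collected in $C$. Correlations enter in
absolute value by default: a reverse-keyed item that correlates $-0.7$ with
its neighbor is as semantically bound to it as one correlating $+0.7$, so
magnitudes are the right scale for alignment questions (raw scores are never
re-keyed).

Three layers of analysis sit on top:

1. **Alignment** (`semantic_alignment()`): *Top-K accuracy* — for each item,
   is its most-correlated partner (argmax of $|C|$ off the diagonal) among
   its $K$ most similar items in $S$? — plus Pearson/Spearman correlations
   between the strict upper triangles of $S$ and $C$, with a t-test on
   $p(p-1)/2 - 2$ degrees of freedom.
2. **Factor analysis on $S$** (`factor_analyze()`): $S$ is treated as a
   correlation-like matrix and decomposed by minimum-residual factor
   analysis, exactly as one would decompose $C$; `factor_agreement()`
   matches the two solutions by Tucker congruence and reports how many items
   land in the same factor.
3. **PsychoLLM** (`fit_psychollm()`): a self-supervised predictor of unseen
   item scores. For a target item $t$, take its $k$ (default 3) nearest
   training items by cosine similarity; a two-layer network maps the
   similarity profile $(s_{t,1}, \dots, s_{t,k})$ through a hidden ReLU
   layer to $k$ softmax weights $w(t)$, and the prediction for respondent
   $i$ is the convex combination $\hat y_{it} = \sum_m w_m(t)\,
   y_{i,n_m(t)}$. Training is self-supervised: every *training* item plays
   the target in turn and the network minimizes the mean squared error over
   all (respondent, item) pairs. Because the inputs are per-item similarity
   profiles rather than anything respondent-specific, the trained network
   transfers to items — and whole questionnaires — it has never seen.

Three evaluation protocols probe increasingly hard transfer:
leave-one-item-out (`loio_evaluate()`), leave-one-subscale-out
(`loso_evaluate()`, all items of one factor held out together), and
cross-questionnaire (`cross_evaluate()`, train on one instrument, predict
the same respondents' answers to another). Metrics are MAE, MAPE (a
fraction; requires 1-based positive Likert codes) and, for rounded
predictions, the exact-match rate; the aggregate is always the unweighted
mean of per-item values. A neighbor-mean baseline
(`neighbor_mean_baseline()`) runs the identical protocols with uniform
weights.

## Why the input features are the k similarities

The architecture description "the similarity matrix is fed into two fully
connected layers" is ambiguous between feeding the whole $p \times p$ matrix
and feeding each target's neighbor-similarity profile. This package feeds
the profile. A network over the full matrix is tied to one questionnaire's
dimension and item order and could not score a new item, whereas a
profile-based network is dimension-free; only this reading supports the
leave-one-subscale-out and cross-questionnaire protocols at all. Weights
depend on the item only, never on the respondent.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_neighbors` | 3 | neighbors per target; 3 typically suffices to capture the most-correlated partner |
| `hidden_units` | 16 | width of the hidden layer |
| `epochs`, `learning_rate` | 500, 0.02 | full-batch Adam; enough budget for softmax logits to express strongly skewed weights (a logit spread of ~2 at ~`lr` movement per step) |
| `seed` | required | all training randomness |
| `clip_to_scale`, `round_predictions` | `TRUE` | clamp to the Likert bounds; round half-away-from-zero to integer codes |

The output layer starts at zero, so the initial softmax weights are exactly
uniform: untrained, PsychoLLM *is* the neighbor-mean baseline, and training
can only move it away from that reference.

## The synthetic generator

Desk-scale testing needs data where the semantic-empirical coupling is
known exactly. The generator (`synthetic_config()`,
`generate_embeddings()`, `generate_responses()`) draws `n_factors` unit
factor axes — orthonormal, or pairwise-oblique at cosine `axis_cosine` —
and places each item at $\mathrm{normalize}(t \cdot a_f + (1-t) \cdot u)$
with tightness $t$ and a random direction $u$. Respondent $i$ draws a
latent $z_i$ of iid standard normals and scores
$y_{ij} = e_j \cdot z_i + \sigma \varepsilon_{ij}$, which gives the exact
population law

$$\mathrm{Corr}(y_j, y_k) = \frac{S_{jk}}{1 + \sigma^2}.$$

So the empirical correlation matrix converges element-wise to a known
monotone function of the similarity matrix, making the generator itself
testable. Discretization uses fixed equal-probability thresholds of the
marginal normal, so all Likert categories stay populated and Pearson on
codes is well-behaved; it is monotone, hence approximately rank-preserving.

`axis_cosine` exists because real clinical subscales (depression, anxiety,
stress) are strongly intercorrelated; with orthonormal axes, holding out a
whole subscale would leave its items orthogonal to every training item, and
cross-construct prediction would be impossible rather than merely harder.
The subscale-transfer studies use `axis_cosine = 0.9` with tightness 0.6,
which reproduces the realistic regime of within-subscale score correlations
around 0.6 and cross-subscale correlations only slightly lower.

### Planted-weights data

`generate_planted_weights_data()` is the oracle for parameter recovery: it
draws an initial independent matrix and then applies one smoothing pass in
which an item's column is replaced by a fixed convex combination (the
planted weights) of its $k$ nearest neighbors' columns plus noise. The pass
deliberately skips *source* items — items appearing in any other item's
neighbor list — leaving them at their initial draw. This is what makes the
planted relation hold exactly in the returned matrix: if sources were
themselves smoothed, every neighbor column would be a mixture of third
items' draws, the degenerate-weights case (weights $(1,0,0)$ duplicating
the nearest neighbor's column) would be false, and the planted weights
would not be identifiable from the data at all.

Pair it with `generate_anchor_embeddings()`: four mutually similar anchor
items (pairwise cosine 0.75) and, for every remaining item, one fixed
convex position over anchors 1–3 (cosines about 0.69/0.66/0.65) plus an
item-unique orthogonal component. By construction every non-anchor item's
top-3 neighbors are anchors 1–3 in that order, anchors prefer anchors, and
all similarity gaps are at least ~0.01 — so with 42 items, 38 (90.5%) carry
the planted relation and the recovery experiment is exactly identifiable.

### Paired questionnaires

`generate_paired_questionnaires()` emulates two related instruments
answered by the same respondents: both item sets load on one shared factor
set and one shared latent sample generates both response matrices on the
same Likert range. Defaults (3 factors × 2 items per instrument, tightness
0.95, `axis_cosine` 0.5, $\sigma = 0.1$) emulate short anxiety/depression
scales whose items are near-paraphrases across instruments — the regime in
which cross-instrument prediction is strong — while keeping each test
item's third semantic neighbor a cross-factor item, so learned skewed
weights genuinely separate PsychoLLM from the uniform baseline.

## Numerical choices

- **Ties** are always broken by ascending item index (neighbor ranking and
  correlation argmax, the latter with a warning): deterministic across
  platforms.
- **Matrix correlation** uses the strict upper triangle only; including the
  unit diagonals would inflate both coefficients. At $|r| = 1$ the t
  statistic is infinite and the p-value exactly 0. The t-test treats
  triangle entries as independent, which they are not; a seeded Mantel
  permutation test (`test = "mantel"`, default 9999 permutations) is the
  statistically honest alternative and is off by default only to keep the
  headline numbers comparable with the t-test convention.
- **minres** extraction optimizes uniquenesses with L-BFGS-B over
  $[10^{-3}, 1]$, starting from squared multiple correlations; loadings
  come from the eigendecomposition of the reduced matrix. Similarity
  matrices with negative eigenvalues are smoothed to the nearest PSD matrix
  (eigenvalue clipping, rescale to unit diagonal) with the Frobenius
  distance reported. Varimax rotation skips Kaiser normalization when some
  communalities are ~0 (e.g. an identity input), where it would divide by
  zero. Factor signs are normalized so each factor's dominant loading is
  positive. Defaults (minres + varimax, user-supplied factor count — 3 for
  a depression/anxiety/stress instrument) are the field's conventions.
- **Rounding** is half-away-from-zero, then clamped to the scale; base R's
  banker's rounding would bias even codes.
- **MAPE** is reported as a fraction and requires strictly positive
  observed codes; inside evaluation results it is `NA` (not an error) when
  targets are continuous, as is the exact-match rate when predictions are
  unrounded.
- **Missing data**: respondents with any missing value among the items an
  analysis uses are dropped for that analysis (complete case). Nothing is
  imputed on the input side.

## Study sizes used by the test suite and acceptance script

Alignment fidelity uses $n = 20{,}000$ continuous respondents (15 items,
$\sigma = 0.5$); discretization robustness $n = 5{,}000$ over 3 seeds;
parameter recovery 42 items × $n = 2{,}000$ at $\sigma = 0.05$; the
LOIO/LOSO studies 15 items × $n = 1{,}000{-}2{,}000$; cross-questionnaire
$n = 1{,}000$ with 5 training restarts averaged. Parameter recovery is
scored on continuous scores with unrounded MAE — it is a continuous
identification check, and discretization is a separately tested layer.

## What passing tests do and do not show

The generator targets the structural assumptions — a latent-trait response
model whose correlation structure is an exact monotone image of the
similarity structure — not the look of real data. It does not emulate real
marginal distributions, acquiescence or other response styles, item-order
effects, missingness mechanisms, or the gap between true semantic
similarity and what any particular embedding model measures. Tests passing
on synthetic data therefore validate the machinery (metrics, protocols,
leakage guards, recovery of known structure), not the empirical claim that
a given language model's geometry matches human response data; that claim
requires real instruments, real respondents, and a real embedding
provider. Cross-instrument prediction is also only defined under identical
Likert bounds on both instruments — heterogeneous scales would need a
score-transformation layer that is out of scope here.
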