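#' Minimum-residual factor analysis of a correlation-like matrix
#'
#' Extracts `n_factors` factors from a symmetric unit-diagonal matrix —
#' either an empirical score correlation matrix or a semantic similarity
#' matrix, which this package deliberately treats as the same kind of
#' object — by minimizing the sum of squared off-diagonal residuals over
#' the uniquenesses (minres). Matrices that are not positive semidefinite
#' beyond round-off are smoothed first by clipping negative eigenvalues at
#' zero and rescaling to a unit diagonal (the Frobenius distance moved is
#' reported in a message). Loadings are rotated (`varimax` by default) and
#' sign-normalized so each factor's largest absolute loading is positive.
#'
#' @param M symmetric matrix with unit diagonal ([cosine_similarity_matrix()]
#'   or [score_correlation_matrix()] output, or a plain matrix).
#' @param n_factors number of factors `m`, `1 <= m < p`.
#' @param rotation `"varimax"`, `"promax"` or `"none"`.
#' @return A `factor_solution`: list with `loadings` (p x m, item ids as row
#'   names), `uniquenesses`, `assignment` (item -> factor index by largest
#'   absolute loading), `n_factors`, `rotation`, `criterion` (final minres
#'   objective value).
#' @export
factor_analyze <- function(M, n_factors,
                           rotation = c("varimax", "promax", "none")) {
  rotation <- match.arg(rotation)
  M <- unclass(as.matrix(M))
  p <- nrow(M)
  ids <- rownames(M) %||% sprintf("item%02d", seq_len(p))
  if (n_factors < 1 || n_factors >= p) {
    abort(sprintf("n_factors must be in [1, %d].", p - 1),
          class = "psychollm_validation_error")
  }
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-8 ||
      max(abs(diag(M) - 1)) > 1e-8) {
    abort("M must be square and symmetric with a unit diagonal.",
          class = "psychollm_validation_error")
  }
  M <- (M + t(M)) / 2
  M <- smooth_to_psd(M)
  m <- as.integer(n_factors)

  loadings_from_psi <- function(psi) {
    Rc <- M
    diag(Rc) <- 1 - psi
    ee <- eigen(Rc, symmetric = TRUE)
    L <- ee$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(pmax(ee$values[seq_len(m)], 0)), m)
    L
  }
  objective <- function(psi) {
    resid <- M - tcrossprod(loadings_from_psi(psi))
    sum(resid[upper.tri(resid)]^2)
  }
  start <- tryCatch({
    smc <- 1 - 1 / diag(solve(M))
    clamp(1 - smc, 0.05, 0.95)
  }, error = function(e) rep(0.5, p))
  opt <- optim(start, objective, method = "L-BFGS-B",
               lower = 1e-3, upper = 1,
               control = list(maxit = 500, factr = 1e9))
  if (!opt$convergence %in% c(0L, 1L)) {
    abort(sprintf("minres failed to converge (optim code %d after %d evals).",
                  opt$convergence, opt$counts[1]),
          class = "psychollm_numeric_error")
  }
  L <- loadings_from_psi(opt$par)

  h2 <- rowSums(L^2)
  if (rotation != "none" && m > 1 && any(h2 > 1e-8)) {
    # Kaiser normalization divides by communalities; unsafe when some are ~0
    normalize <- all(h2 > 1e-6)
    rot <- switch(rotation,
                  varimax = varimax(L, normalize = normalize),
                  promax = promax(L))
    L <- unclass(rot$loadings)
  }
  # sign convention: dominant loading of each factor positive
  for (f in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, f])), f] < 0) L[, f] <- -L[, f]
  }
  rownames(L) <- ids
  colnames(L) <- sprintf("F%d", seq_len(m))
  assignment <- apply(abs(L), 1, which.max)
  structure(
    list(loadings = L,
         uniquenesses = setNames(opt$par, ids),
         assignment = setNames(as.integer(assignment), ids),
         n_factors = m, rotation = rotation, criterion = opt$value),
    class = "factor_solution")
}

# Clip negative eigenvalues at zero and rescale to unit diagonal; report the
# Frobenius distance when smoothing actually did something.
smooth_to_psd <- function(M, tol = 1e-8) {
  ee <- eigen(M, symmetric = TRUE)
  if (min(ee$values) >= -tol) return(M)
  vals <- pmax(ee$values, 0)
  M2 <- ee$vectors %*% diag(vals) %*% t(ee$vectors)
  d <- sqrt(diag(M2))
  d[d == 0] <- 1
  M2 <- M2 / tcrossprod(d)
  diag(M2) <- 1
  inform(sprintf(
    "Smoothed matrix to nearest PSD (Frobenius distance %.4g).",
    sqrt(sum((M2 - M)^2))))
  dimnames(M2) <- dimnames(M)
  M2
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("<factor_solution> %d items, %d factors (minres, %s)\n",
              nrow(x$loadings), x$n_factors, x$rotation))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Agreement between two factor solutions
#'
#' Matches the factors of `b` to those of `a` by the permutation maximizing
#' total absolute Tucker congruence (exhaustive search; factor counts are
#' small), then reports the fraction of items assigned to the same matched
#' factor and the mean matched congruence. Used to ask whether factor
#' analysis of the semantic similarity matrix recovers the same structure
#' as factor analysis of the empirical correlation matrix.
#'
#' @param a,b `factor_solution` objects over the same items with the same
#'   number of factors.
#' @return A list: `agreement_rate` in `[0, 1]`, `mean_congruence` in
#'   `[0, 1]` (absolute Tucker coefficients), `permutation` (factor of `b`
#'   matched to each factor of `a`), `congruence` (m x m matrix).
#' @export
factor_agreement <- function(a, b) {
  if (!setequal(rownames(a$loadings), rownames(b$loadings))) {
    abort("Factor solutions cover different item sets.",
          class = "psychollm_validation_error")
  }
  if (a$n_factors != b$n_factors) {
    abort("Factor solutions have different numbers of factors.",
          class = "psychollm_validation_error")
  }
  ids <- rownames(a$loadings)
  Lb <- b$loadings[ids, , drop = FALSE]
  La <- a$loadings
  m <- a$n_factors
  phi <- matrix(0, m, m)
  for (f in seq_len(m)) {
    for (g in seq_len(m)) {
      phi[f, g] <- tucker_congruence(La[, f], Lb[, g])
    }
  }
  perms <- all_permutations(m)
  scores <- vapply(perms, function(pp) {
    sum(abs(phi[cbind(seq_len(m), pp)]))
  }, numeric(1))
  best <- perms[[which.max(scores)]]
  assign_b <- b$assignment[ids]
  matched_b <- match(assign_b, best) # b factor -> a factor label
  agreement <- mean(matched_b == a$assignment[ids])
  list(agreement_rate = agreement,
       mean_congruence = mean(abs(phi[cbind(seq_len(m), best)])),
       permutation = best, congruence = phi)
}

#' Tucker congruence coefficient between two loading vectors
#'
#' The cosine of the angle between two factors' loading vectors.
#'
#' @param x,y numeric vectors of equal length.
#' @return A value in `[-1, 1]`.
#' @export
tucker_congruence <- function(x, y) {
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}
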