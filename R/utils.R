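# Internal helpers shared across modules.

# Round half away from zero (Likert codes are symmetric around .5 boundaries;
# base round() is banker's rounding and would bias even codes).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clamp <- function(x, lo, hi) {
  pmin(pmax(x, lo), hi)
}

# Derive `n` reproducible sub-seeds (< 2^31) from one master seed without
# touching the caller's RNG state.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

is_whole <- function(x) {
  is.finite(x) & abs(x - round(x)) < 1e-8
}

# all permutations of 1:m (m small; used for factor matching)
all_permutations <- function(m) {
  if (m == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(m)) {
    sub <- all_permutations(m - 1L)
    rest <- setdiff(seq_len(m), i)
    out <- c(out, lapply(sub, function(p) c(i, rest[p])))
  }
  out
}

upper_vec <- function(M) M[upper.tri(M)]

`%||%` <- rlang::`%||%`
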