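#' Construct an embedding matrix
#'
#' One row per item, in questionnaire order; rows may have any norm (cosine
#' similarity normalizes at use time) but must not be zero vectors.
#'
#' @param vectors p x d numeric matrix.
#' @param item_ids character vector of length p.
#' @param provider_tag string recording where the vectors came from.
#' @return An `embedding_matrix` (a numeric matrix with row names and a
#'   `provider_tag` attribute).
#' @export
embedding_matrix <- function(vectors, item_ids, provider_tag = "unknown") {
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (length(item_ids) != nrow(vectors)) {
    abort("`item_ids` must have one entry per embedding row.",
          class = "psychollm_validation_error")
  }
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) {
    abort(sprintf("Zero-norm embedding for item(s): %s.",
                  paste(item_ids[nrm == 0], collapse = ", ")),
          class = "psychollm_validation_error")
  }
  rownames(vectors) <- as.character(item_ids)
  structure(vectors, provider_tag = provider_tag,
            class = c("embedding_matrix", "matrix", "array"))
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d items x %d dims (provider: %s)\n",
              nrow(x), ncol(x), attr(x, "provider_tag")))
  invisible(x)
}

#' Deterministic test embedding provider
#'
#' Maps each item text to a unit-norm `d`-dimensional vector that is a pure
#' function of the text bytes and the seed. Distinct texts map to distinct
#' vectors with probability essentially 1. Useful wherever a language-model
#' provider would be too heavy: every downstream code path works identically
#' on its output.
#'
#' @param d embedding dimension (>= 2).
#' @param seed integer mixed into every text's vector.
#' @return A provider handle for [embed_items()].
#' @examples
#' p <- hash_test_provider(8, seed = 1)
#' v <- p$embed("I feel tired")
#' sum(v^2) # 1
#' @export
hash_test_provider <- function(d, seed = 0L) {
  if (d < 2) {
    abort("Test provider needs d >= 2.", class = "psychollm_validation_error")
  }
  d <- as.integer(d)
  seed <- as.integer(seed)
  embed_one <- function(text) {
    s <- text_seed(text, seed)
    v <- withr::with_seed(s, rnorm(d))
    v / sqrt(sum(v^2))
  }
  structure(
    list(tag = sprintf("hash-test/d=%d/seed=%d", d, seed),
         d = d,
         embed = function(text) embed_one(text)),
    class = "psychollm_provider")
}

# Deterministic 31-bit seed from text bytes plus a user seed (polynomial
# rolling hash; doubles stay exact well below 2^53).
text_seed <- function(text, seed) {
  codes <- utf8ToInt(enc2utf8(text))
  h <- (as.double(seed) %% 2147483647) + 1
  for (c in codes) {
    h <- (h * 131 + c) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

#' Embed questionnaire items through a provider
#'
#' Calls the provider once per distinct item text, in item order. With a
#' `cache_dir`, vectors are read from / appended to an on-disk cache keyed by
#' (provider tag, exact text), so repeated runs are reproducible offline and
#' byte-identical texts always receive identical vectors.
#'
#' @param items a [questionnaire()] or a data frame with `item_id`, `text`.
#' @param provider a provider handle such as [hash_test_provider()].
#' @param cache_dir optional directory for the embedding cache.
#' @return An [embedding_matrix()] with one row per item, in item order.
#' @export
embed_items <- function(items, provider, cache_dir = NULL) {
  items <- as_tibble(items)
  if (!all(c("item_id", "text") %in% names(items))) {
    abort("`items` must have `item_id` and `text` columns.",
          class = "psychollm_schema_error")
  }
  if (!inherits(provider, "psychollm_provider")) {
    abort(paste("Unknown provider. Use hash_test_provider() for offline work",
                "or load a cached matrix with load_embeddings()."),
          class = "psychollm_validation_error")
  }
  cache <- if (!is.null(cache_dir)) read_embedding_cache(cache_dir, provider$tag)
  vecs <- matrix(NA_real_, nrow(items), provider$d)
  new_rows <- list()
  for (i in seq_len(nrow(items))) {
    txt <- items$text[i]
    hit <- if (!is.null(cache)) cache[[txt]]
    if (is.null(hit)) {
      hit <- provider$embed(txt)
      if (all(hit == 0)) {
        abort(sprintf("Provider returned a zero vector for item %s.",
                      items$item_id[i]),
              class = "psychollm_validation_error")
      }
      if (!is.null(cache)) {
        cache[[txt]] <- hit
        new_rows[[length(new_rows) + 1L]] <- c(list(text = txt), as.list(hit))
      }
    }
    vecs[i, ] <- hit
  }
  if (!is.null(cache_dir) && length(new_rows)) {
    write_embedding_cache(cache_dir, provider$tag, new_rows, provider$d)
  }
  embedding_matrix(vecs, items$item_id, provider_tag = provider$tag)
}

cache_path <- function(cache_dir, tag) {
  file.path(cache_dir, paste0(gsub("[^A-Za-z0-9._-]", "_", tag), ".cache.csv"))
}

read_embedding_cache <- function(cache_dir, tag) {
  env <- new.env(parent = emptyenv())
  f <- cache_path(cache_dir, tag)
  if (file.exists(f)) {
    tab <- utils::read.csv(f, check.names = FALSE, colClasses = "character")
    for (i in seq_len(nrow(tab))) {
      env[[tab$text[i]]] <- as.numeric(tab[i, -1])
    }
  }
  env
}

write_embedding_cache <- function(cache_dir, tag, new_rows, d) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  f <- cache_path(cache_dir, tag)
  rows <- vapply(new_rows, function(r) {
    paste(c(encode_csv_field(r$text),
            sprintf("%.17g", unlist(r[-1]))), collapse = ",")
  }, character(1))
  if (!file.exists(f)) {
    header <- paste(c("text", sprintf("V%d", seq_len(d))), collapse = ",")
    writeLines(c(header, rows), f)
  } else {
    cat(rows, file = f, sep = "\n", append = TRUE)
    cat("\n", file = f, append = TRUE)
  }
}

encode_csv_field <- function(x) {
  paste0('"', gsub('"', '""', x), '"')
}

#' Save / load an embedding matrix as text
#'
#' Writes a CSV (`item_id` plus one column per dimension, full 17-digit
#' float precision so the round trip is lossless) and a JSON sidecar at
#' `<path>.json` holding the provider tag, dimension and item ids.
#'
#' @param E an [embedding_matrix()].
#' @param path CSV path.
#' @return `save_embeddings()` returns `path` invisibly; `load_embeddings()`
#'   returns the [embedding_matrix()].
#' @export
save_embeddings <- function(E, path) {
  d <- ncol(E)
  header <- paste(c("item_id", sprintf("V%d", seq_len(d))), collapse = ",")
  rows <- vapply(seq_len(nrow(E)), function(i) {
    paste(c(encode_csv_field(rownames(E)[i]), sprintf("%.17g", E[i, ])),
          collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  jsonlite::write_json(
    list(provider_tag = attr(E, "provider_tag"), d = d,
         item_ids = rownames(E)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_embeddings
#' @param questionnaire optional [questionnaire()]; item ids are checked
#'   against it and an error lists missing/extra ids.
#' @export
load_embeddings <- function(path, questionnaire = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("No such file: %s", path), class = "psychollm_io_error")
  }
  tab <- utils::read.csv(path, check.names = FALSE,
                         colClasses = c(item_id = "character"))
  meta_path <- paste0(path, ".json")
  tag <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path)$provider_tag
  } else {
    "unknown"
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(m) <- NULL
  E <- embedding_matrix(m, tab$item_id, provider_tag = tag)
  if (!is.null(questionnaire)) {
    ids <- item_ids(questionnaire)
    missing <- setdiff(ids, rownames(E))
    extra <- setdiff(rownames(E), ids)
    if (length(missing) || length(extra)) {
      abort(sprintf(
        "Embeddings do not match the questionnaire (missing: %s; extra: %s).",
        paste(missing, collapse = ", ") %|blank|% "none",
        paste(extra, collapse = ", ") %|blank|% "none"),
        class = "psychollm_validation_error")
    }
    E <- E[ids, , drop = FALSE]
    E <- embedding_matrix(E, ids, provider_tag = tag)
  }
  E
}

`%|blank|%` <- function(x, alt) if (nzchar(x)) x else alt
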