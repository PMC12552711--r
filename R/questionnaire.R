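#' Construct a questionnaire
#'
#' A questionnaire is a tibble of items (one row per item) carrying the
#' instrument name and the Likert scale bounds as attributes. Columns:
#' `item_id` (unique, non-empty), `text` (the first-person item statement),
#' and optionally `factor` (subscale label) and `reverse_keyed` (metadata
#' only; scores are never re-keyed — analyses use absolute correlations
#' instead).
#'
#' @param items data frame with columns `item_id`, `text`, and optionally
#'   `factor`, `reverse_keyed`.
#' @param name instrument name.
#' @param scale_min,scale_max integer Likert bounds, `scale_min < scale_max`.
#' @return A `questionnaire` tibble.
#' @examples
#' q <- questionnaire(
#'   data.frame(item_id = c("Q1", "Q2"),
#'              text = c("I worry a lot", "I cannot relax")),
#'   name = "toy", scale_min = 1, scale_max = 4
#' )
#' n_items(q)
#' @export
questionnaire <- function(items, name = "questionnaire",
                          scale_min = 1L, scale_max = 4L) {
  items <- as_tibble(items)
  if (!all(c("item_id", "text") %in% names(items))) {
    abort("`items` must have columns `item_id` and `text`.",
          class = "psychollm_schema_error")
  }
  items$item_id <- as.character(items$item_id)
  items$text <- as.character(items$text)
  if (!"factor" %in% names(items)) items$factor <- NA_character_
  items$factor <- as.character(items$factor)
  if (!"reverse_keyed" %in% names(items)) items$reverse_keyed <- NA
  items$reverse_keyed <- as.logical(items$reverse_keyed)
  items <- items[, c("item_id", "text", "factor", "reverse_keyed")]

  out <- structure(items,
                   q_name = as.character(name)[1],
                   scale_min = as.integer(scale_min),
                   scale_max = as.integer(scale_max),
                   class = c("questionnaire", class(tibble())))
  validate_questionnaire(out)
}

#' Validate a questionnaire object
#'
#' Checks the invariants: at least two items, unique ids, non-empty texts,
#' valid scale bounds, and (when any factor label is present) a complete
#' partition of the items into factors.
#'
#' @param q a [questionnaire()].
#' @return `q`, invisibly unchanged, or an error.
#' @export
validate_questionnaire <- function(q) {
  if (nrow(q) < 2) {
    abort("A questionnaire needs at least 2 items.",
          class = "psychollm_validation_error")
  }
  blank <- !nzchar(trimws(q$text)) | is.na(q$text)
  if (any(blank)) {
    abort(sprintf("Items with empty text: %s.",
                  paste(q$item_id[blank], collapse = ", ")),
          class = "psychollm_schema_error")
  }
  dup <- unique(q$item_id[duplicated(q$item_id)])
  if (length(dup)) {
    abort(sprintf("Duplicate item_id: %s.", paste(dup, collapse = ", ")),
          class = "psychollm_validation_error")
  }
  b <- scale_bounds(q)
  if (anyNA(b) || b[1] >= b[2]) {
    abort("scale_min must be an integer strictly below scale_max.",
          class = "psychollm_validation_error")
  }
  fac <- q$factor
  if (any(!is.na(fac)) && any(is.na(fac))) {
    abort(sprintf(
      "Factor labels must cover all items or none; unlabeled: %s.",
      paste(q$item_id[is.na(fac)], collapse = ", ")),
      class = "psychollm_validation_error")
  }
  invisible(q)
}

#' @export
print.questionnaire <- function(x, ...) {
  b <- scale_bounds(x)
  cat(sprintf("<questionnaire> %s: %d items, Likert %d-%d\n",
              attr(x, "q_name"), nrow(x), b[1], b[2]))
  NextMethod()
}

#' Questionnaire accessors
#'
#' @param q a [questionnaire()].
#' @return `n_items()` the number of items; `item_ids()` the item id vector;
#'   `scale_bounds()` an integer vector `c(scale_min, scale_max)`;
#'   `item_factors()` the factor labels (possibly all `NA`).
#' @export
n_items <- function(q) nrow(q)

#' @rdname n_items
#' @export
item_ids <- function(q) q$item_id

#' @rdname n_items
#' @export
scale_bounds <- function(q) {
  c(attr(q, "scale_min"), attr(q, "scale_max"))
}

#' @rdname n_items
#' @export
item_factors <- function(q) setNames(q$factor, q$item_id)

#' Read a questionnaire definition from JSON or CSV
#'
#' JSON files are self-contained:
#' `{name, scale_min, scale_max, items: [{item_id, text, factor?, reverse_keyed?}]}`.
#' CSV files carry the item table only (columns `item_id`, `text`, and
#' optionally `factor`, `reverse_keyed`); pass `name` and the scale bounds
#' explicitly.
#'
#' @param path file path.
#' @param format `"json"` or `"csv"`; inferred from the extension by default.
#' @param name,scale_min,scale_max used for CSV input (ignored for JSON).
#' @return A [questionnaire()].
#' @export
read_questionnaire <- function(path, format = c("auto", "json", "csv"),
                               name = NULL, scale_min = NULL,
                               scale_max = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    abort(sprintf("No such file: %s", path), class = "psychollm_io_error")
  }
  if (format == "json") {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (f in c("name", "scale_min", "scale_max", "items")) {
      if (is.null(spec[[f]])) {
        abort(sprintf("Questionnaire JSON is missing field `%s`.", f),
              class = "psychollm_schema_error")
      }
    }
    items <- as_tibble(spec$items)
    if (is.null(items$text)) {
      abort("Questionnaire JSON items lack a `text` field.",
            class = "psychollm_schema_error")
    }
    missing_text <- which(is.na(items$text) | !nzchar(trimws(items$text)))
    if (length(missing_text)) {
      abort(sprintf("Missing/empty `text` in item row(s): %s.",
                    paste(missing_text, collapse = ", ")),
            class = "psychollm_schema_error")
    }
    questionnaire(items, name = spec$name,
                  scale_min = spec$scale_min, scale_max = spec$scale_max)
  } else {
    if (is.null(scale_min) || is.null(scale_max)) {
      abort("CSV questionnaires need explicit `scale_min` and `scale_max`.",
            class = "psychollm_schema_error")
    }
    items <- readr::read_csv(path, show_col_types = FALSE,
                             progress = FALSE)
    questionnaire(items,
                  name = name %||% sub("\\.[^.]+$", "", basename(path)),
                  scale_min = scale_min, scale_max = scale_max)
  }
}

#' Write a questionnaire definition
#'
#' The JSON form round-trips all fields including name and scale bounds; the
#' CSV form writes the item table only.
#'
#' @param q a [questionnaire()].
#' @param path output path.
#' @param format `"json"` or `"csv"`; inferred from the extension by default.
#' @return `path`, invisibly.
#' @export
write_questionnaire <- function(q, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  items <- as.data.frame(q)
  if (format == "json") {
    b <- scale_bounds(q)
    jsonlite::write_json(
      list(name = attr(q, "q_name"), scale_min = b[1], scale_max = b[2],
           items = items),
      path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  } else {
    readr::write_csv(items, path, na = "")
  }
  invisible(path)
}

#' Read a respondent-by-item Likert response table
#'
#' Expects a CSV with one row per respondent and one column per item id; an
#' optional leading `respondent_id` column is kept (one is synthesized
#' otherwise). Extra columns (e.g. demographics) are dropped with a warning.
#' Values must be integers within the questionnaire's scale bounds; the
#' `na_token` (empty string by default) marks missing cells. Rows that are
#' missing on every item are dropped with a message.
#'
#' @param path CSV path.
#' @param questionnaire a [questionnaire()] the columns must match.
#' @param na_token string standing for a missing value.
#' @return A tibble: `respondent_id` plus one integer column per item.
#' @export
read_responses <- function(path, questionnaire, na_token = "") {
  if (!file.exists(path)) {
    abort(sprintf("No such file: %s", path), class = "psychollm_io_error")
  }
  raw <- readr::read_csv(path, na = na_token, show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  ids <- item_ids(questionnaire)
  missing_cols <- setdiff(ids, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("Response file lacks item column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "psychollm_schema_error")
  }
  extra <- setdiff(names(raw), c("respondent_id", ids))
  if (length(extra)) {
    warn(sprintf("Ignoring %d non-item column(s): %s.",
                 length(extra), paste(extra, collapse = ", ")))
  }
  rid <- if ("respondent_id" %in% names(raw)) {
    as.character(raw$respondent_id)
  } else {
    sprintf("R%05d", seq_len(nrow(raw)))
  }
  out <- tibble(respondent_id = rid)
  b <- scale_bounds(questionnaire)
  for (id in ids) {
    v <- suppressWarnings(as.numeric(raw[[id]]))
    bad_parse <- which(!is.na(raw[[id]]) & is.na(v))
    bad_value <- which(!is.na(v) & (!is_whole(v) | v < b[1] | v > b[2]))
    bad <- sort(c(bad_parse, bad_value))
    if (length(bad)) {
      i <- bad[1]
      abort(sprintf(
        "Out-of-range or non-integer response at row %d, column %s: \"%s\" (scale %d-%d).",
        i, id, raw[[id]][i], b[1], b[2]),
        class = "psychollm_validation_error")
    }
    out[[id]] <- as.integer(v)
  }
  all_na <- rowSums(!is.na(as.matrix(out[ids]))) == 0
  if (any(all_na)) {
    inform(sprintf("Dropped %d respondent(s) with no observed responses.",
                   sum(all_na)))
    out <- out[!all_na, , drop = FALSE]
  }
  out
}

#' Write a response table to CSV
#'
#' @param responses tibble from [read_responses()] or the generators.
#' @param path output path.
#' @param na_token string used for missing cells.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path, na_token = "") {
  readr::write_csv(responses, path, na = na_token)
  invisible(path)
}

# Internal: validated numeric matrix of item scores, complete cases only.
response_scores <- function(responses, questionnaire,
                            complete_only = TRUE) {
  ids <- item_ids(questionnaire)
  missing_cols <- setdiff(ids, names(responses))
  if (length(missing_cols)) {
    abort(sprintf("Responses lack item column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "psychollm_schema_error")
  }
  X <- as.matrix(as.data.frame(responses[ids]))
  storage.mode(X) <- "double"
  rn <- if ("respondent_id" %in% names(responses)) {
    as.character(responses$respondent_id)
  } else {
    sprintf("R%05d", seq_len(nrow(X)))
  }
  rownames(X) <- rn
  if (complete_only) {
    keep <- complete.cases(X)
    if (!all(keep)) {
      inform(sprintf("Dropping %d incomplete respondent(s) for this analysis.",
                     sum(!keep)))
    }
    X <- X[keep, , drop = FALSE]
  }
  X
}

#' Subsample respondents without replacement
#'
#' Draws a uniform random subset of rows, reproducibly for a fixed seed.
#' Emulates working at ordinary study sample sizes when the source archive
#' is very large.
#'
#' @param responses response tibble.
#' @param n_sub number of respondents to keep (`<= nrow(responses)`).
#' @param seed integer seed.
#' @return A response tibble with `n_sub` rows, in original relative order.
#' @export
subsample_respondents <- function(responses, n_sub, seed) {
  n <- nrow(responses)
  if (n_sub > n) {
    abort(sprintf("n_sub (%d) exceeds the number of respondents (%d).",
                  n_sub, n),
          class = "psychollm_validation_error")
  }
  idx <- withr::with_seed(as.integer(seed), sort(sample.int(n, n_sub)))
  responses[idx, , drop = FALSE]
}
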