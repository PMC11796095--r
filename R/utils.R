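# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Collapse a character vector into "a, b, c" for messages and templates.
comma <- function(x) paste(x, collapse = ", ")

# Deterministic, locale-independent string sort (C collation).
sort_c <- function(x) {
  if (length(x) == 0L) return(x)
  x[order(x, method = "radix")]
}

# Normalize an entity name for scoring and comparisons: case-fold, trim,
# collapse internal whitespace.
normalize_entity <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Render a scalar value the way result rows are compared and serialized.
render_scalar <- function(v) {
  if (is.null(v) || (length(v) == 1L && is.na(v))) return("")
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.numeric(v)) return(format(v, scientific = FALSE, trim = TRUE))
  as.character(v)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}

# Stable JSON for traces and fixtures: unboxed scalars, full precision.
to_stable_json <- function(x, pretty = FALSE) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null", pretty = pretty)
}
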