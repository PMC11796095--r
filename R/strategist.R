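#' Generate candidate strategies for a question
#'
#' Asks the backend for `k` independent, numbered step-by-step plans (default
#' 3), each grounded in the serialized graph schema. A completion that cannot
#' be parsed as a numbered list triggers one regeneration for that slot
#' before a `strategy_parse_error` is raised carrying the raw text.
#'
#' @param question question string.
#' @param schema a [graph_schema()].
#' @param backend an LLM backend.
#' @param k number of candidates (>= 1).
#' @param params sampling parameters for [llm_complete()].
#' @return List of `strategy` objects (fields `steps`, `raw_text`), length `k`.
#' @export
generate_strategies <- function(question, schema, backend, k = 3L, params = list()) {
  stopifnot(is_string(question), inherits(schema, "graph_schema"), is_count(k, min = 1L))
  lapply(seq_len(k), function(i) {
    prompt <- stage_prompt("strategy", list(
      question = question, schema = format_schema(schema), index = i, k = k
    ))
    completion <- llm_complete(backend, prompt, params)
    s <- parse_strategy(completion$text)
    if (is.null(s)) {
      completion <- llm_complete(backend, prompt, params)   # one regeneration per slot
      s <- parse_strategy(completion$text)
      if (is.null(s)) {
        stop_strategy_parse(
          sprintf("candidate %d is not a numbered step list after one retry", i),
          raw = completion$text
        )
      }
    }
    s
  })
}

# Accepts "1." / "1)" / "Step 1:" numbering dialects, one step per line.
parse_strategy <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  pat <- "^\\s*(?:[Ss]tep\\s+)?([0-9]+)\\s*[.):]\\s*(.+?)\\s*$"
  hits <- regmatches(lines, regexec(pat, lines))
  steps <- vapply(hits, function(h) if (length(h) == 3L) h[[3]] else NA_character_, "")
  steps <- steps[!is.na(steps) & nzchar(steps)]
  if (length(steps) == 0L) return(NULL)
  structure(list(steps = steps, raw_text = text), class = "strategy")
}

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf("strategy (%d steps)\n", length(x$steps)))
  for (i in seq_along(x$steps)) cat(sprintf("  %d. %s\n", i, x$steps[[i]]))
  invisible(x)
}

#' Score candidate strategies and select the winner
#'
#' Each candidate is judged by the backend on three criteria — clarity,
#' comprehensiveness and alignment with the graph schema — each an integer
#' in 0..10; the total is their sum. The candidate with the highest total
#' wins; ties break to the lowest index. A judging completion that does not
#' contain three in-range integers is retried once, then raises a
#' `score_parse_error`.
#'
#' @param candidates nonempty list of strategies from [generate_strategies()].
#' @param question the question being answered (shown to the judge).
#' @param schema a [graph_schema()].
#' @param backend an LLM backend.
#' @param params sampling parameters.
#' @return A `strategy_set`: list with `candidates` (list of
#'   `list(strategy, score)`) and `selected_index`.
#' @export
score_and_select <- function(candidates, question, schema, backend, params = list()) {
  stopifnot(length(candidates) >= 1L)
  scored <- lapply(seq_along(candidates), function(i) {
    s <- candidates[[i]]
    prompt <- stage_prompt("judge", list(
      question = question, schema = format_schema(schema),
      strategy = paste(sprintf("%d. %s", seq_along(s$steps), s$steps), collapse = "\n")
    ))
    sc <- parse_score(llm_complete(backend, prompt, params)$text)
    if (is.null(sc)) {
      raw <- llm_complete(backend, prompt, params)$text
      sc <- parse_score(raw)
      if (is.null(sc)) {
        stop_score_parse(
          sprintf("judge reply for candidate %d is not three integers in 0..10", i),
          raw = raw
        )
      }
    }
    list(strategy = s, score = sc)
  })
  totals <- vapply(scored, function(x) x$score$total, numeric(1))
  structure(
    list(candidates = scored, selected_index = which.max(totals)),  # first max wins ties
    class = "strategy_set"
  )
}

parse_score <- function(text) {
  m <- gregexpr("[0-9]+", text)[[1]]
  if (identical(m[1], -1L) || length(m) < 3L) return(NULL)
  vals <- as.integer(regmatches(text, gregexpr("[0-9]+", text))[[1]][1:3])
  if (any(vals < 0L | vals > 10L)) return(NULL)
  list(clarity = vals[[1]], comprehensiveness = vals[[2]],
       schema_alignment = vals[[3]], total = sum(vals))
}

#' @export
print.strategy_set <- function(x, ...) {
  for (i in seq_along(x$candidates)) {
    sc <- x$candidates[[i]]$score
    marker <- if (i == x$selected_index) "*" else " "
    cat(sprintf("%s candidate %d: total %d (clarity %d, comprehensiveness %d, schema %d)\n",
                marker, i, sc$total, sc$clarity, sc$comprehensiveness, sc$schema_alignment))
  }
  invisible(x)
}

#' Selected strategy of a strategy set
#' @param x a `strategy_set`.
#' @return The winning `strategy`.
#' @export
selected_strategy <- function(x) {
  stopifnot(inherits(x, "strategy_set"))
  x$candidates[[x$selected_index]]$strategy
}
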