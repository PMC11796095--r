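#' Generate executable code for each strategy step
#'
#' One backend call per step asks for an R snippet together with its output
#' manifest (`OUTPUTS:`) and the step numbers it depends on (`DEPENDS:`). A
#' reply with no fenced code block or no valid manifest is regenerated once,
#' then raises a `codegen_error` carrying the raw completion. Steps whose code
#' calls `knowledge_extract` become `knowledge` nodes, the rest `compute`
#' nodes, and a synthesis node of kind `output` is appended mechanically: it
#' binds `final_result` to the last step's primary output variable.
#'
#' @param strategy a `strategy`.
#' @param question the question being answered.
#' @param schema a [graph_schema()].
#' @param backend an LLM backend.
#' @param params sampling parameters.
#' @return List with `nodes` (list of [got_node()]) and `edges` (id pairs):
#'   the linear step order plus every declared dependency, plus edges from
#'   all sink steps into the output node.
#' @export
strategy_to_code <- function(strategy, question, schema, backend, params = list()) {
  stopifnot(inherits(strategy, "strategy"))
  steps <- strategy$steps
  strategy_text <- paste(sprintf("%d. %s", seq_along(steps), steps), collapse = "\n")
  nodes <- list()
  deps <- list()
  available <- character()
  for (i in seq_along(steps)) {
    prompt <- stage_prompt("codegen", list(
      question = question, schema = format_schema(schema),
      strategy = strategy_text, index = i, step = steps[[i]],
      available = if (length(available)) comma(available) else "(none)"
    ))
    parsed <- parse_codegen(llm_complete(backend, prompt, params)$text)
    if (is.null(parsed)) {
      raw <- llm_complete(backend, prompt, params)$text   # one regeneration
      parsed <- parse_codegen(raw)
      if (is.null(parsed)) {
        stop_codegen(sprintf(
          "no usable code block/manifest for step %d after one retry", i
        ), raw = raw)
      }
    }
    kind <- if (grepl("knowledge_extract", parsed$code, fixed = TRUE)) "knowledge" else "compute"
    nodes[[i]] <- got_node(
      id = sprintf("step%d", i), kind = kind, code = parsed$code,
      step_text = steps[[i]], outputs = parsed$outputs
    )
    deps[[i]] <- parsed$depends
    available <- unique(c(available, parsed$outputs))
  }
  n <- length(steps)
  final_var <- nodes[[n]]$outputs[[1L]]
  nodes[[n + 1L]] <- got_node(
    id = "output", kind = "output",
    code = sprintf("final_result <- %s", final_var),
    step_text = "Synthesize the final answer.", outputs = "final_result"
  )
  edges <- list()
  for (i in seq_len(n - 1L)) {
    edges[[length(edges) + 1L]] <- c(from = sprintf("step%d", i),
                                     to = sprintf("step%d", i + 1L))
  }
  for (i in seq_len(n)) {
    for (d in deps[[i]]) {
      edges[[length(edges) + 1L]] <- c(from = sprintf("step%d", d),
                                       to = sprintf("step%d", i))
    }
  }
  # every step with no outgoing edge feeds the synthesis node
  froms <- vapply(edges, `[[`, "", "from")
  for (i in seq_len(n)) {
    if (!(sprintf("step%d", i) %in% froms)) {
      edges[[length(edges) + 1L]] <- c(from = sprintf("step%d", i), to = "output")
    }
  }
  list(nodes = nodes, edges = unique(edges))
}

# Expected reply layout:
#   OUTPUTS: var1, var2
#   DEPENDS: 1, 3        (or "none")
#   ```r
#   <code>
#   ```
parse_codegen <- function(text) {
  code <- extract_code_block(text)
  if (is.null(code)) return(NULL)
  out_m <- regmatches(text, regexpr("(?m)^\\s*OUTPUTS:\\s*(.*)$", text, perl = TRUE))
  if (length(out_m) == 0L) return(NULL)
  outputs <- trimws(strsplit(sub("^\\s*OUTPUTS:\\s*", "", out_m[[1]]), ",")[[1]])
  outputs <- outputs[nzchar(outputs)]
  if (length(outputs) == 0L ||
      !all(grepl("^[A-Za-z.][A-Za-z0-9._]*$", outputs))) {
    return(NULL)
  }
  depends <- integer()
  dep_m <- regmatches(text, regexpr("(?m)^\\s*DEPENDS:\\s*(.*)$", text, perl = TRUE))
  if (length(dep_m) > 0L) {
    dep_txt <- sub("^\\s*DEPENDS:\\s*", "", dep_m[[1]])
    depends <- as.integer(regmatches(dep_txt, gregexpr("[0-9]+", dep_txt))[[1]])
  }
  list(code = code, outputs = outputs, depends = depends)
}

#' Compile a strategy into a validated Graph of Thoughts
#'
#' Convenience wrapper: [strategy_to_code()], then [emit_xml()], then
#' [parse_and_validate()]. Build and validation errors propagate so the
#' agent's compile loop can regenerate the strategy.
#'
#' @inheritParams strategy_to_code
#' @return List with `got` (the validated `got_graph`) and `document`
#'   (the `got_document`).
#' @export
compile_strategy <- function(strategy, question, schema, backend, params = list()) {
  gen <- strategy_to_code(strategy, question, schema, backend, params)
  document <- emit_xml(gen$nodes, gen$edges)
  list(got = parse_and_validate(document), document = document)
}
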