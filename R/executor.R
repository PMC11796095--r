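#' Revise a failing node via the backend
#'
#' One turn of the self-debugging loop: the broken code, the captured error
#' and a summary of the variables available to the node are sent to the
#' backend, which must reply with a fenced code block. The bound is enforced
#' here: calling with `attempts_made >= max_debug_attempts` raises a
#' `debug_exhausted_error` immediately (so `max_debug_attempts = 0` never
#' consults the backend at all).
#'
#' @param node the failing [got_node()].
#' @param failure structured failure from [execute_node()].
#' @param backend an LLM backend.
#' @param available character vector of variable names visible to the node.
#' @param attempts_made revisions already tried for this node.
#' @param max_debug_attempts revision bound (default 3).
#' @param params sampling parameters.
#' @return The node with revised code.
#' @export
self_debug <- function(node, failure, backend, available = character(),
                       attempts_made = 0L, max_debug_attempts = 3L,
                       params = list()) {
  if (attempts_made >= max_debug_attempts) {
    stop_debug_exhausted(sprintf(
      "node '%s' still failing after %d debug attempt(s): %s",
      node$id, attempts_made, failure$error_text
    ), attempts = attempts_made)
  }
  prompt <- stage_prompt("debug", list(
    step = node$step_text, code = node$code, error = failure$error_text,
    available = if (length(available)) comma(available) else "(none)"
  ))
  text <- llm_complete(backend, prompt, params)$text
  revised <- extract_code_block(text)
  if (is.null(revised)) revised <- node$code   # unusable reply: retry as-is, bound still ticks
  got_node(id = node$id, kind = node$kind, code = revised,
           step_text = node$step_text, outputs = node$outputs)
}

#' Execute a Graph of Thoughts over a knowledge graph
#'
#' Runs nodes in the stable topological order. Each node's environment is
#' the union of its parents' output manifests (when two parents export the
#' same name, the parent on the later-declared edge wins and the conflict is
#' logged on the trace); knowledge nodes reach the graph only through the
#' injected `knowledge_extract`. A failing node enters the self-debugging
#' loop — execute, capture the error, have the backend revise the code,
#' re-execute — bounded by `max_debug_attempts` revisions, so backend calls
#' per node never exceed `max_debug_attempts` on top of code generation. A
#' node still failing at the bound raises a condition of classes
#' `debug_exhausted_error` and `execution_error`, carrying the partial trace.
#' On success the output node's environment is synthesized into the answer.
#'
#' @param got a validated `got_graph`.
#' @param graph a [property_graph()] (or [cypher_endpoint()]).
#' @param backend an LLM backend (debugging, query repair, prose synthesis).
#' @param question the question being answered (for synthesis).
#' @param index optional [build_index()] result for vector fallback.
#' @param max_debug_attempts per-node revision bound (default 3).
#' @param timeout per-node wall-clock limit in seconds (default 10).
#' @param retrieval_top_k,retrieval_token_budget fallback retrieval policy.
#' @param params sampling parameters.
#' @return An `execution_trace`: per-node records (code as run, debug
#'   attempts, outputs, retrieval provenance), `answer_text`, and
#'   `structured` — the output node's result object, returned verbatim for
#'   scoring without passing through the model.
#' @export
execute_graph <- function(got, graph, backend, question = "",
                          index = NULL, max_debug_attempts = 3L, timeout = 10,
                          retrieval_top_k = 10L, retrieval_token_budget = 1024L,
                          params = list()) {
  stopifnot(inherits(got, "got_graph"))
  order <- attr(got, "topo_order")
  nodes_by_id <- stats::setNames(got$nodes, vapply(got$nodes, `[[`, "", "id"))
  log_env <- new.env(parent = emptyenv())
  knowledge_fn <- make_knowledge_fn(graph, index, backend, log_env,
                                    top_k = retrieval_top_k,
                                    token_budget = retrieval_token_budget)
  node_envs <- list()
  trace_nodes <- list()
  warnings <- character()
  t0 <- Sys.time()

  for (id in order) {
    node <- nodes_by_id[[id]]
    ctx <- list()
    for (e in got$edges) {                     # later-declared edge wins conflicts
      if (e[["to"]] != id) next
      parent_out <- node_envs[[e[["from"]]]]
      clash <- intersect(names(ctx), names(parent_out))
      if (length(clash) > 0L) {
        msg <- sprintf("node '%s': variable(s) %s redefined by parent '%s'",
                       id, comma(clash), e[["from"]])
        warnings <- c(warnings, msg)
        warning(msg, call. = FALSE)
      }
      ctx[names(parent_out)] <- parent_out
    }
    log_env$retrievals <- list()
    attempts <- list()
    attempts_made <- 0L
    res <- execute_node(node, ctx, knowledge_fn, timeout)
    while (!res$ok) {
      if (attempts_made >= max_debug_attempts) {
        trace_nodes[[id]] <- node_trace_record(node, attempts, NULL,
                                               log_env$retrievals, "failed")
        partial <- execution_trace(question, trace_nodes, got, NULL, NULL,
                                   warnings, t0)
        stop(structure(
          class = c("debug_exhausted_error", "execution_error",
                    "gotqa_error", "error", "condition"),
          list(message = sprintf(
                 "node '%s' still failing after %d debug attempt(s): %s",
                 id, attempts_made, res$failure$error_text),
               call = NULL, attempts = attempts_made, trace = partial)
        ))
      }
      node <- self_debug(node, res$failure, backend,
                         available = names(ctx),
                         attempts_made = attempts_made,
                         max_debug_attempts = max_debug_attempts,
                         params = params)
      attempts_made <- attempts_made + 1L
      res <- execute_node(node, ctx, knowledge_fn, timeout)
      attempts[[attempts_made]] <- list(
        attempt_index = attempts_made,
        error_text = if (res$ok) NA_character_ else res$failure$error_text,
        revised_code = node$code,
        outcome = if (res$ok) "success" else "failure"
      )
      if (!res$ok) attempts[[attempts_made]]$error_text <-
        res$failure$error_text
    }
    node_envs[[id]] <- res$outputs
    trace_nodes[[id]] <- node_trace_record(node, attempts, res$outputs,
                                           log_env$retrievals, "succeeded")
  }

  out_id <- order[[length(order)]]
  # the output node is last in any linear extension (everything reaches it)
  final_env <- node_envs[[out_id]]
  syn <- synthesize_answer(final_env, question, backend, params)
  execution_trace(question, trace_nodes, got, syn$answer_text, syn$structured,
                  warnings, t0)
}

node_trace_record <- function(node, attempts, outputs, retrievals, status) {
  list(id = node$id, kind = node$kind, code = node$code,
       step_text = node$step_text,
       debug_attempts = attempts,
       outputs = outputs,
       retrievals = retrievals,
       status = status)
}

execution_trace <- function(question, trace_nodes, got, answer_text,
                            structured, warnings, t0) {
  structure(
    list(question = question,
         nodes = trace_nodes,
         order = attr(got, "topo_order"),
         answer_text = answer_text,
         structured = structured,
         warnings = warnings),
    class = "execution_trace",
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
}

#' Synthesize the final answer from the output node's environment
#'
#' The structured result (`final_result` in the environment) is returned
#' verbatim — it never passes through the model, so what gets scored is
#' byte-for-byte what node code computed. The prose rendering is produced by
#' the backend from the question plus a rendering of the environment; an
#' empty result set short-circuits to a fixed "no results" sentence.
#'
#' @param final_env named list: the output node's variables.
#' @param question the question being answered.
#' @param backend an LLM backend.
#' @param params sampling parameters.
#' @return List with `answer_text` and `structured`.
#' @export
synthesize_answer <- function(final_env, question, backend, params = list()) {
  structured <- final_env$final_result %||% final_env[[length(final_env)]]
  if (length(structured) == 0L) {
    return(list(answer_text = "No matching results were found.",
                structured = structured))
  }
  rendering <- paste(vapply(names(final_env), function(nm) {
    v <- final_env[[nm]]
    sprintf("%s = %s", nm,
            if (is.data.frame(v)) paste(utils::capture.output(print(v)), collapse = "\n")
            else comma(vapply(v, render_scalar, "")))
  }, ""), collapse = "\n")
  prompt <- stage_prompt("synthesize", list(question = question, results = rendering))
  answer_text <- llm_complete(backend, prompt, params)$text
  list(answer_text = answer_text, structured = structured)
}

#' @export
print.execution_trace <- function(x, ...) {
  cat(sprintf("execution_trace: %d node(s), %s\n", length(x$nodes),
              if (is.null(x$answer_text)) "failed" else "answered"))
  for (n in x$nodes) {
    cat(sprintf("  [%s] %s: %s (%d debug attempt(s))\n",
                n$kind, n$id, n$status, length(n$debug_attempts)))
  }
  if (!is.null(x$answer_text)) cat("  answer: ", x$answer_text, "\n", sep = "")
  invisible(x)
}

#' Canonical JSON serialization of a trace
#'
#' The replayable record of a run: prompts aside, everything needed to audit
#' it — per-node code as run, debug attempts, outputs, retrieval provenance,
#' the structured answer and the prose answer. Wall-clock timing lives on
#' the live object (attribute `"elapsed"`) but is deliberately excluded
#' here, so identical-seed runs serialize byte-identically.
#'
#' @param trace an `execution_trace`.
#' @return A JSON string.
#' @export
trace_json <- function(trace) {
  stopifnot(inherits(trace, "execution_trace"))
  payload <- unclass(trace)
  attr(payload, "elapsed") <- NULL
  as.character(to_stable_json(payload, pretty = TRUE))
}

#' Persist a trace (canonical JSON) to a file
#' @param trace an `execution_trace`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
trace_write <- function(trace, path) {
  writeLines(trace_json(trace), path)
  invisible(path)
}
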