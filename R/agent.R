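#' Agent configuration
#'
#' Bounds and policy for one agent run, validated at construction: `k`
#' candidate strategies (default 3), `compile_attempts` full
#' strategy-to-XML attempts (default 3; 0 means the compile stage errors
#' immediately), `max_debug_attempts` per-node code revisions (default 3),
#' `timeout` seconds of wall clock per node (default 10), retrieval policy
#' (`top_k` fallback passages, per-passage `token_budget`), sampling
#' `temperature` (default 0 — every pipeline stage wants mode-seeking,
#' reproducible text), a `seed` governing any stochastic choice under
#' scripted backends, and an optional `trace_dir` where each run's XML
#' document and canonical trace JSON are persisted.
#'
#' @param k strategy fan-out, >= 1.
#' @param compile_attempts strategy/XML compile bound, >= 0.
#' @param max_debug_attempts per-node self-debug bound, >= 0.
#' @param timeout per-node wall-clock seconds, > 0.
#' @param retrieval list with `top_k` and `token_budget`.
#' @param temperature sampling temperature.
#' @param max_prompt_chars prompt-length budget checked before transport.
#' @param seed integer seed.
#' @param trace_dir directory for persisted traces, or `NULL`.
#' @return An `agent_config`.
#' @export
agent_config <- function(k = 3L, compile_attempts = 3L, max_debug_attempts = 3L,
                         timeout = 10, retrieval = list(),
                         temperature = 0, max_prompt_chars = 60000L,
                         seed = 1L, trace_dir = NULL) {
  retrieval <- utils::modifyList(list(top_k = 10L, token_budget = 1024L), retrieval)
  cfg <- list(k = as.integer(k), compile_attempts = as.integer(compile_attempts),
              max_debug_attempts = as.integer(max_debug_attempts),
              timeout = timeout, retrieval = retrieval,
              temperature = temperature,
              max_prompt_chars = as.integer(max_prompt_chars),
              seed = as.integer(seed), trace_dir = trace_dir)
  if (!is_count(cfg$k, 1L)) stop_config("k must be an integer >= 1")
  for (key in c("compile_attempts", "max_debug_attempts")) {
    if (!is_count(cfg[[key]])) stop_config(sprintf("%s must be an integer >= 0", key))
  }
  if (!is.numeric(cfg$timeout) || cfg$timeout <= 0) stop_config("timeout must be > 0")
  if (!is_count(cfg$retrieval$top_k, 1L)) stop_config("retrieval top_k must be >= 1")
  if (!is_count(cfg$retrieval$token_budget, 1L)) stop_config("retrieval token_budget must be >= 1")
  structure(cfg, class = "agent_config")
}

#' Load an agent configuration from YAML
#'
#' Keys mirror the [agent_config()] arguments; unknown keys raise a
#' `config_error` so typos never silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return An `agent_config`.
#' @export
config_read <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("no such config file: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(agent_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop_config(sprintf("unknown config key(s): %s", comma(unknown)))
  }
  do.call(agent_config, raw)
}

#' @export
print.agent_config <- function(x, ...) {
  cat(sprintf(
    "agent_config: k=%d, compile_attempts=%d, max_debug_attempts=%d, timeout=%gs, top_k=%d, seed=%d\n",
    x$k, x$compile_attempts, x$max_debug_attempts, x$timeout,
    x$retrieval$top_k, x$seed))
  invisible(x)
}

#' Answer a question over a knowledge graph
#'
#' The full pipeline in the stage order of the architecture: generate `k`
#' candidate strategies, judge and select one, generate per-step code,
#' assemble and compile the GoT XML (a compile or validation failure sends
#' the loop back to strategy generation, at most `compile_attempts` times),
#' execute the graph with self-debugging, and synthesize the answer. The
#' structured answer is what node code computed, returned verbatim for
#' scoring; the prose answer is the backend's rendering of it. Stage entry
#' order is recorded on the result, and when `config$trace_dir` is set the
#' XML document and canonical trace JSON are persisted there.
#'
#' @param question nonempty question string (checked before any backend
#'   call; an empty one raises an `input_error`).
#' @param graph a [property_graph()].
#' @param backend an LLM backend.
#' @param config an [agent_config()].
#' @param index optional [build_index()] result for vector fallback.
#' @return An `agent_answer`: list with `answer_text`, `structured`,
#'   `trace`, `strategies` (the scored `strategy_set`), `document` (GoT
#'   XML) and `stages` (entry order).
#' @export
answer_question <- function(question, graph, backend, config = agent_config(),
                            index = NULL) {
  if (!is_string(question) || !nzchar(trimws(question))) {
    stop_input("question must be a nonempty string")
  }
  stopifnot(inherits(config, "agent_config"))
  schema <- graph_schema(graph)
  params <- list(temperature = config$temperature,
                 max_prompt_chars = config$max_prompt_chars)
  stages <- character()
  enter <- function(stage) stages <<- c(stages, stage)

  withr::with_seed(config$seed, {
    compiled <- NULL
    strategy_set <- NULL
    last_error <- NULL
    attempt <- 0L
    while (is.null(compiled) && attempt < config$compile_attempts) {
      attempt <- attempt + 1L
      enter("strategy_generation")
      candidates <- generate_strategies(question, schema, backend,
                                        k = config$k, params = params)
      enter("strategy_scoring")
      strategy_set <- score_and_select(candidates, question, schema, backend, params)
      enter("code_generation")
      enter("xml_compilation")
      compiled <- tryCatch(
        compile_strategy(selected_strategy(strategy_set), question, schema,
                         backend, params),
        graph_build_error = function(e) { last_error <<- e; NULL },
        graph_validation_error = function(e) { last_error <<- e; NULL },
        xml_parse_error = function(e) { last_error <<- e; NULL },
        codegen_error = function(e) { last_error <<- e; NULL }
      )
    }
    if (is.null(compiled)) {
      stop_compile(sprintf(
        "no valid Graph of Thoughts after %d compile attempt(s)%s", attempt,
        if (is.null(last_error)) "" else paste0(": ", conditionMessage(last_error))
      ), attempts = attempt)
    }
    enter("got_execution")
    trace <- execute_graph(
      compiled$got, graph, backend, question = question, index = index,
      max_debug_attempts = config$max_debug_attempts, timeout = config$timeout,
      retrieval_top_k = config$retrieval$top_k,
      retrieval_token_budget = config$retrieval$token_budget, params = params
    )
    enter("answer_synthesis")
    ans <- structure(
      list(answer_text = trace$answer_text, structured = trace$structured,
           trace = trace, strategies = strategy_set,
           document = compiled$document, stages = stages),
      class = "agent_answer"
    )
    if (!is.null(config$trace_dir)) persist_run(ans, config$trace_dir)
    ans
  })
}

persist_run <- function(ans, trace_dir) {
  dir.create(trace_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- format(length(list.files(trace_dir)) + 1L)
  trace_write(ans$trace, file.path(trace_dir, sprintf("run-%s-trace.json", stamp)))
  writeLines(ans$document$xml_text,
             file.path(trace_dir, sprintf("run-%s-got.xml", stamp)))
  invisible(ans)
}

#' @export
print.agent_answer <- function(x, ...) {
  cat("agent_answer\n")
  cat("  structured: ",
      if (is.logical(x$structured)) render_scalar(x$structured)
      else comma(as.character(x$structured)), "\n", sep = "")
  cat("  answer: ", x$answer_text, "\n", sep = "")
  invisible(x)
}
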