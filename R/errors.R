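# Structured condition classes used across the pipeline. Every error the
# package raises deliberately carries a subclass of "gotqa_error" so callers
# (and the agent loop) can dispatch on failure kind rather than message text.

gotqa_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "gotqa_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' @export
print.gotqa_error <- function(x, ...) {
  cat("<", class(x)[[1L]], "> ", conditionMessage(x), "\n", sep = "")
  invisible(x)
}

# Condition raisers, one per spec'd failure mode.
stop_query_syntax <- function(message, position = NA_integer_) {
  gotqa_abort(message, "query_syntax_error", position = position)
}
stop_graph_format <- function(message, record = NULL) {
  gotqa_abort(message, "graph_format_error", record = record)
}
stop_backend <- function(message) gotqa_abort(message, "backend_error")
stop_script_gap <- function(message) gotqa_abort(message, "script_gap_error")
stop_prompt_too_long <- function(message) gotqa_abort(message, "prompt_too_long_error")
stop_strategy_parse <- function(message, raw = NULL) {
  gotqa_abort(message, "strategy_parse_error", raw = raw)
}
stop_score_parse <- function(message, raw = NULL) {
  gotqa_abort(message, "score_parse_error", raw = raw)
}
stop_codegen <- function(message, raw = NULL) gotqa_abort(message, "codegen_error", raw = raw)
stop_graph_build <- function(message) gotqa_abort(message, "graph_build_error")
stop_xml_parse <- function(message) gotqa_abort(message, "xml_parse_error")
stop_graph_validation <- function(message) gotqa_abort(message, "graph_validation_error")
stop_execution <- function(message, trace = NULL) {
  gotqa_abort(message, "execution_error", trace = trace)
}
stop_debug_exhausted <- function(message, attempts = NULL) {
  gotqa_abort(message, "debug_exhausted_error", attempts = attempts)
}
stop_retrieval <- function(message) gotqa_abort(message, "retrieval_error")
stop_scoring <- function(message) gotqa_abort(message, "scoring_error")
stop_config <- function(message) gotqa_abort(message, "config_error")
stop_input <- function(message) gotqa_abort(message, "input_error")
stop_compile <- function(message, attempts = NULL) {
  gotqa_abort(message, "compile_error", attempts = attempts)
}
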