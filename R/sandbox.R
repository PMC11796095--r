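# Restricted evaluation environment for LLM-generated node code. Allow-list
# of pure-computation builtins only: no import mechanism, no file system, no
# network, no process control, no eval/parse. Anything off the list fails at
# lookup ("could not find function"), which execute_node reports as a sandbox
# violation. knowledge_extract is the single injected side-channel.

SANDBOX_ALLOWED <- c(
  # language primitives and operators
  "+", "-", "*", "/", "^", "%%", "%/%", "==", "!=", "<", "<=", ">", ">=",
  "!", "&", "&&", "|", "||", "(", "{", "[", "[[", "$", "@",
  "<-", "=", "[<-", "[[<-", "$<-", "if", "for", "while", "repeat",
  "break", "next", "function", "return", "invisible", "%in%",
  # construction and coercion
  "c", "list", "vector", "numeric", "character", "logical", "integer",
  "as.character", "as.numeric", "as.integer", "as.logical", "as.list",
  "as.vector", "as.data.frame", "data.frame", "matrix", "array",
  # structure
  "length", "names", "names<-", "unlist", "unname", "rev", "unique",
  "sort", "order", "rank", "duplicated", "nrow", "ncol", "dim",
  "head", "tail", "rbind", "cbind", "colnames", "rownames", "t",
  "setdiff", "intersect", "union", "match", "which", "which.min",
  "which.max", "seq", "seq_len", "seq_along", "rep", "append",
  # math and aggregation
  "sum", "mean", "median", "min", "max", "range", "abs", "round",
  "floor", "ceiling", "signif", "sqrt", "exp", "log", "log2", "log10",
  "prod", "cumsum", "tabulate", "table",
  # predicates
  "any", "all", "isTRUE", "isFALSE", "is.null", "is.na", "is.character",
  "is.numeric", "is.logical", "is.list", "is.function", "is.data.frame",
  "identical", "ifelse", "xor",
  # strings
  "paste", "paste0", "sprintf", "format", "toupper", "tolower", "trimws",
  "nchar", "substr", "substring", "strsplit", "grepl", "grep", "regmatches",
  "regexpr", "gregexpr", "sub", "gsub", "startsWith", "endsWith",
  # functional
  "sapply", "lapply", "vapply", "mapply", "Map", "Filter", "Reduce",
  "Position", "Find", "do.call", "Negate", "identity",
  # error signalling from within node code
  "stop", "warning", "stopifnot", "tryCatch", "conditionMessage",
  "simpleError", "nargs", "missing", "on.exit",
  # explicit NULL/NA/TRUE/FALSE come in via parsing, not lookup
  "print", "cat", "message"
)

# Fresh sandbox scope: allow-listed bindings, then emptyenv() — the base
# namespace is not on the search path of node code.
sandbox_scope <- function(knowledge_fn = NULL) {
  base_env <- new.env(parent = emptyenv())
  for (nm in SANDBOX_ALLOWED) {
    fn <- if (exists(nm, envir = baseenv(), inherits = FALSE)) {
      get(nm, envir = baseenv())
    } else if (nm %in% c("head", "tail")) {
      getExportedValue("utils", nm)
    } else {
      getExportedValue("stats", nm)
    }
    assign(nm, fn, envir = base_env)
  }
  if (!is.null(knowledge_fn)) {
    assign("knowledge_extract", knowledge_fn, envir = base_env)
  }
  base_env
}

#' Execute one Graph-of-Thoughts node in the sandbox
#'
#' Evaluates the node's code in a fresh environment containing only the
#' injected context variables, an allow-list of pure-computation builtins
#' and (for knowledge nodes) the `knowledge_extract` helper, under a
#' wall-clock timeout. On success only the variables in the node's declared
#' output manifest are returned. Failures never raise: they come back as a
#' structured record (exception text, offending code, failure kind) ready
#' for the self-debugging loop.
#'
#' @param node a [got_node()].
#' @param ctx named list of variables injected from parent nodes.
#' @param knowledge_fn injected retrieval helper (or `NULL` for pure nodes).
#' @param timeout wall-clock limit in seconds (default 10).
#' @return List with `ok`; on success `outputs` (named list, exactly the
#'   manifest); on failure `failure` (list with `error_text`, `code`,
#'   `kind` one of `"error"`, `"sandbox"`, `"timeout"`).
#' @export
execute_node <- function(node, ctx = list(), knowledge_fn = NULL, timeout = 10) {
  stopifnot(inherits(node, "got_node"))
  scope <- sandbox_scope(knowledge_fn)
  env <- new.env(parent = scope)
  for (nm in names(ctx)) assign(nm, ctx[[nm]], envir = env)

  exprs <- tryCatch(parse(text = node$code), error = function(e) e)
  if (inherits(exprs, "condition")) {
    return(node_failure(node, sprintf("parse error: %s", conditionMessage(exprs)), "error"))
  }
  setTimeLimit(elapsed = timeout, transient = TRUE)
  on.exit(setTimeLimit(cpu = Inf, elapsed = Inf), add = TRUE)
  res <- tryCatch({
    for (ex in exprs) eval(ex, envir = env)
    NULL
  }, error = function(e) e)
  setTimeLimit(cpu = Inf, elapsed = Inf)
  if (inherits(res, "condition")) {
    msg <- conditionMessage(res)
    kind <- if (grepl("reached elapsed time limit", msg)) "timeout"
            else if (grepl("could not find function", msg)) "sandbox"
            else "error"
    return(node_failure(node, msg, kind))
  }
  missing <- node$outputs[!vapply(node$outputs, exists, logical(1),
                                  envir = env, inherits = FALSE)]
  if (length(missing) > 0L) {
    return(node_failure(node, sprintf(
      "declared output variable(s) not produced: %s", comma(missing)
    ), "error"))
  }
  outs <- mget(node$outputs, envir = env, inherits = FALSE)
  list(ok = TRUE, outputs = outs)
}

node_failure <- function(node, error_text, kind) {
  list(ok = FALSE,
       failure = list(error_text = error_text, code = node$code, kind = kind))
}
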