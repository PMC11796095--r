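# Cypher-first, vector-fallback knowledge extraction. The vector path exists
# as a backup for requests the query engine cannot serve; an *empty* Cypher
# result does not trigger it — empty is a valid answer, and silently falling
# back would mask wrong queries.

#' Deterministic hashed term-frequency embedder
#'
#' Maps text to a unit-normalized vector of fixed dimension by hashing
#' lower-cased word tokens into buckets and counting. Identical texts embed
#' identically, with no model or network involved, which is what index and
#' retrieval tests need.
#'
#' @param dim embedding dimension (default 256).
#' @return `function(texts)` returning a `length(texts) x dim` matrix with
#'   unit-norm rows (all-zero rows for token-free text stay zero).
#' @export
hash_embedder <- function(dim = 256L) {
  force(dim)
  function(texts) {
    out <- matrix(0, nrow = length(texts), ncol = dim)
    for (i in seq_along(texts)) {
      tokens <- strsplit(tolower(texts[[i]]), "[^a-z0-9]+")[[1]]
      tokens <- tokens[nzchar(tokens)]
      for (tok in tokens) {
        # polynomial rolling hash over code points, stable across platforms
        h <- 0
        for (cp in utf8ToInt(tok)) h <- (h * 31 + cp) %% 1e9
        bucket <- (h %% dim) + 1L
        out[i, bucket] <- out[i, bucket] + 1
      }
      nrm <- sqrt(sum(out[i, ]^2))
      if (nrm > 0) out[i, ] <- out[i, ] / nrm
    }
    out
  }
}

# Text rendering of graph elements for the index.
describe_node <- function(n) {
  sprintf("%s named %s with properties %s",
          comma(n$labels), n$properties$name,
          paste(names(n$properties), vapply(n$properties, render_scalar, ""),
                sep = "=", collapse = " "))
}
describe_edge <- function(g, e) {
  sprintf("%s %s %s",
          node_property(g, e$start, "name"), gsub("_", " ", tolower(e$type)),
          node_property(g, e$end, "name"))
}

#' Build a vector index over a property graph
#'
#' One record per node and per edge: a text description templated from
#' labels, names and relationship types, embedded with the supplied
#' embedder. Exact search at this scale; no approximate structures.
#'
#' @param graph a [property_graph()].
#' @param embedder embedding function as from [hash_embedder()].
#' @return A `vector_index`: list with `keys`, `descriptions`, `embeddings`
#'   (matrix, one unit-norm row per record).
#' @export
build_index <- function(graph, embedder = hash_embedder()) {
  stopifnot(inherits(graph, "property_graph"))
  keys <- c(
    vapply(graph$nodes, function(n) paste0("node:", n$id), ""),
    vapply(graph$edges, function(e) paste0("edge:", e$id), "")
  )
  descriptions <- c(
    vapply(graph$nodes, describe_node, ""),
    vapply(graph$edges, function(e) describe_edge(graph, e), "")
  )
  emb <- if (length(keys) == 0L) matrix(0, 0, 0) else embedder(descriptions)
  structure(list(keys = keys, descriptions = descriptions, embeddings = emb),
            class = "vector_index")
}

#' @export
print.vector_index <- function(x, ...) {
  cat(sprintf("vector_index: %d records, dimension %d\n",
              length(x$keys), ncol(x$embeddings)))
  invisible(x)
}

#' Rank index records by cosine similarity to a query
#'
#' Exact search: cosine against every record, descending; ties break by key
#' order as stored in the index.
#'
#' @param index a [build_index()] result.
#' @param text query text (embedded with the same embedder family as the
#'   index — pass the embedder used to build it).
#' @param top_k number of records to return (truncated to index size).
#' @param embedder embedding function; must match the index's.
#' @return Data frame with `key`, `description`, `similarity`, best first.
#' @export
vector_search <- function(index, text, top_k = 10L, embedder = hash_embedder()) {
  stopifnot(inherits(index, "vector_index"))
  if (length(index$keys) == 0L) stop_retrieval("vector index is empty")
  q <- embedder(text)[1L, ]
  sims <- as.numeric(index$embeddings %*% q)
  ord <- order(-sims, seq_along(sims))   # ties: key (storage) order
  keep <- utils::head(ord, max(0L, as.integer(top_k)))
  data.frame(
    key = index$keys[keep],
    description = index$descriptions[keep],
    similarity = sims[keep],
    stringsAsFactors = FALSE
  )
}

#' Extract knowledge for one request
#'
#' The single retrieval entry point node code sees. Cypher is always
#' preferred: if the request carries a query that executes, the result rows
#' are returned with `provenance = "cypher"` and the vector index is never
#' touched. A query that fails to parse or execute gets one backend repair
#' attempt (code + error + schema); if the repaired query also fails, or no
#' query was supplied, the request text falls back to [vector_search()]
#' (`provenance = "vector"`, at most `top_k` passages, each truncated to the
#' token budget). Both paths failing raises a `retrieval_error`.
#'
#' @param request list with `text` and/or `cypher` (at least one).
#' @param graph a [property_graph()] or [cypher_endpoint()].
#' @param index a [build_index()] result (may be `NULL` if `cypher` given).
#' @param backend an LLM backend, used only for the single repair attempt
#'   (may be `NULL` to disable repair).
#' @param top_k fallback passage count (default 10).
#' @param token_budget per-passage whitespace-token budget (default 1024).
#' @param embedder embedder matching the index.
#' @return A `retrieval_result`: list with `values` (character vector or
#'   data.frame for cypher; character passages for vector), `provenance`
#'   (`"cypher"` or `"vector"`), `cypher` (the query that ran, if any),
#'   `request`.
#' @export
knowledge_extract <- function(request, graph, index = NULL, backend = NULL,
                              top_k = 10L, token_budget = 1024L,
                              embedder = hash_embedder()) {
  if (is.null(request$text) && is.null(request$cypher)) {
    stop_retrieval("knowledge request needs at least one of text/cypher")
  }
  if (!is.null(request$cypher)) {
    res <- try_cypher(graph, request$cypher)
    if (!inherits(res, "condition")) {
      return(retrieval_result(result_values(res), "cypher", request$cypher, request))
    }
    if (!is.null(backend)) {                       # one repair attempt
      repaired <- repair_cypher(graph, request$cypher, res, backend)
      if (!is.null(repaired)) {
        res2 <- try_cypher(graph, repaired)
        if (!inherits(res2, "condition")) {
          return(retrieval_result(result_values(res2), "cypher", repaired, request))
        }
      }
    }
  }
  if (is.null(request$text) || is.null(index) || length(index$keys) == 0L) {
    stop_retrieval("cypher retrieval failed and no vector fallback is available")
  }
  hits <- vector_search(index, request$text, top_k = top_k, embedder = embedder)
  passages <- vapply(hits$description, truncate_tokens, "", budget = token_budget,
                     USE.NAMES = FALSE)
  retrieval_result(passages, "vector", NULL, request)
}

retrieval_result <- function(values, provenance, cypher, request) {
  structure(list(values = values, provenance = provenance, cypher = cypher,
                 request = request),
            class = "retrieval_result")
}

try_cypher <- function(graph, query) {
  tryCatch(execute_cypher(graph, query), gotqa_error = function(e) e)
}

repair_cypher <- function(graph, query, failure, backend) {
  schema_txt <- if (inherits(graph, "property_graph")) {
    format_schema(graph_schema(graph))
  } else {
    "(external endpoint; schema unavailable)"
  }
  prompt <- stage_prompt("cypher_repair", list(
    schema = schema_txt, cypher = query, error = conditionMessage(failure)
  ))
  out <- tryCatch(llm_complete(backend, prompt)$text, gotqa_error = function(e) NULL)
  if (is.null(out)) return(NULL)
  line <- trimws(gsub("`", "", out))
  line <- strsplit(line, "\n", fixed = TRUE)[[1]]
  line <- line[nzchar(trimws(line))]
  if (length(line) == 0L) NULL else trimws(line[[1]])
}

truncate_tokens <- function(text, budget) {
  toks <- strsplit(text, "[[:space:]]+")[[1]]
  if (length(toks) <= budget) return(text)
  paste(toks[seq_len(budget)], collapse = " ")
}

# The closure the executor injects into node code as knowledge_extract(...).
# Records provenance of every call into `log_env` for the trace.
make_knowledge_fn <- function(graph, index, backend, log_env,
                              top_k = 10L, token_budget = 1024L) {
  function(text = NULL, cypher = NULL) {
    res <- knowledge_extract(list(text = text, cypher = cypher),
                             graph = graph, index = index, backend = backend,
                             top_k = top_k, token_budget = token_budget)
    log_env$retrievals[[length(log_env$retrievals) + 1L]] <- list(
      cypher = res$cypher %||% NA_character_,
      text = text %||% NA_character_,
      provenance = res$provenance,
      n_values = if (is.data.frame(res$values)) nrow(res$values) else length(res$values)
    )
    res$values
  }
}
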