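#' Score a structured answer against an item's ground truth
#'
#' True/false and multiple-choice items score exact-match in `{0, 1}` after
#' entity normalization (case-fold, trim, collapse internal whitespace; no
#' fuzzy matching). Open-ended items score the Jaccard overlap
#' `|A n B| / |A u B|` between the normalized predicted and true entity
#' sets, which penalizes omissions and hallucinated extras symmetrically;
#' two empty sets count as full agreement. The answer type must match the
#' question type or a `scoring_error` is raised.
#'
#' @param item a `qa_item`.
#' @param answer the structured answer: character vector (open), logical
#'   scalar (tf), or single option string (mc).
#' @return A score in `[0, 1]`.
#' @examples
#' it <- structure(list(qtype = "open", truth = c("liver", "kidney")),
#'                 class = "qa_item")
#' score_response(it, c("Liver", "kidney"))   # 1
#' score_response(it, c("liver", "heart"))    # 1/3
#' @export
score_response <- function(item, answer) {
  stopifnot(inherits(item, "qa_item"))
  switch(item$qtype,
    open = {
      if (!is.character(answer) && !is.null(answer)) {
        if (is.factor(answer)) answer <- as.character(answer)
        else stop_scoring("open-ended items need a character entity set")
      }
      pred <- unique(normalize_entity(answer %||% character()))
      pred <- pred[nzchar(pred)]
      truth <- unique(normalize_entity(item$truth))
      truth <- truth[nzchar(truth)]
      if (length(pred) == 0L && length(truth) == 0L) return(1)
      length(intersect(pred, truth)) / length(union(pred, truth))
    },
    tf = {
      if (!is.logical(answer) || length(answer) != 1L || is.na(answer)) {
        stop_scoring("true/false items need a single logical answer")
      }
      as.numeric(identical(answer, item$truth))
    },
    mc = {
      if (!is.character(answer) || length(answer) != 1L) {
        stop_scoring("multiple-choice items need a single option string")
      }
      as.numeric(normalize_entity(answer) == normalize_entity(item$truth))
    },
    stop_scoring(sprintf("unknown question type '%s'", item$qtype))
  )
}

#' Truth-emitting scripted backend for one benchmark item
#'
#' Builds the scripted backend that makes the pipeline's ceiling measurable:
#' at every stage it replies with exactly what a perfect model would — a
#' one-step strategy, top judge scores, code that retrieves the item's own
#' ground-truth Cypher and reduces it to the answer shape, and a minimal
#' synthesis sentence. Running the full agent under this backend isolates
#' the pipeline itself: any score below 1 would be loss introduced by the
#' machinery, not by the model.
#'
#' @param item a `qa_item`.
#' @return A [scripted_backend()].
#' @export
oracle_backend <- function(item) {
  stopifnot(inherits(item, "qa_item"))
  code <- oracle_node_code(item)
  scripted_backend(list(
    list(pattern = "## TASK: strategy generation",
         response = "1. Run the ground-truth retrieval and reduce it to the answer."),
    list(pattern = "## TASK: strategy judging", response = "9 9 9"),
    list(pattern = "## TASK: code generation",
         response = paste0("OUTPUTS: result\nDEPENDS: none\n```r\n", code, "\n```")),
    list(pattern = "## TASK: self-debugging",
         response = paste0("```r\n", code, "\n```")),
    list(pattern = "## TASK: answer synthesis",
         response = "Computed directly from the knowledge graph.")
  ), id = "oracle")
}

oracle_node_code <- function(item) {
  stopifnot(!grepl("'", item$truth_cypher, fixed = TRUE))
  fetch <- sprintf("rows <- knowledge_extract(cypher = '%s')", item$truth_cypher)
  switch(item$qtype,
    open = paste(fetch, "result <- unique(as.character(rows))", sep = "\n"),
    tf = paste(fetch, "result <- length(rows) > 0", sep = "\n"),
    mc = paste(
      fetch,
      sprintf("opts <- c(%s)", paste(sprintf("'%s'", item$options), collapse = ", ")),
      "hit <- opts[opts %in% as.character(rows)]",
      "result <- if (length(hit) > 0) hit[[1]] else opts[[1]]",
      sep = "\n"
    )
  )
}

#' Run the agent over a question set and score it
#'
#' Answers every item with [answer_question()] and scores the structured
#' (not prose) answer with [score_response()]. The backend is built per
#' item by `backend_factory`, defaulting to the truth-emitting
#' [oracle_backend()] — under which the mean score measures pipeline
#' fidelity and should be exactly 1.
#'
#' @param graph a [property_graph()].
#' @param items list of `qa_item` objects.
#' @param config an [agent_config()].
#' @param backend_factory `function(item)` returning an LLM backend.
#' @return A `score_report`: list with `scores` (per item), `mean`, `n`,
#'   and `failures` (indices of items whose run errored; they score 0).
#' @export
benchmark_run <- function(graph, items, config = agent_config(),
                          backend_factory = oracle_backend) {
  scores <- numeric(length(items))
  failures <- integer()
  for (i in seq_along(items)) {
    item <- items[[i]]
    ans <- tryCatch(
      answer_question(item$question, graph, backend_factory(item), config),
      gotqa_error = function(e) e
    )
    if (inherits(ans, "condition")) {
      failures <- c(failures, i)
      scores[[i]] <- 0
    } else {
      scores[[i]] <- score_response(item, ans$structured)
    }
  }
  structure(
    list(scores = scores, mean = if (length(scores)) mean(scores) else NA_real_,
         n = length(items), failures = failures),
    class = "score_report"
  )
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("score_report: n = %d, mean = %.4f, failures = %d\n",
              x$n, x$mean, length(x$failures)))
  invisible(x)
}

#' Plain-text table for a set of score reports
#' @param reports named list of `score_report`s (name = dataset label).
#' @return Character vector of table lines.
#' @export
format_score_table <- function(reports) {
  c(sprintf("%-24s %6s %8s", "dataset", "n", "mean"),
    vapply(names(reports), function(nm) {
      sprintf("%-24s %6d %8.4f", nm, reports[[nm]]$n, reports[[nm]]$mean)
    }, ""))
}
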