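#' Construct a Graph-of-Thoughts node
#'
#' One executable reasoning step: `knowledge` nodes call the injected
#' `knowledge_extract` helper, `compute` nodes do pure computation, and the
#' single `output` node synthesizes the final result. `outputs` is the node's
#' manifest — the only variables forwarded to children.
#'
#' @param id unique node id.
#' @param kind one of `"knowledge"`, `"compute"`, `"output"`.
#' @param code nonempty R code snippet.
#' @param step_text the strategy step this node implements.
#' @param outputs character vector of variable names the node defines.
#' @return A `got_node`.
#' @export
got_node <- function(id, kind, code, step_text = "", outputs = character()) {
  stopifnot(is_string(id), kind %in% c("knowledge", "compute", "output"))
  if (!is_string(code) || !nzchar(trimws(code))) {
    stop_graph_build(sprintf("node '%s' has empty code", id))
  }
  structure(list(id = id, kind = kind, code = code, step_text = step_text,
                 outputs = as.character(outputs)),
            class = "got_node")
}

#' Assemble and validate a Graph of Thoughts
#'
#' Enforces the structural invariants: unique node ids, at least one node,
#' exactly one `output` node, edges referencing declared ids, acyclicity, and
#' the output node reachable from every node. A stable topological execution
#' order (ties broken by document order) is attached as attribute
#' `"topo_order"`.
#'
#' @param nodes list of [got_node()] objects.
#' @param edges list of `c(from, to)` id pairs (or a 2-column matrix).
#' @param error which condition class violations raise: build errors (from
#'   the emitter) or validation errors (from the parser).
#' @return A `got_graph` (list with `nodes`, `edges`).
#' @export
got_graph <- function(nodes, edges = list(), error = c("build", "validation")) {
  error <- match.arg(error)
  fail <- if (error == "build") stop_graph_build else stop_graph_validation
  if (is.matrix(edges)) edges <- lapply(seq_len(nrow(edges)), function(i) edges[i, ])
  edges <- unique(lapply(edges, function(e) c(from = unname(e[[1]]), to = unname(e[[2]]))))
  if (length(nodes) < 1L) fail("a Graph of Thoughts needs at least one node")
  ids <- vapply(nodes, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    fail(sprintf("duplicate node id(s): %s", comma(unique(ids[duplicated(ids)]))))
  }
  kinds <- vapply(nodes, `[[`, "", "kind")
  if (sum(kinds == "output") != 1L) {
    fail(sprintf("exactly one output node required, found %d", sum(kinds == "output")))
  }
  for (e in edges) {
    if (!(e[["from"]] %in% ids) || !(e[["to"]] %in% ids)) {
      fail(sprintf("edge %s -> %s references an undeclared node id", e[["from"]], e[["to"]]))
    }
  }
  order <- topo_order(ids, edges, fail)
  out_id <- ids[kinds == "output"]
  reach <- reaches(ids, edges, out_id)
  if (!all(reach)) {
    fail(sprintf("output node unreachable from node(s): %s", comma(ids[!reach])))
  }
  structure(list(nodes = nodes, edges = edges),
            class = "got_graph", topo_order = order)
}

# Kahn's algorithm; among ready nodes the one earliest in document order runs
# first, so the execution order is a deterministic linear extension.
topo_order <- function(ids, edges, fail) {
  indeg <- stats::setNames(rep(0L, length(ids)), ids)
  for (e in edges) indeg[[e[["to"]]]] <- indeg[[e[["to"]]]] + 1L
  order <- character()
  remaining <- ids
  while (length(remaining) > 0L) {
    ready <- remaining[indeg[remaining] == 0L]
    if (length(ready) == 0L) {
      fail(sprintf("cycle detected among node(s): %s", comma(remaining)))
    }
    nxt <- ready[[1L]]
    order <- c(order, nxt)
    remaining <- setdiff(remaining, nxt)
    for (e in edges) {
      if (e[["from"]] == nxt) indeg[[e[["to"]]]] <- indeg[[e[["to"]]]] - 1L
    }
  }
  order
}

# Which nodes reach `target` following edges forward.
reaches <- function(ids, edges, target) {
  reach <- stats::setNames(ids == target, ids)
  repeat {
    changed <- FALSE
    for (e in edges) {
      if (reach[[e[["to"]]]] && !reach[[e[["from"]]]]) {
        reach[[e[["from"]]]] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  reach
}

got_parents <- function(got, id) {
  vapply(Filter(function(e) e[["to"]] == id, got$edges), `[[`, "", "from")
}

#' @export
print.got_graph <- function(x, ...) {
  cat(sprintf("got_graph: %d nodes, %d edges\n", length(x$nodes), length(x$edges)))
  for (n in x$nodes) {
    cat(sprintf("  [%s] %s -> {%s}\n", n$kind, n$id, comma(n$outputs)))
  }
  invisible(x)
}
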