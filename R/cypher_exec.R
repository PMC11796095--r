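#' Execute a Cypher query against a property graph
#'
#' Evaluates a query in the supported subset (linear `MATCH` patterns of one
#' or two relationships, optional direction, label filters, inline
#' property-equality maps, `WHERE` with `=`, `<>`, `IN` and `AND`, `RETURN`
#' of node names or properties with optional `DISTINCT` and `LIMIT`).
#' Matching follows property-graph semantics: a repeated pattern variable
#' unifies to the same node, and no relationship may be bound twice within a
#' single match. Rows are returned in a stable order (sorted by the string
#' rendering of the row); `DISTINCT` deduplicates before `LIMIT` applies.
#' An unknown label or relationship type matches zero rows; only malformed
#' query text raises a `query_syntax_error` (with a character position).
#'
#' @param endpoint a [property_graph()] for the in-memory engine, or a
#'   [cypher_endpoint()] wrapping an external database.
#' @param query query string.
#' @param ... passed to methods.
#' @return A `result_table`: a list with `columns` (character vector) and
#'   `rows` (data.frame of rendered values, one column per return item).
#' @examples
#' g <- property_graph(
#'   nodes = list(
#'     list(id = "g1", labels = "Gene", properties = list(name = "METTL5")),
#'     list(id = "b1", labels = "BodyPart", properties = list(name = "liver")),
#'     list(id = "b2", labels = "BodyPart", properties = list(name = "kidney"))
#'   ),
#'   edges = list(
#'     list(id = "e1", type = "OVEREXPRESSES", start = "b1", end = "g1"),
#'     list(id = "e2", type = "OVEREXPRESSES", start = "b2", end = "g1")
#'   )
#' )
#' execute_cypher(g,
#'   'MATCH (b:BodyPart)-[:OVEREXPRESSES]->(g:Gene {name: "METTL5"}) RETURN b.name')
#' @export
execute_cypher <- function(endpoint, query, ...) UseMethod("execute_cypher")

#' @export
execute_cypher.property_graph <- function(endpoint, query, ...) {
  ast <- cypher_parse(query)
  bindings <- match_pattern(endpoint, ast)
  project_bindings(endpoint, ast, bindings)
}

#' Wrap an external Cypher endpoint
#'
#' Adapter sharing the [execute_cypher()] signature with the in-memory
#' engine, so the retrieval layer is indifferent to where queries run. The
#' handler receives the query string and must return a `result_table` (or a
#' data.frame, which is converted). The in-memory engine is the default
#' everywhere, so no server is ever required.
#'
#' @param handler `function(query)` forwarding to the external database.
#' @param uri optional connection URI, kept for the record.
#' @return A `cypher_endpoint` object.
#' @export
cypher_endpoint <- function(handler, uri = NULL) {
  stopifnot(is.function(handler))
  structure(list(handler = handler, uri = uri), class = "cypher_endpoint")
}

#' @export
execute_cypher.cypher_endpoint <- function(endpoint, query, ...) {
  out <- endpoint$handler(query)
  if (inherits(out, "result_table")) return(out)
  if (is.data.frame(out)) return(result_table(names(out), out))
  stop_backend("external cypher endpoint returned neither a result_table nor a data.frame")
}

result_table <- function(columns, rows) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (ncol(rows) == 0L && length(columns) > 0L) {
    rows <- as.data.frame(
      stats::setNames(rep(list(character()), length(columns)), columns),
      stringsAsFactors = FALSE
    )
  }
  names(rows) <- columns
  structure(list(columns = columns, rows = rows), class = "result_table")
}

#' @export
print.result_table <- function(x, ...) {
  cat(sprintf("result_table: %d row(s)\n", nrow(x$rows)))
  print(x$rows)
  invisible(x)
}

#' @export
as.data.frame.result_table <- function(x, ...) x$rows

#' Flatten a result table to a value vector
#'
#' Single-column tables become a character vector of that column; wider
#' tables are returned as their data.frame. This is the shape node code sees
#' from knowledge retrieval.
#'
#' @param x a `result_table`.
#' @return Character vector or data.frame.
#' @export
result_values <- function(x) {
  stopifnot(inherits(x, "result_table"))
  if (length(x$columns) == 1L) return(as.character(x$rows[[1L]]))
  x$rows
}

# --- pattern matching ------------------------------------------------------

# Candidate node ids for one node pattern (label + inline property map).
match_node_candidates <- function(g, np) {
  ids <- vapply(g$nodes, `[[`, "", "id")
  keep <- rep(TRUE, length(ids))
  if (!is.na(np$label)) {
    keep <- vapply(g$nodes, function(n) np$label %in% n$labels, logical(1))
  }
  if (length(np$props) > 0L) {
    for (key in names(np$props)) {
      want <- np$props[[key]]
      keep <- keep & vapply(g$nodes, function(n) {
        v <- n$properties[[key]]
        !is.null(v) && scalar_equal(v, want)
      }, logical(1))
    }
  }
  ids[keep]
}

scalar_equal <- function(a, b) {
  if (is.null(a) || is.null(b)) return(FALSE)
  if (length(a) != 1L || length(b) != 1L) return(FALSE)
  if (is.na(a) || is.na(b)) return(FALSE)
  if (is.numeric(a) && is.numeric(b)) return(a == b)
  if (is.logical(a) || is.logical(b)) return(identical(as.logical(a), as.logical(b)))
  identical(as.character(a), as.character(b))
}

# Oriented edge table for one relationship pattern: columns .from/.to/.epos.
oriented_edges <- function(g, rp) {
  et <- attr(g, "edge_table")
  if (!is.na(rp$type)) et <- et[et$type == rp$type, , drop = FALSE]
  fwd <- data.frame(.from = et$start, .to = et$end, .epos = et$pos,
                    stringsAsFactors = FALSE)
  bwd <- data.frame(.from = et$end, .to = et$start, .epos = et$pos,
                    stringsAsFactors = FALSE)
  switch(rp$dir, out = fwd, "in" = bwd, both = rbind(fwd, bwd))
}

# Join-based evaluation: start from the first node pattern's candidates and
# extend one relationship at a time. Binding table columns: one per node
# variable (node id) plus .e1/.e2 (edge positions, for relationship
# uniqueness).
match_pattern <- function(g, ast) {
  first <- ast$nodes[[1L]]
  b <- data.frame(x = match_node_candidates(g, first), stringsAsFactors = FALSE)
  names(b) <- first$var
  for (i in seq_along(ast$rels)) {
    if (nrow(b) == 0L) break
    rp <- ast$rels[[i]]
    np <- ast$nodes[[i + 1L]]
    left_var <- ast$nodes[[i]]$var
    oe <- oriented_edges(g, rp)
    oe <- oe[oe$.to %in% match_node_candidates(g, np), , drop = FALSE]
    b <- merge(b, oe, by.x = left_var, by.y = ".from")
    if (np$var %in% names(b)[names(b) != ".to"]) {
      b <- b[b[[np$var]] == b$.to, , drop = FALSE]    # repeated variable unifies
      b$.to <- NULL
    } else {
      names(b)[names(b) == ".to"] <- np$var
    }
    names(b)[names(b) == ".epos"] <- paste0(".e", i)
  }
  if (all(c(".e1", ".e2") %in% names(b))) {
    b <- b[b$.e1 != b$.e2, , drop = FALSE]            # relationship uniqueness
  }
  b
}

resolve_operand <- function(g, op, row) {
  switch(op$kind,
    lit = op$value,
    name = node_property(g, row[[op$var]], "name"),
    prop = node_property(g, row[[op$var]], op$key)
  )
}

eval_where <- function(g, where, row) {
  for (cond in where) {
    lhs <- resolve_operand(g, cond$lhs, row)
    ok <- switch(cond$op,
      eq = scalar_equal(lhs, resolve_operand(g, cond$rhs, row)),
      neq = {
        rhs <- resolve_operand(g, cond$rhs, row)
        # three-valued logic collapsed: comparisons with a missing value fail
        !is.null(lhs) && !is.null(rhs) && !any(is.na(lhs)) && !any(is.na(rhs)) &&
          !scalar_equal(lhs, rhs)
      },
      "in" = any(vapply(cond$rhs, function(v) scalar_equal(lhs, v), logical(1)))
    )
    if (!isTRUE(ok)) return(FALSE)
  }
  TRUE
}

project_bindings <- function(g, ast, bindings) {
  cols <- vapply(ast$items, `[[`, "", "colname")
  if (nrow(bindings) > 0L && length(ast$where) > 0L) {
    keep <- vapply(seq_len(nrow(bindings)), function(r) {
      eval_where(g, ast$where, as.list(bindings[r, , drop = FALSE]))
    }, logical(1))
    bindings <- bindings[keep, , drop = FALSE]
  }
  out <- lapply(ast$items, function(item) {
    if (nrow(bindings) == 0L) return(character())
    vapply(bindings[[item$var]], function(id) {
      v <- if (is.na(item$key)) node_property(g, id, "name")
           else node_property(g, id, item$key)
      render_scalar(v)
    }, "", USE.NAMES = FALSE)
  })
  df <- as.data.frame(stats::setNames(out, cols), stringsAsFactors = FALSE,
                      check.names = FALSE)
  if (nrow(df) > 0L) {
    key <- do.call(paste, c(unname(as.list(df)), sep = "\x1f"))
    if (ast$distinct) df <- df[!duplicated(key), , drop = FALSE]
    key <- do.call(paste, c(unname(as.list(df)), sep = "\x1f"))
    df <- df[order(key, method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
  }
  if (!is.na(ast$limit)) df <- utils::head(df, ast$limit)
  result_table(cols, df)
}
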