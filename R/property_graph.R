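#' In-memory labeled property graph
#'
#' The factual substrate the agent reasons over: labeled nodes (genes, drugs,
#' diseases, body parts, pathways, ...) joined by typed, directed
#' relationships, each side carrying a scalar property map. Every node must
#' have at least one label and a `name` property; relationship types are
#' normalized to upper case, matching the convention of property-graph
#' databases.
#'
#' @param nodes list of node records, each a list with `id` (string),
#'   `labels` (character vector, nonempty) and `properties` (named list of
#'   scalars containing at least `name`).
#' @param edges list of edge records, each a list with `id`, `type`,
#'   `start`, `end` (node ids) and optional `properties`.
#' @return A `property_graph` object.
#' @examples
#' g <- property_graph(
#'   nodes = list(
#'     list(id = "g1", labels = "Gene", properties = list(name = "METTL5")),
#'     list(id = "b1", labels = "BodyPart", properties = list(name = "liver"))
#'   ),
#'   edges = list(
#'     list(id = "e1", type = "OVEREXPRESSES", start = "b1", end = "g1")
#'   )
#' )
#' graph_schema(g)
#' @export
property_graph <- function(nodes = list(), edges = list()) {
  nodes <- lapply(nodes, normalize_node)
  edges <- lapply(edges, normalize_edge)
  g <- structure(list(nodes = nodes, edges = edges), class = "property_graph")
  validate_property_graph(g)
  build_graph_index(g)
}

normalize_node <- function(n) {
  if (is.null(n$id) || !nzchar(as.character(n$id))) {
    stop_graph_format("node record without an id", record = n)
  }
  labels <- unique(as.character(n$labels %||% character()))
  props <- n$properties %||% list()
  list(id = as.character(n$id), labels = labels, properties = props)
}

normalize_edge <- function(e) {
  if (is.null(e$id) || !nzchar(as.character(e$id))) {
    stop_graph_format("edge record without an id", record = e)
  }
  type <- toupper(as.character(e$type %||% ""))
  list(
    id = as.character(e$id), type = type,
    start = as.character(e$start %||% ""), end = as.character(e$end %||% ""),
    properties = e$properties %||% list()
  )
}

validate_property_graph <- function(g) {
  ids <- vapply(g$nodes, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop_graph_format(sprintf(
      "duplicate node id(s): %s", comma(unique(ids[duplicated(ids)]))
    ))
  }
  for (n in g$nodes) {
    if (length(n$labels) == 0L) {
      stop_graph_format(sprintf("node '%s' has no label", n$id), record = n)
    }
    if (!is_string(n$properties$name %||% NULL)) {
      stop_graph_format(sprintf("node '%s' lacks a 'name' property", n$id), record = n)
    }
  }
  for (e in g$edges) {
    if (!nzchar(e$type)) {
      stop_graph_format(sprintf("edge '%s' has an empty type", e$id), record = e)
    }
    if (!(e$start %in% ids) || !(e$end %in% ids)) {
      stop_graph_format(sprintf(
        "edge '%s' (%s) references a missing node id", e$id, e$type
      ), record = e)
    }
  }
  invisible(g)
}

# Precompute lookup structures the query engine uses: a position index by node
# id and a flat edge table. Stored as attributes so the graph stays a plain,
# serializable list.
build_graph_index <- function(g) {
  ids <- vapply(g$nodes, `[[`, "", "id")
  idx <- seq_along(ids)
  names(idx) <- ids
  attr(g, "node_pos") <- idx
  attr(g, "edge_table") <- if (length(g$edges) == 0L) {
    data.frame(pos = integer(), type = character(), start = character(),
               end = character(), stringsAsFactors = FALSE)
  } else {
    data.frame(
      pos = seq_along(g$edges),
      type = vapply(g$edges, `[[`, "", "type"),
      start = vapply(g$edges, `[[`, "", "start"),
      end = vapply(g$edges, `[[`, "", "end"),
      stringsAsFactors = FALSE
    )
  }
  g
}

node_by_id <- function(g, id) g$nodes[[attr(g, "node_pos")[[id]]]]

node_property <- function(g, id, key) {
  v <- node_by_id(g, id)$properties[[key]]
  if (is.null(v)) NA else v
}

#' @export
print.property_graph <- function(x, ...) {
  labs <- sort_c(unique(unlist(lapply(x$nodes, `[[`, "labels"))))
  types <- sort_c(unique(vapply(x$edges, `[[`, "", "type")))
  cat(sprintf("property_graph: %d nodes, %d edges\n", length(x$nodes), length(x$edges)))
  cat("  labels: ", comma(labs), "\n", sep = "")
  cat("  relationship types: ", comma(types), "\n", sep = "")
  invisible(x)
}

#' Derive the schema of a property graph
#'
#' Scans every edge and records the set of `(start label, relationship type,
#' end label)` signatures, plus the property keys observed per label. The
#' schema is what gets serialized into prompts so generated strategies and
#' queries align with the graph actually loaded.
#'
#' @param graph a [property_graph()].
#' @return A `graph_schema` object with `labels` (named list: label ->
#'   character vector of property keys) and `signatures` (data.frame with
#'   columns `start_label`, `type`, `end_label`).
#' @export
graph_schema <- function(graph) {
  stopifnot(inherits(graph, "property_graph"))
  labels <- list()
  for (n in graph$nodes) {
    for (lab in n$labels) {
      labels[[lab]] <- sort_c(unique(c(labels[[lab]], names(n$properties))))
    }
  }
  sigs <- character()
  for (e in graph$edges) {
    s <- node_by_id(graph, e$start)$labels
    t <- node_by_id(graph, e$end)$labels
    for (sl in s) for (el in t) {
      sigs <- c(sigs, paste(sl, e$type, el, sep = "\x1f"))
    }
  }
  sigs <- sort_c(unique(sigs))
  parts <- strsplit(sigs, "\x1f", fixed = TRUE)
  signatures <- data.frame(
    start_label = vapply(parts, `[[`, "", 1L),
    type = vapply(parts, `[[`, "", 2L),
    end_label = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
  structure(
    list(labels = labels[sort_c(names(labels))], signatures = signatures),
    class = "graph_schema"
  )
}

#' @export
print.graph_schema <- function(x, ...) {
  cat(format_schema(x))
  invisible(x)
}

#' Render a schema as a human-readable prompt block
#'
#' @param schema a [graph_schema()].
#' @return A single string listing node labels with their property keys and
#'   all relationship signatures, in the arrow notation of Cypher patterns.
#' @export
format_schema <- function(schema) {
  stopifnot(inherits(schema, "graph_schema"))
  lines <- c("Node labels:")
  if (length(schema$labels) == 0L) {
    lines <- c(lines, "  (none)")
  } else {
    for (lab in names(schema$labels)) {
      lines <- c(lines, sprintf("  %s {%s}", lab, comma(schema$labels[[lab]])))
    }
  }
  lines <- c(lines, "Relationships:")
  if (nrow(schema$signatures) == 0L) {
    lines <- c(lines, "  (none)")
  } else {
    s <- schema$signatures
    lines <- c(lines, sprintf("  (:%s)-[:%s]->(:%s)", s$start_label, s$type, s$end_label))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Read a property graph from its JSON node/edge-list file
#'
#' The on-disk dialect is one JSON object with a `nodes` array (`id`,
#' `labels`, `properties`) and an `edges` array (`id`, `type`, `start`,
#' `end`, `properties`). It is validated on read: an edge referencing a
#' missing node id, or a node without a label or `name`, raises a
#' `graph_format_error` naming the offending record.
#'
#' @param path file path.
#' @return A [property_graph()].
#' @export
graph_read <- function(path) {
  if (!file.exists(path)) stop_graph_format(sprintf("no such graph file: %s", path))
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop_graph_format(sprintf("not valid JSON: %s", conditionMessage(e)))
  )
  if (!is.list(raw) || is.null(raw$nodes)) {
    stop_graph_format("graph file must be a JSON object with 'nodes' and 'edges' arrays")
  }
  property_graph(nodes = raw$nodes, edges = raw$edges %||% list())
}

#' Write a property graph to the JSON node/edge-list dialect
#'
#' @param graph a [property_graph()].
#' @param path destination file path.
#' @return `path`, invisibly. `graph_read(graph_write(g, p))` is identical to
#'   `g` up to record ordering.
#' @export
graph_write <- function(graph, path) {
  stopifnot(inherits(graph, "property_graph"))
  payload <- list(
    nodes = lapply(graph$nodes, function(n) {
      list(id = n$id, labels = as.list(n$labels), properties = n$properties)
    }),
    edges = lapply(graph$edges, function(e) {
      list(id = e$id, type = e$type, start = e$start, end = e$end,
           properties = e$properties)
    })
  )
  writeLines(to_stable_json(payload, pretty = TRUE), path)
  invisible(path)
}
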