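# The GoT XML dialect: root <GoT> with one <Instruction id=".." kind=".."
# outputs="a,b"> element per node (children <Step> for the originating
# strategy step and <Code> carrying the snippet as CDATA) and one
# <Edge from=".." to=".."/> element per dependency. Minimal, diffable,
# CDATA-safe for arbitrary code.

#' Serialize a Graph of Thoughts to XML
#'
#' Validates the node/edge lists (a violation raises a `graph_build_error`
#' naming the broken rule) and emits the XML document that is the structural
#' backbone of a run: it is persisted with the trace and is what
#' [parse_and_validate()] compiles back into an executable graph.
#'
#' @param nodes list of [got_node()] objects.
#' @param edges list of `c(from, to)` id pairs.
#' @return A `got_document`: list with `xml_text`.
#' @export
emit_xml <- function(nodes, edges = list()) {
  got <- got_graph(nodes, edges, error = "build")
  doc <- xml2::xml_new_root("GoT")
  for (n in got$nodes) {
    inst <- xml2::xml_add_child(doc, "Instruction", id = n$id, kind = n$kind,
                                outputs = comma(n$outputs))
    step <- xml2::xml_add_child(inst, "Step")
    xml2::xml_set_text(step, n$step_text)
    code <- xml2::xml_add_child(inst, "Code")
    xml2::xml_add_child(code, xml2::xml_cdata(n$code))
  }
  for (e in got$edges) {
    xml2::xml_add_child(doc, "Edge", from = e[["from"]], to = e[["to"]])
  }
  structure(list(xml_text = as.character(doc)), class = "got_document")
}

#' Compile a GoT XML document into an executable graph
#'
#' Parses the XML (malformed text raises an `xml_parse_error`) and
#' revalidates every structural invariant — duplicate ids, dangling edges,
#' cycles, missing or multiple output nodes all raise a
#' `graph_validation_error`. Either condition signals the agent loop to
#' return to strategy generation, bounded by `compile_attempts`.
#'
#' @param doc a `got_document` from [emit_xml()], or raw XML text.
#' @return A `got_graph` with its `"topo_order"` attribute set.
#' @export
parse_and_validate <- function(doc) {
  xml_text <- if (inherits(doc, "got_document")) doc$xml_text else doc
  stopifnot(is_string(xml_text))
  xml <- tryCatch(
    xml2::read_xml(xml_text),
    error = function(e) stop_xml_parse(sprintf("malformed XML: %s", conditionMessage(e)))
  )
  if (xml2::xml_name(xml) != "GoT") stop_xml_parse("root element must be <GoT>")
  insts <- xml2::xml_find_all(xml, "./Instruction")
  nodes <- lapply(insts, function(inst) {
    id <- xml2::xml_attr(inst, "id")
    kind <- xml2::xml_attr(inst, "kind")
    if (is.na(id) || is.na(kind)) {
      stop_graph_validation("Instruction element missing id or kind attribute")
    }
    if (!(kind %in% c("knowledge", "compute", "output"))) {
      stop_graph_validation(sprintf("node '%s' has unknown kind '%s'", id, kind))
    }
    outputs_attr <- xml2::xml_attr(inst, "outputs")
    outputs <- if (is.na(outputs_attr) || !nzchar(outputs_attr)) character()
               else trimws(strsplit(outputs_attr, ",", fixed = TRUE)[[1]])
    code <- xml2::xml_text(xml2::xml_find_first(inst, "./Code"))
    if (is.na(code) || !nzchar(trimws(code))) {
      stop_graph_validation(sprintf("node '%s' has empty code", id))
    }
    step <- xml2::xml_text(xml2::xml_find_first(inst, "./Step"))
    got_node(id = id, kind = kind, code = code,
             step_text = if (is.na(step)) "" else step, outputs = outputs)
  })
  edges <- lapply(xml2::xml_find_all(xml, "./Edge"), function(e) {
    from <- xml2::xml_attr(e, "from")
    to <- xml2::xml_attr(e, "to")
    if (is.na(from) || is.na(to)) {
      stop_graph_validation("Edge element missing from or to attribute")
    }
    c(from = from, to = to)
  })
  got_graph(nodes, edges, error = "validation")
}
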