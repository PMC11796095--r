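test_that("the worked-example strategy compiles to two knowledge nodes, one compute node and one output node", {
  g <- worked_example_graph()
  b <- worked_example_backend()
  strategy <- generate_strategies(worked_example_question, graph_schema(g), b, k = 1L)[[1]]
  gen <- strategy_to_code(strategy, worked_example_question, graph_schema(g), b)
  kinds <- vapply(gen$nodes, `[[`, "", "kind")
  expect_identical(kinds, c("knowledge", "knowledge", "compute", "output"))
  edge_keys <- vapply(gen$edges, function(e) paste(e[["from"]], e[["to"]]), "")
  expect_true(all(c("step1 step3", "step2 step3", "step3 output") %in% edge_keys))
  got <- parse_and_validate(emit_xml(gen$nodes, gen$edges))
  expect_s3_class(got, "got_graph")
})

test_that("a one-step strategy yields a knowledge node plus the output node", {
  b <- scripted_backend(list(
    list(pattern = "## TASK: code generation",
         response = "OUTPUTS: result\nDEPENDS: none\n```r\nresult <- knowledge_extract(text = 'x')\n```")
  ))
  s <- structure(list(steps = "Fetch everything.", raw_text = ""), class = "strategy")
  gen <- strategy_to_code(s, "q?", graph_schema(property_graph()), b)
  expect_length(gen$nodes, 2L)
  expect_identical(vapply(gen$nodes, `[[`, "", "kind"), c("knowledge", "output"))
  expect_identical(gen$nodes[[2]]$code, "final_result <- result")
})

test_that("codegen without a fenced block errors after one regeneration", {
  b <- scripted_backend(list(
    list(pattern = "## TASK: code generation",
         response = "OUTPUTS: x\nDEPENDS: none\nhere is code with no fence")
  ))
  s <- structure(list(steps = "step", raw_text = ""), class = "strategy")
  expect_error(strategy_to_code(s, "q?", graph_schema(property_graph()), b),
               class = "codegen_error")
  expect_length(backend_transcript(b), 2L)
})

test_that("XML emission enforces graph invariants by name", {
  n1 <- got_node("a", "compute", "x <- 1", outputs = "x")
  out <- got_node("out", "output", "final_result <- x", outputs = "final_result")
  dup <- got_node("a", "output", "y <- 2", outputs = "y")
  err <- expect_error(emit_xml(list(n1, dup), list()), class = "graph_build_error")
  expect_match(conditionMessage(err), "duplicate|output")
  expect_error(emit_xml(list(n1), list()), class = "graph_build_error")  # no output node
  expect_error(
    emit_xml(list(n1, out), list(c(from = "a", to = "ghost"))),
    class = "graph_build_error"
  )
})

test_that("a minimal single-node graph emits one Instruction element", {
  out <- got_node("out", "output", "final_result <- 1", outputs = "final_result")
  doc <- emit_xml(list(out), list())
  xml <- xml2::read_xml(doc$xml_text)
  expect_length(xml2::xml_find_all(xml, "./Instruction"), 1L)
  expect_identical(xml2::xml_attr(xml2::xml_find_first(xml, "./Instruction"), "kind"),
                   "output")
})

test_that("parse rejects malformed XML, cycles and dangling edges", {
  expect_error(parse_and_validate("<GoT><Instruction id='a'"),
               class = "xml_parse_error")
  expect_error(parse_and_validate("<NotGoT/>"), class = "xml_parse_error")

  cyc <- paste0(
    "<GoT>",
    "<Instruction id='a' kind='compute' outputs='x'><Step/><Code><![CDATA[x <- 1]]></Code></Instruction>",
    "<Instruction id='b' kind='output' outputs='y'><Step/><Code><![CDATA[y <- 2]]></Code></Instruction>",
    "<Edge from='a' to='b'/><Edge from='b' to='a'/>",
    "</GoT>"
  )
  expect_error(parse_and_validate(cyc), class = "graph_validation_error")

  dangling <- paste0(
    "<GoT>",
    "<Instruction id='a' kind='output' outputs='x'><Step/><Code><![CDATA[x <- 1]]></Code></Instruction>",
    "<Edge from='a' to='ghost'/>",
    "</GoT>"
  )
  err <- expect_error(parse_and_validate(dangling), class = "graph_validation_error")
  expect_match(conditionMessage(err), "ghost")

  unreachable <- paste0(
    "<GoT>",
    "<Instruction id='a' kind='compute' outputs='x'><Step/><Code><![CDATA[x <- 1]]></Code></Instruction>",
    "<Instruction id='b' kind='output' outputs='y'><Step/><Code><![CDATA[y <- 2]]></Code></Instruction>",
    "</GoT>"
  )
  expect_error(parse_and_validate(unreachable), class = "graph_validation_error")
})

test_that("emit-then-parse is the identity on random valid DAGs", {
  for (s in 1:60) {
    dag <- random_got_dag(7000 + s)
    got <- parse_and_validate(emit_xml(dag$nodes, dag$edges))
    expect_same_got(got, got_graph(dag$nodes, dag$edges))
  }
})

test_that("the topological order is a linear extension with document-order ties", {
  for (s in 1:20) {
    dag <- random_got_dag(8100 + s)
    got <- got_graph(dag$nodes, dag$edges)
    ord <- attr(got, "topo_order")
    pos <- stats::setNames(seq_along(ord), ord)
    for (e in got$edges) {
      expect_lt(pos[[e[["from"]]]], pos[[e[["to"]]]])
    }
    expect_identical(sort(ord), sort(vapply(got$nodes, `[[`, "", "id")))
  }
})
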