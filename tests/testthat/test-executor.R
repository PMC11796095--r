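silent_backend <- function() scripted_backend(list(
  list(pattern = "## TASK: answer synthesis", response = "done"),
  list(pattern = "## TASK: self-debugging", response = "```r\nbroken <- broken\n```")
))

linear_got <- function(codes, outputs) {
  n <- length(codes)
  nodes <- lapply(seq_len(n), function(i) {
    got_node(sprintf("step%d", i), "compute", codes[[i]], outputs = outputs[[i]])
  })
  nodes[[n + 1L]] <- got_node("output", "output",
                              sprintf("final_result <- %s", outputs[[n]][[1]]),
                              outputs = "final_result")
  edges <- lapply(seq_len(n), function(i) {
    c(from = sprintf("step%d", i),
      to = if (i < n) sprintf("step%d", i + 1L) else "output")
  })
  got_graph(nodes, edges)
}

test_that("a single compute node runs and its outputs reach the trace", {
  got <- linear_got(list("x <- 1 + 1"), list("x"))
  tr <- execute_graph(got, property_graph(), silent_backend(), question = "?")
  expect_identical(tr$nodes$step1$outputs$x, 2)
  expect_identical(tr$structured, 2)
  expect_identical(tr$answer_text, "done")
})

test_that("node environments are the union of parent manifests", {
  got <- linear_got(list("a <- c(1, 2, 3)", "b <- a * 2", "s <- sum(b)"),
                    list("a", "b", "s"))
  tr <- execute_graph(got, property_graph(), silent_backend(), question = "?")
  expect_identical(tr$nodes$step3$outputs$s, 12)
})

test_that("set intersection inside a node matches the builtin oracle", {
  nodes <- list(
    got_node("s1", "compute", "xs <- c('liver','kidney','brain')", outputs = "xs"),
    got_node("s2", "compute", "ys <- c('liver','kidney','heart')", outputs = "ys"),
    got_node("s3", "compute", "common <- sort(intersect(xs, ys))", outputs = "common"),
    got_node("output", "output", "final_result <- common", outputs = "final_result")
  )
  edges <- list(c(from = "s1", to = "s3"), c(from = "s2", to = "s3"),
                c(from = "s3", to = "output"))
  tr <- execute_graph(got_graph(nodes, edges), property_graph(), silent_backend())
  expect_identical(tr$structured,
                   sort(intersect(c("liver", "kidney", "brain"),
                                  c("liver", "kidney", "heart"))))
})

test_that("when two parents export the same name the later-declared edge wins", {
  nodes <- list(
    got_node("s1", "compute", "v <- 'first'", outputs = "v"),
    got_node("s2", "compute", "v <- 'second'", outputs = "v"),
    got_node("s3", "compute", "picked <- v", outputs = "picked"),
    got_node("output", "output", "final_result <- picked", outputs = "final_result")
  )
  edges <- list(c(from = "s1", to = "s3"), c(from = "s2", to = "s3"),
                c(from = "s3", to = "output"))
  expect_warning(
    tr <- execute_graph(got_graph(nodes, edges), property_graph(), silent_backend()),
    "redefined"
  )
  expect_identical(tr$structured, "second")
  expect_match(tr$warnings, "redefined by parent 's2'")
})

test_that("failures come back structured, including error class and offending code", {
  node <- got_node("n", "compute", "y <- not_defined_anywhere + 1", outputs = "y")
  res <- execute_node(node)
  expect_false(res$ok)
  expect_match(res$failure$error_text, "not_defined_anywhere")
  expect_identical(res$failure$code, node$code)
})

test_that("hostile snippets all die in the sandbox without executing", {
  hostile <- c(
    "x <- readLines('/etc/passwd')",
    "x <- file('out.txt', 'w')",
    "x <- system('ls')",
    "x <- system2('ls')",
    "library(utils); x <- 1",
    "x <- utils::read.csv('f.csv')",
    "x <- eval(parse(text = 'Sys.getenv()'))",
    "x <- Sys.getenv('HOME')",
    "x <- url('http://example.com')",
    "x <- download.file('http://example.com', 'f')",
    "x <- get('readLines')(n = 1)",
    "x <- source('script.R')",
    "x <- q()",
    "x <- .Internal(getwd())",
    "x <- new.env(); x <- environment()"
  )
  for (code in hostile) {
    res <- execute_node(got_node("h", "compute", code, outputs = "x"))
    expect_false(res$ok, label = code)
    expect_identical(res$failure$kind, "sandbox", label = code)
  }
})

test_that("runaway node code hits the wall-clock timeout and is debuggable", {
  node <- got_node("slow", "compute", "x <- 0\nwhile (TRUE) x <- x + 1",
                   outputs = "x")
  res <- execute_node(node, timeout = 0.3)
  expect_false(res$ok)
  expect_identical(res$failure$kind, "timeout")
})

test_that("a node not producing its declared manifest is a structured failure", {
  node <- got_node("n", "compute", "something_else <- 1", outputs = "declared")
  res <- execute_node(node)
  expect_false(res$ok)
  expect_match(res$failure$error_text, "declared")
})

test_that("a scripted repair fixes a one-token fault on the first attempt", {
  nodes <- list(
    got_node("s1", "compute", "ys <- c('a','b'); zs <- c('b','c')",
             outputs = c("ys", "zs")),
    got_node("s2", "compute", "x <- intersectoin(ys, zs)", outputs = "x"),
    got_node("output", "output", "final_result <- x", outputs = "final_result")
  )
  edges <- list(c(from = "s1", to = "s2"), c(from = "s2", to = "output"))
  fixer <- scripted_backend(list(
    list(pattern = "## TASK: self-debugging",
         response = "```r\nx <- intersect(ys, zs)\n```"),
    list(pattern = "## TASK: answer synthesis", response = "fixed")
  ))
  tr <- execute_graph(got_graph(nodes, edges), property_graph(), fixer)
  expect_identical(tr$structured, "b")
  attempts <- tr$nodes$s2$debug_attempts
  expect_length(attempts, 1L)
  expect_identical(attempts[[1]]$outcome, "success")
  expect_match(attempts[[1]]$revised_code, "intersect\\(")
})

test_that("an unrepairable fault exhausts the bound with one backend call per revision", {
  nodes <- list(
    got_node("s1", "compute", "x <- stop('unfixable')", outputs = "x"),
    got_node("output", "output", "final_result <- x", outputs = "final_result")
  )
  edges <- list(c(from = "s1", to = "output"))
  b <- scripted_backend(list(
    list(pattern = "## TASK: self-debugging", response = "```r\nx <- stop('unfixable')\n```")
  ))
  err <- expect_error(
    execute_graph(got_graph(nodes, edges), property_graph(), b,
                  max_debug_attempts = 3L),
    class = "debug_exhausted_error"
  )
  expect_s3_class(err, "execution_error")
  expect_identical(err$attempts, 3L)
  expect_length(backend_transcript(b), 3L)      # exactly one call per revision
  expect_length(err$trace$nodes$s1$debug_attempts, 3L)
})

test_that("max_debug_attempts = 0 fails immediately without consulting the backend", {
  b <- scripted_backend(list(list(pattern = ".", response = "never")))
  node <- got_node("n", "compute", "x <- oops()", outputs = "x")
  expect_error(
    self_debug(node, list(error_text = "boom", code = node$code), b,
               attempts_made = 0L, max_debug_attempts = 0L),
    class = "debug_exhausted_error"
  )
  nodes <- list(node, got_node("output", "output", "final_result <- x",
                               outputs = "final_result"))
  expect_error(
    execute_graph(got_graph(nodes, list(c(from = "n", to = "output"))),
                  property_graph(), b, max_debug_attempts = 0L),
    class = "debug_exhausted_error"
  )
  expect_length(backend_transcript(b), 0L)
})

test_that("synthesis quotes only computed values and returns them verbatim", {
  b <- scripted_backend(list(list(
    pattern = "## TASK: answer synthesis",
    response = function(txt) {
      m <- regmatches(txt, regexpr("final_result = [^\n]*", txt))
      paste("The answer is:", sub("final_result = ", "", m))
    }
  )))
  syn <- synthesize_answer(list(final_result = c("liver", "kidney")),
                           "which parts?", b)
  expect_match(syn$answer_text, "liver")
  expect_match(syn$answer_text, "kidney")
  expect_identical(syn$structured, c("liver", "kidney"))

  empty <- synthesize_answer(list(final_result = character()), "which?", b)
  expect_match(empty$answer_text, "No matching results")
  expect_length(empty$structured, 0L)

  boolean <- synthesize_answer(list(final_result = TRUE), "is it?", b)
  expect_identical(boolean$structured, TRUE)
  expect_match(trace_json(structure(
    list(question = "q", nodes = list(), order = character(),
         answer_text = "t", structured = TRUE, warnings = character()),
    class = "execution_trace"
  )), '"structured": true', fixed = TRUE)
})
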