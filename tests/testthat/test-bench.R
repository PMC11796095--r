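test_that("the generator honours sizes, densities and determinism", {
  g <- generate_kg(seed = 1, sizes = c(Gene = 10, Drug = 3, Disease = 3,
                                       BodyPart = 5, Pathway = 2))
  labels <- unlist(lapply(g$nodes, `[[`, "labels"))
  expect_identical(sum(labels == "Gene"), 10L)
  expect_identical(sum(labels == "Pathway"), 2L)

  none <- generate_kg(seed = 1, densities = c(TREATS = 0))
  expect_false(any(vapply(none$edges, `[[`, "", "type") == "TREATS"))

  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  graph_write(generate_kg(seed = 33), p1)
  graph_write(generate_kg(seed = 33), p2)
  expect_identical(readLines(p1), readLines(p2))

  expect_error(generate_kg(seed = 1, densities = c(BINDS = 1.5)),
               class = "config_error")
  expect_error(generate_kg(seed = 1, sizes = c(Gene = 0)),
               class = "config_error")
})

test_that("every generated item's truth_cypher reproduces its traversal truth", {
  g <- generate_kg(seed = 21)
  for (qt in c("open", "tf", "mc")) {
    for (h in 1:2) {
      items <- generate_questions(g, qt, hops = h, n = 15, seed = 8)
      expect_gte(length(items), 10L)
      for (it in items) {
        rows <- result_values(execute_cypher(g, it$truth_cypher))
        if (qt == "open") {
          expect_identical(sort(unique(rows), method = "radix"), it$truth)
        } else if (qt == "tf") {
          expect_identical(length(rows) > 0L, it$truth)
        } else {
          # the option filter reduces the query to exactly the correct option
          expect_identical(rows, it$truth)
          expect_true(it$truth %in% it$options)
          expect_gte(length(it$options), 2L)
          full <- result_values(execute_cypher(
            g, gsub(" WHERE x.name IN \\[[^]]*\\]", "", it$truth_cypher)))
          expect_identical(intersect(it$options, full), it$truth)
        }
      }
    }
  }
})

test_that("2-hop open sets include intersection questions with brute-force truth", {
  g <- generate_kg(seed = 77)
  items <- generate_questions(g, "open", hops = 2, n = 40, seed = 5)
  inter <- Filter(function(it) grepl("the genes .* and ", it$question), items)
  expect_gte(length(inter), 1L)
  it <- inter[[1]]
  genes <- regmatches(it$question,
                      regexec("the genes (\\S+) and (\\S+)\\.", it$question))[[1]][2:3]
  by_gene <- lapply(genes, function(gene) {
    unlist(lapply(seq_along(g$edges), function(i) {
      e <- g$edges[[i]]
      if (e$type == "OVEREXPRESSES" &&
          gotqa:::node_property(g, e$end, "name") == gene) {
        gotqa:::node_property(g, e$start, "name")
      }
    }))
  })
  expect_identical(it$truth,
                   sort(intersect(by_gene[[1]], by_gene[[2]]), method = "radix"))
})

test_that("question generation is deterministic and survives the JSONL round-trip", {
  g <- generate_kg(seed = 3)
  a <- generate_questions(g, "mc", hops = 1, n = 12, seed = 4)
  b <- generate_questions(g, "mc", hops = 1, n = 12, seed = 4)
  expect_identical(a, b)
  path <- withr::local_tempfile(fileext = ".jsonl")
  questions_write(a, path)
  expect_identical(questions_read(path), a)
  tf <- generate_questions(g, "tf", hops = 2, n = 8, seed = 4)
  questions_write(tf, path)
  expect_identical(questions_read(path), tf)
})

test_that("open-ended scoring is normalized Jaccard overlap", {
  it <- structure(list(qtype = "open", truth = c("liver", "kidney")),
                  class = "qa_item")
  expect_identical(score_response(it, c("Liver", " kidney ")), 1)
  expect_identical(score_response(it, c("liver", "heart")), 1 / 3)
  expect_identical(score_response(it, character()), 0)
  expect_identical(score_response(it, c("liver", "kidney", "brain")), 2 / 3)
  empty <- structure(list(qtype = "open", truth = character()), class = "qa_item")
  expect_identical(score_response(empty, character()), 1)
  expect_identical(score_response(empty, "anything"), 0)
  # exhaustive small-universe check: score 1 iff normalized sets are equal
  universe <- c("a", "b", "c")
  subsets <- unlist(lapply(0:3, function(k) combn(universe, k, simplify = FALSE)),
                    recursive = FALSE)
  for (truth in subsets) {
    item <- structure(list(qtype = "open", truth = truth), class = "qa_item")
    for (pred in subsets) {
      s <- score_response(item, pred)
      expect_gte(s, 0); expect_lte(s, 1)
      expect_identical(s == 1, setequal(truth, pred))
    }
  }
})

test_that("tf and mc scoring are exact match in {0,1} with type checking", {
  tf <- structure(list(qtype = "tf", truth = TRUE), class = "qa_item")
  expect_identical(score_response(tf, TRUE), 1)
  expect_identical(score_response(tf, FALSE), 0)
  expect_error(score_response(tf, "true"), class = "scoring_error")
  mc <- structure(list(qtype = "mc", truth = "Liver"), class = "qa_item")
  expect_identical(score_response(mc, "liver"), 1)
  expect_identical(score_response(mc, "heart"), 0)
  expect_error(score_response(mc, c("a", "b")), class = "scoring_error")
  expect_error(score_response(mc, TRUE), class = "scoring_error")
})
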