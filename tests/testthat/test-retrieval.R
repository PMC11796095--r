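test_that("the hashed embedder is deterministic, unit-normalized and fixed-dimension", {
  emb <- hash_embedder(256L)
  e1 <- emb(c("liver overexpresses GENE001", "drug binds gene"))
  e2 <- emb(c("liver overexpresses GENE001", "drug binds gene"))
  expect_identical(e1, e2)
  expect_identical(dim(e1), c(2L, 256L))
  expect_equal(sqrt(rowSums(e1^2)), c(1, 1), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(e1[1, ], e1[2, ])))
})

test_that("the index has one record per node and per edge and is reproducible", {
  g <- generate_kg(seed = 5, sizes = c(Gene = 8, Drug = 4, Disease = 4,
                                       BodyPart = 6, Pathway = 3))
  idx <- build_index(g)
  expect_length(idx$keys, length(g$nodes) + length(g$edges))
  expect_identical(build_index(g), idx)
  empty <- build_index(property_graph())
  expect_length(empty$keys, 0L)
  expect_error(vector_search(empty, "anything"), class = "retrieval_error")
})

test_that("a record's own description ranks first; top_k larger than the index returns it all", {
  g <- worked_example_graph()
  idx <- build_index(g)
  probe <- idx$descriptions[[3]]
  hits <- vector_search(idx, probe, top_k = 3L)
  expect_identical(hits$key[[1]], idx$keys[[3]])
  expect_equal(hits$similarity[[1]], 1, tolerance = 1e-12)
  all_hits <- vector_search(idx, "anything at all", top_k = 1000L)
  expect_identical(nrow(all_hits), length(idx$keys))
})

test_that("ranking equals a brute-force cosine sort on a random index", {
  g <- random_small_kg(909)
  idx <- build_index(g)
  emb <- hash_embedder(256L)
  query <- "genes associated with Alzheimer disease in the hippocampus"
  q <- emb(query)[1L, ]
  sims <- as.numeric(idx$embeddings %*% q)          # cosine: rows are unit norm
  brute <- idx$keys[order(-sims, seq_along(sims))]
  hits <- vector_search(idx, query, top_k = length(idx$keys))
  expect_identical(hits$key, brute)
  expect_equal(hits$similarity, sort(sims, decreasing = TRUE), tolerance = 1e-12)
})

test_that("valid cypher wins, matches the engine, and never touches the vector path", {
  g <- worked_example_graph()
  idx <- build_index(g)
  b <- scripted_backend(list(list(pattern = ".", response = "never called")))
  q <- 'MATCH (b:BodyPart)-[:OVEREXPRESSES]->(g:Gene {name: "METTL5"}) RETURN DISTINCT b.name'
  res <- knowledge_extract(list(text = "body parts for METTL5", cypher = q),
                           g, idx, b)
  expect_identical(res$provenance, "cypher")
  expect_identical(res$values, result_values(execute_cypher(g, q)))
  expect_length(backend_transcript(b), 0L)   # no repair, no fallback
})

test_that("broken cypher gets exactly one scripted repair, then succeeds as cypher", {
  g <- worked_example_graph()
  good <- 'MATCH (b:BodyPart)-[:OVEREXPRESSES]->(g:Gene {name: "METTL5"}) RETURN b.name'
  fixer <- scripted_backend(list(
    list(pattern = "## TASK: cypher repair", response = good)
  ))
  res <- knowledge_extract(list(cypher = "MATCH (b:BodyPart -[:OVER"), g,
                           build_index(g), fixer)
  expect_identical(res$provenance, "cypher")
  expect_identical(res$cypher, good)
  expect_length(backend_transcript(fixer), 1L)
})

test_that("empty rows are a valid cypher answer, not a fallback trigger", {
  g <- worked_example_graph()
  idx <- build_index(g)
  res <- knowledge_extract(
    list(text = "anything", cypher = 'MATCH (b:BodyPart)-[:OVEREXPRESSES]->(g:Gene {name: "NOPE"}) RETURN b.name'),
    g, idx, backend = NULL
  )
  expect_identical(res$provenance, "cypher")
  expect_length(res$values, 0L)
})

test_that("absent or unrepairable cypher falls back to at most top_k passages", {
  g <- generate_kg(seed = 4, sizes = c(Gene = 10, Drug = 5, Disease = 5,
                                       BodyPart = 8, Pathway = 4))
  idx <- build_index(g)
  res <- knowledge_extract(list(text = "which body parts express genes"),
                           g, idx, backend = NULL, top_k = 5L)
  expect_identical(res$provenance, "vector")
  expect_lte(length(res$values), 5L)

  res2 <- knowledge_extract(
    list(text = "which body parts express genes", cypher = "MATCH broken ("),
    g, idx, backend = NULL, top_k = 3L
  )
  expect_identical(res2$provenance, "vector")
  expect_lte(length(res2$values), 3L)

  expect_error(
    knowledge_extract(list(cypher = "MATCH broken ("), g, NULL, NULL),
    class = "retrieval_error"
  )
})

test_that("fallback passages respect the token budget", {
  g <- generate_kg(seed = 4, sizes = c(Gene = 10, Drug = 5, Disease = 5,
                                       BodyPart = 8, Pathway = 4))
  idx <- build_index(g)
  res <- knowledge_extract(list(text = "gene"), g, idx, NULL,
                           top_k = 4L, token_budget = 3L)
  for (p in res$values) {
    expect_lte(length(strsplit(p, "[[:space:]]+")[[1]]), 3L)
  }
})
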