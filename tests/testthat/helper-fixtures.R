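# Fixtures are built in code; nothing binary ships with the package.

# Two genes with overlapping over-expression neighborhoods: the canonical
# worked example (METTL5 in liver/kidney/brain, STYXL2 in liver/kidney/heart).
worked_example_graph <- function() {
  property_graph(
    nodes = list(
      list(id = "g1", labels = "Gene", properties = list(name = "METTL5")),
      list(id = "g2", labels = "Gene", properties = list(name = "STYXL2")),
      list(id = "b1", labels = "BodyPart", properties = list(name = "liver")),
      list(id = "b2", labels = "BodyPart", properties = list(name = "kidney")),
      list(id = "b3", labels = "BodyPart", properties = list(name = "brain")),
      list(id = "b4", labels = "BodyPart", properties = list(name = "heart"))
    ),
    edges = list(
      list(id = "e1", type = "OVEREXPRESSES", start = "b1", end = "g1"),
      list(id = "e2", type = "OVEREXPRESSES", start = "b2", end = "g1"),
      list(id = "e3", type = "OVEREXPRESSES", start = "b3", end = "g1"),
      list(id = "e4", type = "OVEREXPRESSES", start = "b1", end = "g2"),
      list(id = "e5", type = "OVEREXPRESSES", start = "b2", end = "g2"),
      list(id = "e6", type = "OVEREXPRESSES", start = "b4", end = "g2")
    )
  )
}

# Brute-force intersection of the two over-expression neighborhoods,
# computed by direct edge scan (independent of the query engine).
worked_example_truth <- function(g) {
  starts_into <- function(gene_id) {
    unlist(lapply(g$edges, function(e) {
      if (e$type == "OVEREXPRESSES" && e$end == gene_id) e$start else NULL
    }))
  }
  name_of <- function(id) {
    for (n in g$nodes) if (n$id == id) return(n$properties$name)
  }
  ids <- intersect(starts_into("g1"), starts_into("g2"))
  sort(unname(vapply(ids, name_of, "")))
}

worked_example_question <-
  "List the body parts/anatomy which over-express the genes METTL5 and STYXL2."

# Scripted backend that walks the worked example through the real multi-node
# pipeline: a three-step strategy, per-step code (two knowledge nodes, one
# compute node), judge scores and a synthesis sentence.
worked_example_backend <- function() {
  cy <- function(gene) sprintf(
    'MATCH (b:BodyPart)-[:OVEREXPRESSES]->(g:Gene {name: "%s"}) RETURN DISTINCT b.name',
    gene
  )
  step_code <- function(i) {
    if (i == 1L) paste0("OUTPUTS: mettl5_parts\nDEPENDS: none\n```r\n",
                        sprintf("mettl5_parts <- knowledge_extract(cypher = '%s')", cy("METTL5")),
                        "\n```")
    else if (i == 2L) paste0("OUTPUTS: styxl2_parts\nDEPENDS: none\n```r\n",
                             sprintf("styxl2_parts <- knowledge_extract(cypher = '%s')", cy("STYXL2")),
                             "\n```")
    else paste0("OUTPUTS: body_parts\nDEPENDS: 1, 2\n```r\n",
                "body_parts <- sort(intersect(mettl5_parts, styxl2_parts))\n```")
  }
  scripted_backend(list(
    list(pattern = "## TASK: strategy generation", response = paste(
      "1. Find the body parts or anatomy that over-expresses the gene METTL5.",
      "2. Find the body parts or anatomy that over-expresses the gene STYXL2.",
      "3. List the intersection of body parts from steps 1 and 2.",
      sep = "\n"
    )),
    list(pattern = "## TASK: strategy judging", response = "9 8 9"),
    list(pattern = "Step 1:", response = step_code(1L)),
    list(pattern = "Step 2:", response = step_code(2L)),
    list(pattern = "Step 3:", response = step_code(3L)),
    list(pattern = "## TASK: answer synthesis",
         response = "The body parts over-expressing both genes are listed in body_parts.")
  ))
}

# Small random knowledge graphs for oracle comparisons (<= 50 nodes).
random_small_kg <- function(seed) {
  withr::with_seed(seed, {
    sizes <- c(Gene = sample(2:8, 1), Drug = sample(1:5, 1),
               Disease = sample(1:5, 1), BodyPart = sample(2:6, 1),
               Pathway = sample(1:4, 1))
    dens <- stats::runif(6, 0.05, 0.5)
    names(dens) <- c("OVEREXPRESSES", "UNDEREXPRESSES", "ASSOCIATES_WITH",
                     "TREATS", "BINDS", "PARTICIPATES_IN")
  })
  generate_kg(seed = seed, sizes = sizes, densities = dens)
}

# Random valid DAG whose last node is the single output; every sink is wired
# into it, so the output is reachable from every node. Codes carry newlines,
# quotes and XML-hostile characters to stress CDATA round-tripping.
random_got_dag <- function(seed, max_nodes = 20L) {
  withr::with_seed(seed, {
    n <- sample(2:max_nodes, 1)
    ids <- c(sprintf("n%d", seq_len(n - 1L)), "out")
    nodes <- lapply(seq_len(n), function(i) {
      got_node(
        id = ids[[i]],
        kind = if (i == n) "output" else sample(c("knowledge", "compute"), 1),
        code = sprintf("x%d <- %d + %d # <tricky> & \"chars\"\ny <- 'a > b'", i,
                       sample(1:9, 1), sample(1:9, 1)),
        step_text = sprintf("step %d with <angle> & amp", i),
        outputs = sprintf("x%d", i)
      )
    })
    edges <- list()
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (j < n && stats::runif(1) < 0.25) {
          edges[[length(edges) + 1L]] <- c(from = ids[[i]], to = ids[[j]])
        }
      }
    }
    froms <- vapply(edges, `[[`, "", "from")
    for (i in seq_len(n - 1L)) {
      if (!(ids[[i]] %in% froms)) {
        edges[[length(edges) + 1L]] <- c(from = ids[[i]], to = "out")
      }
    }
    list(nodes = nodes, edges = edges)
  })
}

# Structural equality of two got_graphs (ids, kinds, code, steps, manifests,
# edge sets).
expect_same_got <- function(a, b) {
  key <- function(g) {
    nodes <- lapply(g$nodes, function(n) n[c("id", "kind", "code", "step_text", "outputs")])
    nodes <- nodes[order(vapply(nodes, `[[`, "", "id"), method = "radix")]
    edges <- sort(vapply(g$edges, function(e) paste(e[["from"]], e[["to"]]), ""),
                  method = "radix")
    list(nodes = nodes, edges = edges)
  }
  expect_identical(key(a), key(b))
}
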