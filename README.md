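# gotqa — Graph-of-Thoughts question answering over biomedical knowledge graphs

Large language models reason fluently but hallucinate facts. For questions
whose answers live in a curated biomedical knowledge graph — *which body
parts over-express both of these genes? which drugs treat diseases
associated with this gene?* — the reliable approach is to let the model
plan and let the graph answer. `gotqa` implements that division of labour
as an agent pipeline:

1. **Strategize** — the backend proposes *k* candidate step-by-step
   strategies (default 3), each grounded in the graph's serialized schema.
2. **Score and select** — each candidate is judged on clarity,
   comprehensiveness and schema alignment (integers 0–10); the highest
   total wins, ties to the lowest index.
3. **Generate code** — every step becomes an R snippet with a declared
   output manifest and dependency list.
4. **Compile to XML** — the snippets are assembled into a Graph of
   Thoughts (GoT): a validated DAG serialized as XML
   (`<Instruction id kind outputs>` with CDATA code, `<Edge from to>`). A
   document that fails validation sends the agent back to strategy
   generation, at most `compile_attempts` times.
5. **Execute with self-debugging** — nodes run in dependency order inside
   a restricted sandbox (allow-listed pure builtins, no file/network/system
   access, per-node wall-clock timeout); variables flow along edges. A
   failing node is revised by the backend from its code + error + visible
   variables, at most `max_debug_attempts` times.
6. **Retrieve knowledge, Cypher first** — node code reaches the graph only
   through `knowledge_extract()`: a Cypher query against the in-memory
   engine when one is supplied (one backend repair attempt if it fails),
   falling back to cosine similarity over a vector index of node/edge
   descriptions otherwise. Empty rows are a valid answer, never a fallback
   trigger.
7. **Answer** — the structured result computed by node code is returned
   verbatim for scoring; the prose answer is the backend's rendering of it.
   Fidelity is preserved because the scored object never passes through
   the model.

Everything runs offline: a deterministic **scripted backend** stands in for
a chat API (ordered pattern → response rules, byte-identical replays), and a
**synthetic knowledge-graph generator** emulates an Alzheimer's-style schema
(Gene, Drug, Disease, BodyPart, Pathway; over/under-expression, association,
treatment, binding, pathway participation). A live chat API plugs in through
`fn_backend()` without touching the pipeline.

## The query engine

`execute_cypher()` evaluates a Cypher subset sufficient for 1- and 2-hop
biomedical questions: linear `MATCH` patterns of one or two relationships
with optional direction, label filters and inline property maps; `WHERE`
with `=`, `<>`, `IN`, `AND`; `RETURN` of node names or properties with
optional `DISTINCT` and `LIMIT`. Matching uses property-graph semantics
(repeated variables unify; no relationship is bound twice in one match) and
returns rows in a stable order, sorted by their string rendering. The test
suite holds the engine equal to an exhaustive binding-enumeration oracle
over hundreds of random graphs.

Notably, a 2-relationship pattern expresses set intersection directly:

```
MATCH (g1:Gene {name: "METTL5"})<-[:OVEREXPRESSES]-(b:BodyPart)
      -[:OVEREXPRESSES]->(g2:Gene {name: "STYXL2"})
RETURN DISTINCT b.name
```

## The benchmark

`generate_kg()` + `generate_questions()` + `score_response()` form an
offline benchmark in six shapes: open-ended, true/false and multiple-choice
questions at 1 and 2 hops. Every item is self-verifying — it stores both a
ground truth computed by brute-force traversal and a Cypher query that
reproduces it. Scoring is exact match for true/false and multiple choice
and Jaccard overlap |A∩B|/|A∪B| over normalized entity sets for open-ended
answers. Under the truth-emitting `oracle_backend()` the full agent scores
a mean of 1.0 on every shape: the pipeline itself introduces no loss.

## Worked example

```r
library(gotqa)

g <- graph_read(system.file("extdata", "synthetic_alzkb_small.json",
                            package = "gotqa"))
g
#> property_graph: 40 nodes, 66 edges
#>   labels: BodyPart, Disease, Drug, Gene, Pathway
#>   relationship types: ASSOCIATES_WITH, BINDS, OVEREXPRESSES, PARTICIPATES_IN, TREATS, UNDEREXPRESSES

execute_cypher(g,
  'MATCH (b:BodyPart)-[:OVEREXPRESSES]->(g:Gene {name: "GENE005"}) RETURN DISTINCT b.name')
#> result_table: 3 row(s)
#>    b.name
#> 1   brain
#> 2  kidney
#> 3 stomach
```

End to end, with a scripted backend that plans "find METTL5's body parts,
find STYXL2's, intersect" over a six-node fixture in which METTL5 is
over-expressed in liver/kidney/brain and STYXL2 in liver/kidney/heart:

```r
ans <- answer_question(
  "List the body parts/anatomy which over-express the genes METTL5 and STYXL2.",
  fixture, backend)
ans
#> agent_answer
#>   structured: kidney, liver
#>   answer: The body parts over-expressing both genes are listed in body_parts.
ans$stages
#> strategy_generation -> strategy_scoring -> code_generation ->
#> xml_compilation -> got_execution -> answer_synthesis
```

`structured` is exactly the intersection {kidney, liver} as computed by node
code — the object that gets scored. The trace (`ans$trace`, serializable
with `trace_json()`) records per-node code as run, debug attempts, outputs
and retrieval provenance; identical seeds and scripts reproduce it byte for
byte.

The fixture and backend above are built in a few lines; see
`tests/testthat/helper-fixtures.R` for the exact construction, and the
`got-pipeline` vignette for the design rationale.

## Command line

A thin front end over the same functions ships in `inst/cli/gotqa`:

```sh
gotqa make-kg --seed 1 --out graph.json
gotqa make-questions --graph graph.json --qtype open --hops 2 --n 50 --seed 1 --out q.jsonl
gotqa benchmark --graph graph.json --questions q.jsonl --out report.json --oracle
gotqa ask --graph graph.json --question "..." --config config.yaml
```

Exit codes: 0 success, 2 configuration error, 3 pipeline failure.

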