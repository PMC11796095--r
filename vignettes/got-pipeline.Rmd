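---
title: "The Graph-of-Thoughts pipeline: design and rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Graph-of-Thoughts pipeline: design and rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gotqa)
```

## The problem and the division of labour

Questions over a biomedical knowledge graph have exact answers: the set of
body parts over-expressing two given genes is a fact of the graph, not a
matter of style. A language model asked such a question directly will often
produce a fluent, partially wrong entity list. The architecture implemented
here assigns the model only the tasks it is good at — planning, judging
plans, writing small code snippets, repairing them, phrasing a final
sentence — and routes every factual claim through deterministic machinery:
a query engine over the graph and sandboxed execution of the generated
code. The single scored object is whatever the code computed; it never
passes through the model on its way out. That one rule is the source of
most of the package's reliability properties, and the oracle-backend
benchmark below exists precisely to verify that the machinery around the
model loses nothing.

## Pipeline stages and their failure loops

A run proceeds strategy generation → strategy judging → per-step code
generation → XML assembly and validation → graph execution → synthesis.
Two bounded loops absorb model fallibility:

* **Compile loop.** Generated code arrives with a declared output manifest
  and a dependency list. Dependencies that point at nonexistent or later
  steps produce dangling edges or cycles; validation rejects the document
  and the agent returns to strategy generation, at most `compile_attempts`
  (default 3) times before a terminal error. With `compile_attempts = 0`
  the agent refuses immediately — a deliberate degenerate case, useful for
  testing terminal behaviour.
* **Self-debug loop.** A node that raises is re-generated from its code,
  the captured error and the names of visible variables, then re-executed;
  at most `max_debug_attempts` (default 3) revisions. The bound is
  enforced at the entry of the repair call, so a bound of zero never
  consults the backend. Backend calls per node are therefore at most
  `max_debug_attempts` beyond the one code-generation call.

The XML document is assembled mechanically from the generated snippets
rather than asked of the model as XML. The model supplies only code,
manifests and dependencies; structure is imposed by the package. This
makes malformed-document failures rare by construction and keeps the
validation errors that do occur (cycles, dangling dependencies) meaningful
signals about the plan rather than about bracket balancing.

## Execution semantics

Nodes run in a stable topological order (Kahn's algorithm, ties broken by
document order). A node's environment is the union of its parents' output
manifests; only manifest variables propagate, which keeps inter-node
contracts explicit and traces compact. When two parents export the same
name, the parent on the later-declared edge wins and the conflict is
recorded on the trace and raised as an R warning — silent shadowing was
the alternative and was rejected as a debugging hazard.

The sandbox is an allow-list: node code sees pure-computation builtins,
the injected `knowledge_extract`, and nothing else — no `library`, no
`::`, no `eval`/`parse`, no file, network, process or environment access.
Anything off the list fails at symbol lookup and surfaces as a structured
sandbox-violation failure, which is itself debuggable. A wall-clock limit
(default 10 s per node) converts runaway loops into timeout failures. The
test suite keeps a battery of hostile snippets (file reads, `system`,
`url`, `.Internal`, `get`-based laundering) that must all die in the
sandbox.

## Retrieval policy

Cypher is always preferred: it is exact, and its result size is bounded by
the graph, not by a context window. The fallback rules are deliberately
narrow. A query that parses and runs — even to zero rows — is the answer;
empty is informative, and falling back on "insufficient" results would
silently mask wrong queries. Only a query that fails to parse or execute
gets one backend repair attempt, and only after that (or with no query at
all) does the request text go to vector search: cosine similarity over
hashed term-frequency embeddings (fixed dimension 256, unit-normalized) of
templated node and edge descriptions, top `k = 10` passages, each truncated
to a 1024-token budget. The embedder is deterministic by design so that
retrieval tests are exact; a production embedder can be substituted without
touching the policy.

## The query engine and its oracle

The supported Cypher subset — linear patterns of one or two relationships,
optional direction, label filters, inline property maps, `WHERE` with
`=`/`<>`/`IN`/`AND`, `RETURN` with `DISTINCT` and `LIMIT` — covers every
question shape the benchmark generates while remaining small enough to
verify exhaustively. Two semantic choices are worth stating. Repeated
pattern variables unify to the same node. No relationship may be bound
twice within a single match (the property-graph convention); this is what
makes the 2-relationship intersection pattern correct, and it is mirrored
in the brute-force oracle the tests compare against. Rows are rendered to
strings (missing properties as empty, booleans as `true`/`false`) and
sorted by that rendering, so result order is a function of content only.
Row-set equality against nested-loop enumeration over hundreds of random
graph/query pairs is the engine's correctness argument; the engine itself
uses joins, the oracle does not.

## The synthetic knowledge graph and the benchmark

The generator emits the five-label schema (Gene, Drug, Disease, BodyPart,
Pathway) and six relationship types of an Alzheimer's-style knowledge
base. Defaults — 30 genes, 15 drugs, 12 diseases, 14 body parts, 10
pathways, edge probabilities 0.10–0.15 per relationship — give each entity
a handful of neighbours, so 1-hop answers are small nonempty sets and
2-hop intersections are frequently, but not always, nonempty; that is the
regime the question templates need, at a scale where every test remains
exhaustive. Anatomy and disease names come from small real vocabularies
(so normalization is exercised by names like "skeletal muscle"); genes,
drugs and pathways are patterned synthetic names, and every node carries a
`synthetic = TRUE` property.

What the generator does **not** emulate: the scale of a real knowledge
base (tens of thousands of nodes), its skewed degree distributions,
multi-label nodes, noisy or near-duplicate entity names, and the phrasing
diversity of hand-written questions. Consequently a perfect benchmark
score here demonstrates pipeline fidelity — plan → code → query → answer
with zero loss — not model quality on real data, which additionally
depends on a live model's strategy and Cypher quality.

Every generated item is self-verifying: the stored truth is computed by
direct edge traversal, and the stored Cypher reproduces it on the source
graph (for true/false items the query returns witness rows and truth is
"any row exists"; multiple-choice queries filter the answer set down to
the offered options, leaving exactly the correct one). The test suite
asserts this agreement item by item, so a dataset cannot drift from its
graph. Open-ended answers are scored by Jaccard overlap over case-folded,
whitespace-collapsed entity names — it penalizes omissions and fabricated
extras symmetrically — with the empty-truth/empty-answer case defined as
1. No fuzzy matching: near-miss names score as misses, which keeps
benchmark numbers conservative.

## Determinism and the trace

Scripted backends are pure functions of the prompt; generators take
explicit seeds; the agent pins its remaining randomness with the
configured seed. The canonical trace serialization contains the replayable
record — per-node code as run, debug attempts, outputs, retrieval
provenance, the structured and prose answers — and deliberately excludes
wall-clock timing, which lives as an attribute on the live object. Two
runs with identical inputs therefore serialize byte-identically, and the
test suite asserts exactly that.

## Parameters at a glance

| Parameter | Default | Rationale |
|---|---|---|
| `k` (strategy fan-out) | 3 | enough diversity for judging without tripling cost |
| `compile_attempts` | 3 | plan-level faults are usually phrasing luck; three tries suffice |
| `max_debug_attempts` | 3 | one-token faults repair in one; unbounded loops are worse than failure |
| `timeout` (s/node) | 10 | generous for set algebra over graph rows |
| `temperature` | 0 | every stage wants mode-seeking, reproducible text |
| `retrieval$top_k` | 10 | passages per vector fallback |
| `retrieval$token_budget` | 1024 | per-passage truncation |
| `max_prompt_chars` | 60000 | checked before any transport |

## Problem sizes used in verification

The shipped checks run the engine/oracle comparison on 200 random graphs
of at most 50 nodes, XML round-trips on 500 random DAGs of up to 20 nodes,
and the six benchmark shapes at 50 questions each over the default
generator graph — sizes at which the exhaustive oracles are instant and
the full sweep stays comfortably interactive.

## Known limitations

The Cypher subset excludes write clauses, `OPTIONAL MATCH`, aggregation
and patterns beyond two relationships; the executor runs nodes
sequentially (no parallel scheduling) and supports no inter-node control
flow beyond the DAG; strategy judging uses exactly three criteria; the
scripted strategy/judging/codegen prompts are versioned templates in
`inst/prompts/`, and a live backend's behaviour on them is inherently
outside what offline tests can certify.
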