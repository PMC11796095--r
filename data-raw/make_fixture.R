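# Regenerates the shipped synthetic knowledge-graph fixture.
# Run from the package root: Rscript data-raw/make_fixture.R
devtools::load_all(".", quiet = TRUE)
g <- generate_kg(
  seed = 2024,
  sizes = c(Gene = 12, Drug = 8, Disease = 8, BodyPart = 8, Pathway = 4)
)
stopifnot(length(g$nodes) == 40L)
graph_write(g, file.path("inst", "extdata", "synthetic_alzkb_small.json"))
cat("wrote", length(g$nodes), "nodes,", length(g$edges), "edges\n")
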