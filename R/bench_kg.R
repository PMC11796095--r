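# Synthetic biomedical knowledge graph in the style of an Alzheimer's
# knowledge base: Gene / Drug / Disease / BodyPart / Pathway nodes joined by
# six typed relationships. Entirely generated, clearly labelled synthetic;
# names for anatomy and diseases come from small real vocabularies so that
# questions read naturally and case/whitespace normalization gets exercised.

BODY_PART_VOCAB <- c(
  "liver", "kidney", "brain", "heart", "lung", "spleen", "pancreas",
  "stomach", "skin", "skeletal muscle", "cerebellum", "hippocampus",
  "thyroid gland", "retina", "adrenal gland", "bone marrow", "prostate",
  "ovary", "testis", "colon", "small intestine", "esophagus", "bladder",
  "lymph node", "spinal cord", "pituitary gland", "salivary gland",
  "adipose tissue", "aorta", "trachea"
)

DISEASE_VOCAB <- c(
  "Alzheimer disease", "Parkinson disease", "frontotemporal dementia",
  "vascular dementia", "mild cognitive impairment", "major depressive disorder",
  "type 2 diabetes mellitus", "hypertension", "atherosclerosis", "stroke",
  "epilepsy", "multiple sclerosis", "amyotrophic lateral sclerosis",
  "schizophrenia", "bipolar disorder", "obesity", "chronic kidney disease",
  "rheumatoid arthritis", "asthma", "osteoporosis"
)

# (type, start label, end label) catalog — the schema the generator emits.
KG_RELATIONS <- list(
  list(type = "OVEREXPRESSES", start = "BodyPart", end = "Gene"),
  list(type = "UNDEREXPRESSES", start = "BodyPart", end = "Gene"),
  list(type = "ASSOCIATES_WITH", start = "Gene", end = "Disease"),
  list(type = "TREATS", start = "Drug", end = "Disease"),
  list(type = "BINDS", start = "Drug", end = "Gene"),
  list(type = "PARTICIPATES_IN", start = "Gene", end = "Pathway")
)

default_kg_sizes <- function() {
  c(Gene = 30L, Drug = 15L, Disease = 12L, BodyPart = 14L, Pathway = 10L)
}

default_kg_densities <- function() {
  c(OVEREXPRESSES = 0.15, UNDEREXPRESSES = 0.10, ASSOCIATES_WITH = 0.12,
    TREATS = 0.15, BINDS = 0.10, PARTICIPATES_IN = 0.15)
}

synth_name <- function(label, i) {
  switch(label,
    Gene = sprintf("GENE%03d", i),
    Drug = sprintf("drug-%03d", i),
    Disease = if (i <= length(DISEASE_VOCAB)) DISEASE_VOCAB[[i]]
              else sprintf("disease %03d", i),
    BodyPart = if (i <= length(BODY_PART_VOCAB)) BODY_PART_VOCAB[[i]]
               else sprintf("body part %03d", i),
    Pathway = sprintf("pathway of process %03d", i)
  )
}

#' Generate a synthetic biomedical knowledge graph
#'
#' Deterministic given the seed: node counts per label are exact, and each
#' relationship type is drawn independently per (start, end) node pair with
#' its configured edge probability. The six relationship signatures are
#' body-part over-/under-expression of genes, gene-disease association,
#' drug-disease treatment, drug-gene binding, and gene-pathway participation.
#'
#' @param seed integer seed; same arguments, same seed, identical graph
#'   (including its JSON serialization).
#' @param sizes named integer vector of node counts per label
#'   (`Gene`, `Drug`, `Disease`, `BodyPart`, `Pathway`), all >= 1.
#' @param densities named numeric vector of per-relationship edge
#'   probabilities in `[0, 1]`; a density of 0 yields no edges of that type.
#' @return A [property_graph()].
#' @examples
#' g <- generate_kg(seed = 1, sizes = c(Gene = 10, Drug = 4, Disease = 4,
#'                                      BodyPart = 6, Pathway = 3))
#' g
#' @export
generate_kg <- function(seed = 1L, sizes = default_kg_sizes(),
                        densities = default_kg_densities()) {
  full_sizes <- default_kg_sizes()
  full_sizes[names(sizes)] <- as.integer(sizes)
  full_dens <- default_kg_densities()
  full_dens[names(densities)] <- as.numeric(densities)
  if (any(is.na(full_sizes)) || any(full_sizes < 1L)) {
    stop_config("every label needs a node count >= 1")
  }
  if (any(is.na(full_dens)) || any(full_dens < 0) || any(full_dens > 1)) {
    stop_config("edge densities must lie in [0, 1]")
  }
  withr::with_seed(as.integer(seed), {
    nodes <- list()
    ids_by_label <- list()
    for (label in names(full_sizes)) {
      for (i in seq_len(full_sizes[[label]])) {
        id <- sprintf("%s-%d", tolower(label), i)
        nodes[[length(nodes) + 1L]] <- list(
          id = id, labels = label,
          properties = list(name = synth_name(label, i), synthetic = TRUE)
        )
        ids_by_label[[label]] <- c(ids_by_label[[label]], id)
      }
    }
    edges <- list()
    counter <- 0L
    for (rel in KG_RELATIONS) {
      p <- full_dens[[rel$type]]
      for (s in ids_by_label[[rel$start]]) {
        draw <- stats::runif(length(ids_by_label[[rel$end]]))
        hit <- ids_by_label[[rel$end]][draw < p]
        for (d in hit) {
          counter <- counter + 1L
          edges[[counter]] <- list(id = sprintf("e%d", counter), type = rel$type,
                                   start = s, end = d)
        }
      }
    }
    property_graph(nodes = nodes, edges = edges)
  })
}
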