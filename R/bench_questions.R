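# Benchmark question generator: six dataset shapes (open / true-false /
# multiple choice, each at 1 or 2 hops). Every item is self-verifying: its
# ground truth is computed by direct edge-table traversal, and it carries a
# Cypher query that reproduces that truth on the source graph — the test
# suite checks the two agree, so a generated dataset can never drift from
# the graph it came from.

# Flat (start_name, type, end_name) view used for all traversal truths.
edge_name_table <- function(graph) {
  et <- attr(graph, "edge_table")
  nm <- function(ids) vapply(ids, function(id) node_property(graph, id, "name"), "")
  data.frame(
    type = et$type,
    start_name = if (nrow(et)) nm(et$start) else character(),
    end_name = if (nrow(et)) nm(et$end) else character(),
    stringsAsFactors = FALSE
  )
}

# 1-hop phrasing catalog. "rev": given an end-node name, the answer is the
# set of start-node names; "fwd": the reverse.
HOP1_TEMPLATES <- list(
  list(type = "OVEREXPRESSES", dir = "rev", src = "BodyPart", dst = "Gene",
       q = "List the body parts/anatomy which over-express the gene %s."),
  list(type = "OVEREXPRESSES", dir = "fwd", src = "BodyPart", dst = "Gene",
       q = "List the genes which are over-expressed in the %s."),
  list(type = "UNDEREXPRESSES", dir = "rev", src = "BodyPart", dst = "Gene",
       q = "List the body parts/anatomy which under-express the gene %s."),
  list(type = "ASSOCIATES_WITH", dir = "fwd", src = "Gene", dst = "Disease",
       q = "List the diseases associated with the gene %s."),
  list(type = "ASSOCIATES_WITH", dir = "rev", src = "Gene", dst = "Disease",
       q = "List the genes associated with %s."),
  list(type = "TREATS", dir = "rev", src = "Drug", dst = "Disease",
       q = "List the drugs that treat %s."),
  list(type = "BINDS", dir = "fwd", src = "Drug", dst = "Gene",
       q = "List the genes bound by the drug %s."),
  list(type = "PARTICIPATES_IN", dir = "fwd", src = "Gene", dst = "Pathway",
       q = "List the pathways the gene %s participates in.")
)

# 2-hop chains: anchor at one end, answer at the other; each hop may run
# with or against edge direction. arrow "fwd" means the pattern hop follows
# edge direction left-to-right.
HOP2_TEMPLATES <- list(
  list(kind = "chain",
       q = "List the diseases associated with genes that the drug %s binds.",
       anchor = c("Drug"), mid = "Gene", ans = "Disease",
       hop1 = c(type = "BINDS", arrow = "fwd"),
       hop2 = c(type = "ASSOCIATES_WITH", arrow = "fwd")),
  list(kind = "chain",
       q = "List the drugs that treat diseases associated with the gene %s.",
       anchor = c("Gene"), mid = "Disease", ans = "Drug",
       hop1 = c(type = "ASSOCIATES_WITH", arrow = "fwd"),
       hop2 = c(type = "TREATS", arrow = "rev")),
  list(kind = "chain",
       q = "List the genes over-expressed in body parts that over-express the gene %s.",
       anchor = c("Gene"), mid = "BodyPart", ans = "Gene",
       hop1 = c(type = "OVEREXPRESSES", arrow = "rev"),
       hop2 = c(type = "OVEREXPRESSES", arrow = "fwd")),
  list(kind = "intersection",
       q = "List the body parts/anatomy which over-express the genes %s and %s.",
       type = "OVEREXPRESSES", via = "BodyPart", of = "Gene")
)

anchor_label <- function(tpl) tpl$anchor[[1]]

# --- traversal truths (independent of the Cypher engine) -------------------

hop1_truth <- function(ent, tpl, name) {
  rows <- ent[ent$type == tpl$type, , drop = FALSE]
  if (tpl$dir == "rev") sort_c(unique(rows$start_name[rows$end_name == name]))
  else sort_c(unique(rows$end_name[rows$start_name == name]))
}

chain_truth <- function(ent, tpl, name) {
  step <- function(hop, from_names) {
    rows <- ent[ent$type == hop[["type"]], , drop = FALSE]
    if (hop[["arrow"]] == "fwd") {
      list(hits = rows[rows$start_name %in% from_names, , drop = FALSE],
           to = "end_name")
    } else {
      list(hits = rows[rows$end_name %in% from_names, , drop = FALSE],
           to = "start_name")
    }
  }
  s1 <- step(tpl$hop1, name)
  mids <- unique(s1$hits[[s1$to]])
  s2 <- step(tpl$hop2, mids)
  out <- unique(s2$hits[[s2$to]])
  # relationship uniqueness: a chain whose two hops are the same edge is not
  # a match (only possible for same-type back-and-forth chains)
  if (tpl$hop1[["type"]] == tpl$hop2[["type"]] &&
      tpl$hop1[["arrow"]] != tpl$hop2[["arrow"]]) {
    rows <- ent[ent$type == tpl$hop1[["type"]], , drop = FALSE]
    reach <- character()
    anchored <- if (tpl$hop1[["arrow"]] == "rev") {
      rows[rows$end_name == name, , drop = FALSE]
    } else {
      rows[rows$start_name == name, , drop = FALSE]
    }
    for (i in seq_len(nrow(anchored))) {
      mid <- if (tpl$hop1[["arrow"]] == "rev") anchored$start_name[[i]] else anchored$end_name[[i]]
      second <- if (tpl$hop2[["arrow"]] == "fwd") {
        rows[rows$start_name == mid, , drop = FALSE]
      } else {
        rows[rows$end_name == mid, , drop = FALSE]
      }
      # drop the exact edge used on hop 1
      keep <- !(second$start_name == anchored$start_name[[i]] &
                second$end_name == anchored$end_name[[i]])
      reach <- c(reach, if (tpl$hop2[["arrow"]] == "fwd") second$end_name[keep]
                        else second$start_name[keep])
    }
    out <- unique(reach)
  }
  sort_c(out)
}

intersection_truth <- function(ent, tpl, a, b) {
  rows <- ent[ent$type == tpl$type, , drop = FALSE]
  sort_c(intersect(rows$start_name[rows$end_name == a],
                   rows$start_name[rows$end_name == b]))
}

# --- cypher renderings -----------------------------------------------------

hop1_cypher <- function(tpl, name, extra_where = NULL) {
  base <- if (tpl$dir == "rev") {
    sprintf('MATCH (x:%s)-[:%s]->(y:%s {name: "%s"})', tpl$src, tpl$type, tpl$dst, name)
  } else {
    sprintf('MATCH (y:%s {name: "%s"})-[:%s]->(x:%s)', tpl$src, name, tpl$type, tpl$dst)
  }
  paste0(base, if (!is.null(extra_where)) paste0(" ", extra_where),
         " RETURN DISTINCT x.name")
}

chain_cypher <- function(tpl, name, extra_where = NULL) {
  hop_txt <- function(hop) {
    if (hop[["arrow"]] == "fwd") sprintf("-[:%s]->", hop[["type"]])
    else sprintf("<-[:%s]-", hop[["type"]])
  }
  paste0(
    sprintf('MATCH (a:%s {name: "%s"})%s(m:%s)%s(x:%s)',
            anchor_label(tpl), name, hop_txt(tpl$hop1), tpl$mid,
            hop_txt(tpl$hop2), tpl$ans),
    if (!is.null(extra_where)) paste0(" ", extra_where),
    " RETURN DISTINCT x.name"
  )
}

intersection_cypher <- function(tpl, a, b, extra_where = NULL) {
  paste0(
    sprintf('MATCH (g1:%s {name: "%s"})<-[:%s]-(x:%s)-[:%s]->(g2:%s {name: "%s"})',
            tpl$of, a, tpl$type, tpl$via, tpl$type, tpl$of, b),
    if (!is.null(extra_where)) paste0(" ", extra_where),
    " RETURN DISTINCT x.name"
  )
}

in_clause <- function(values) {
  sprintf("WHERE x.name IN [%s]",
          paste(sprintf('"%s"', values), collapse = ", "))
}

qa_item <- function(question, qtype, hops, truth, truth_cypher,
                    options = NULL) {
  structure(list(question = question, qtype = qtype, hops = as.integer(hops),
                 options = options, truth = truth, truth_cypher = truth_cypher),
            class = "qa_item")
}

#' @export
print.qa_item <- function(x, ...) {
  cat(sprintf("[%s %d-hop] %s\n", x$qtype, x$hops, x$question))
  if (!is.null(x$options)) cat("  options: ", comma(x$options), "\n", sep = "")
  cat("  truth: ", if (is.logical(x$truth)) render_scalar(x$truth)
      else comma(x$truth), "\n", sep = "")
  invisible(x)
}

#' Generate benchmark questions over a knowledge graph
#'
#' Instantiates natural-language templates against the graph and records,
#' for every item, a ground truth computed by brute-force edge traversal and
#' a Cypher query that reproduces it. Open-ended items answer with an entity
#' set (2-hop includes chain questions and intersection questions of the
#' form "which body parts over-express genes A and B"); true/false items
#' assert the existence of an edge (1-hop) or a path (2-hop), with the
#' query returning the witness rows, so truth is "any row exists";
#' multiple-choice items carry one correct option plus same-label
#' distractors drawn from outside the answer set, and their query filters
#' the answer set down to the offered options, returning exactly the
#' correct one.
#'
#' @param graph a [property_graph()].
#' @param qtype `"open"`, `"tf"` or `"mc"`.
#' @param hops 1 or 2.
#' @param n number of items requested; if the graph is too sparse to
#'   instantiate that many distinct items, fewer are returned with a warning.
#' @param seed integer seed; generation is deterministic.
#' @param n_options options per multiple-choice item (default 4).
#' @return List of `qa_item` objects.
#' @export
generate_questions <- function(graph, qtype = c("open", "tf", "mc"),
                               hops = 1L, n = 50L, seed = 1L, n_options = 4L) {
  qtype <- match.arg(qtype)
  stopifnot(hops %in% c(1L, 2L), is_count(n, 1L))
  ent <- edge_name_table(graph)
  names_by_label <- label_name_map(graph)
  withr::with_seed(as.integer(seed), {
    items <- list()
    seen <- character()
    guard <- 0L
    while (length(items) < n && guard < 60L * n) {
      guard <- guard + 1L
      item <- switch(qtype,
        open = make_open_item(ent, names_by_label, hops),
        tf = make_tf_item(ent, names_by_label, hops),
        mc = make_mc_item(ent, names_by_label, hops, n_options)
      )
      if (is.null(item) || item$question %in% seen) next
      seen <- c(seen, item$question)
      items[[length(items) + 1L]] <- item
    }
    if (length(items) < n) {
      warning(sprintf(
        "graph too sparse for %d distinct %s %d-hop items; returning %d",
        n, qtype, hops, length(items)
      ), call. = FALSE)
    }
    items
  })
}

label_name_map <- function(graph) {
  out <- list()
  for (nd in graph$nodes) {
    for (lab in nd$labels) {
      out[[lab]] <- c(out[[lab]], nd$properties$name)
    }
  }
  lapply(out, unique)
}

pick <- function(x) if (length(x) == 0L) NULL else x[[sample.int(length(x), 1L)]]

make_open_item <- function(ent, names_by_label, hops) {
  if (hops == 1L) {
    tpl <- HOP1_TEMPLATES[[sample.int(length(HOP1_TEMPLATES), 1L)]]
    pool <- if (tpl$dir == "rev") unique(ent$end_name[ent$type == tpl$type])
            else unique(ent$start_name[ent$type == tpl$type])
    name <- pick(pool)
    if (is.null(name)) return(NULL)
    truth <- hop1_truth(ent, tpl, name)
    qa_item(sprintf(tpl$q, name), "open", 1L, truth, hop1_cypher(tpl, name))
  } else {
    tpl <- HOP2_TEMPLATES[[sample.int(length(HOP2_TEMPLATES), 1L)]]
    if (tpl$kind == "intersection") {
      rows <- ent[ent$type == tpl$type, , drop = FALSE]
      genes <- unique(rows$end_name)
      if (length(genes) < 2L) return(NULL)
      pair <- sample(genes, 2L)
      truth <- intersection_truth(ent, tpl, pair[[1]], pair[[2]])
      qa_item(sprintf(tpl$q, pair[[1]], pair[[2]]), "open", 2L, truth,
              intersection_cypher(tpl, pair[[1]], pair[[2]]))
    } else {
      pool <- anchored_pool(ent, tpl)
      name <- pick(pool)
      if (is.null(name)) return(NULL)
      truth <- chain_truth(ent, tpl, name)
      qa_item(sprintf(tpl$q, name), "open", 2L, truth, chain_cypher(tpl, name))
    }
  }
}

anchored_pool <- function(ent, tpl) {
  rows <- ent[ent$type == tpl$hop1[["type"]], , drop = FALSE]
  if (tpl$hop1[["arrow"]] == "fwd") unique(rows$start_name) else unique(rows$end_name)
}

make_tf_item <- function(ent, names_by_label, hops) {
  want_true <- stats::runif(1) < 0.5
  if (hops == 1L) {
    tpl <- HOP1_TEMPLATES[[sample.int(length(HOP1_TEMPLATES), 1L)]]
    rows <- ent[ent$type == tpl$type, , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    if (want_true) {
      r <- rows[sample.int(nrow(rows), 1L), ]
      s <- r$start_name; d <- r$end_name
    } else {
      s <- pick(names_by_label[[tpl$src]])
      d <- pick(names_by_label[[tpl$dst]])
      if (is.null(s) || is.null(d)) return(NULL)
      if (any(rows$start_name == s & rows$end_name == d)) return(NULL)
    }
    question <- sprintf("True or false: there is a %s relationship from %s to %s.",
                        gsub("_", " ", tolower(tpl$type)), s, d)
    cy <- sprintf('MATCH (a:%s {name: "%s"})-[:%s]->(b:%s {name: "%s"}) RETURN a.name',
                  tpl$src, s, tpl$type, tpl$dst, d)
    qa_item(question, "tf", 1L, want_true, cy)
  } else {
    tpl <- HOP2_TEMPLATES[[1L]]   # Drug -BINDS-> Gene -ASSOCIATES_WITH-> Disease
    drugs <- unique(ent$start_name[ent$type == "BINDS"])
    diseases <- names_by_label$Disease
    if (length(drugs) == 0L || length(diseases) == 0L) return(NULL)
    d <- pick(drugs)
    truthful <- chain_truth(ent, tpl, d)
    target <- if (want_true) pick(truthful) else pick(setdiff(diseases, truthful))
    if (is.null(target)) return(NULL)
    question <- sprintf("True or false: the drug %s binds a gene associated with %s.",
                        d, target)
    cy <- sprintf(paste0('MATCH (a:Drug {name: "%s"})-[:BINDS]->(m:Gene)',
                         '-[:ASSOCIATES_WITH]->(x:Disease {name: "%s"}) RETURN DISTINCT m.name'),
                  d, target)
    qa_item(question, "tf", 2L, want_true, cy)
  }
}

make_mc_item <- function(ent, names_by_label, hops, n_options) {
  base <- make_open_item(ent, names_by_label, hops)
  if (is.null(base) || length(base$truth) == 0L) return(NULL)
  correct <- pick(base$truth)
  # distractors: same-label entities outside the full answer set
  answer_label <- mc_answer_label(base$truth, names_by_label)
  if (is.null(answer_label)) return(NULL)
  pool <- setdiff(names_by_label[[answer_label]], base$truth)
  if (length(pool) < n_options - 1L) return(NULL)
  options <- sample(c(correct, sample(pool, n_options - 1L)))
  question <- sub("^List the", "Which of the following is among the", base$question)
  question <- paste0(question, " Options: ", comma(options))
  cy <- add_in_filter(base$truth_cypher, options)
  qa_item(question, "mc", hops, correct, cy, options = options)
}

mc_answer_label <- function(truth, names_by_label) {
  for (lab in names(names_by_label)) {
    if (all(truth %in% names_by_label[[lab]])) return(lab)
  }
  NULL
}

add_in_filter <- function(cypher, options) {
  sub(" RETURN DISTINCT x.name",
      paste0(" ", in_clause(options), " RETURN DISTINCT x.name"),
      cypher, fixed = TRUE)
}

# --- JSONL persistence -----------------------------------------------------

#' Write benchmark questions as JSONL
#'
#' One JSON object per line with keys `question`, `qtype`, `hops`,
#' `options`, `truth`, `truth_cypher`.
#'
#' @param items list of `qa_item` objects.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
questions_write <- function(items, path) {
  lines <- vapply(items, function(it) {
    as.character(to_stable_json(list(
      question = it$question, qtype = it$qtype, hops = it$hops,
      options = it$options, truth = it$truth, truth_cypher = it$truth_cypher
    )))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read benchmark questions from JSONL
#' @param path JSONL file from [questions_write()].
#' @return List of `qa_item` objects.
#' @export
questions_read <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lapply(lines[nzchar(lines)], function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    truth <- if (x$qtype == "tf") as.logical(x$truth) else as.character(x$truth)
    qa_item(x$question, x$qtype, as.integer(x$hops), truth, x$truth_cypher,
            options = if (is.null(x$options)) NULL else as.character(x$options))
  })
}
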