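# Independent brute-force oracle for the query engine: enumerates every
# node / edge-tuple binding by nested loops over the raw graph lists, then
# filters, projects, deduplicates and sorts. Shares only the parser with the
# engine — evaluation is written from scratch against the same documented
# semantics (repeated variables unify, no edge may be bound twice in one
# match, missing properties render empty and never compare equal).

oracle_node_prop <- function(g, id, key) {
  for (n in g$nodes) if (n$id == id) {
    v <- n$properties[[key]]
    return(if (is.null(v)) NA else v)
  }
  NA
}

oracle_render <- function(v) {
  if (is.null(v) || (length(v) == 1L && is.na(v))) return("")
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.numeric(v)) return(format(v, scientific = FALSE, trim = TRUE))
  as.character(v)
}

oracle_scalar_eq <- function(a, b) {
  if (is.null(a) || is.null(b) || any(is.na(a)) || any(is.na(b))) return(FALSE)
  if (is.numeric(a) && is.numeric(b)) return(a == b)
  identical(as.character(a), as.character(b))
}

oracle_node_ok <- function(g, id, np) {
  node <- NULL
  for (n in g$nodes) if (n$id == id) { node <- n; break }
  if (!is.na(np$label) && !(np$label %in% node$labels)) return(FALSE)
  for (key in names(np$props)) {
    if (!oracle_scalar_eq(node$properties[[key]], np$props[[key]])) return(FALSE)
  }
  TRUE
}

# All (from, to, edge_index) orientations an edge offers for a rel pattern.
oracle_orientations <- function(e, idx, rp) {
  if (!is.na(rp$type) && e$type != rp$type) return(list())
  fwd <- list(from = e$start, to = e$end, idx = idx)
  bwd <- list(from = e$end, to = e$start, idx = idx)
  switch(rp$dir, out = list(fwd), "in" = list(bwd), both = list(fwd, bwd))
}

oracle_execute <- function(g, query) {
  ast <- gotqa:::cypher_parse(query)
  k <- length(ast$rels)
  bindings <- list()
  add_binding <- function(assign) bindings[[length(bindings) + 1L]] <<- assign

  unify <- function(assign, var, id) {
    if (!is.null(assign[[var]])) {
      if (assign[[var]] != id) return(NULL)
      return(assign)
    }
    assign[[var]] <- id
    assign
  }

  if (k == 0L) {
    for (n in g$nodes) {
      if (oracle_node_ok(g, n$id, ast$nodes[[1]])) {
        add_binding(stats::setNames(list(n$id), ast$nodes[[1]]$var))
      }
    }
  } else if (k == 1L) {
    for (i in seq_along(g$edges)) {
      for (o in oracle_orientations(g$edges[[i]], i, ast$rels[[1]])) {
        if (!oracle_node_ok(g, o$from, ast$nodes[[1]])) next
        if (!oracle_node_ok(g, o$to, ast$nodes[[2]])) next
        a <- unify(list(), ast$nodes[[1]]$var, o$from)
        a <- unify(a, ast$nodes[[2]]$var, o$to)
        if (!is.null(a)) add_binding(a)
      }
    }
  } else {
    for (i in seq_along(g$edges)) {
      for (o1 in oracle_orientations(g$edges[[i]], i, ast$rels[[1]])) {
        for (j in seq_along(g$edges)) {
          if (i == j) next                       # relationship uniqueness
          for (o2 in oracle_orientations(g$edges[[j]], j, ast$rels[[2]])) {
            if (o1$to != o2$from) next
            if (!oracle_node_ok(g, o1$from, ast$nodes[[1]])) next
            if (!oracle_node_ok(g, o1$to, ast$nodes[[2]])) next
            if (!oracle_node_ok(g, o2$to, ast$nodes[[3]])) next
            a <- unify(list(), ast$nodes[[1]]$var, o1$from)
            if (!is.null(a)) a <- unify(a, ast$nodes[[2]]$var, o1$to)
            if (!is.null(a)) a <- unify(a, ast$nodes[[3]]$var, o2$to)
            if (!is.null(a)) add_binding(a)
          }
        }
      }
    }
  }

  resolve <- function(op, assign) {
    switch(op$kind,
      lit = op$value,
      name = oracle_node_prop(g, assign[[op$var]], "name"),
      prop = oracle_node_prop(g, assign[[op$var]], op$key)
    )
  }
  where_ok <- function(assign) {
    for (cond in ast$where) {
      lhs <- resolve(cond$lhs, assign)
      ok <- switch(cond$op,
        eq = oracle_scalar_eq(lhs, resolve(cond$rhs, assign)),
        neq = {
          rhs <- resolve(cond$rhs, assign)
          !any(is.na(lhs)) && !any(is.na(rhs)) && !oracle_scalar_eq(lhs, rhs)
        },
        "in" = any(vapply(cond$rhs, function(v) oracle_scalar_eq(lhs, v), logical(1)))
      )
      if (!isTRUE(ok)) return(FALSE)
    }
    TRUE
  }
  bindings <- Filter(where_ok, bindings)

  rows <- vapply(bindings, function(assign) {
    paste(vapply(ast$items, function(item) {
      v <- if (is.na(item$key)) oracle_node_prop(g, assign[[item$var]], "name")
           else oracle_node_prop(g, assign[[item$var]], item$key)
      oracle_render(v)
    }, ""), collapse = "\x1f")
  }, "")
  if (ast$distinct) rows <- unique(rows)
  rows <- sort(rows, method = "radix")
  if (!is.na(ast$limit)) rows <- head(rows, ast$limit)
  cols <- vapply(ast$items, `[[`, "", "colname")
  parts <- strsplit(rows, "\x1f", fixed = TRUE)
  df <- as.data.frame(
    stats::setNames(lapply(seq_along(cols), function(ci) {
      vapply(parts, function(p) if (ci <= length(p)) p[[ci]] else "", "")
    }), cols),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  df
}

# Rendered-row comparison between engine output and the oracle.
expect_engine_matches_oracle <- function(g, query) {
  engine <- as.data.frame(execute_cypher(g, query))
  oracle <- oracle_execute(g, query)
  rownames(engine) <- NULL
  rownames(oracle) <- NULL
  expect_identical(engine, oracle, label = sprintf("engine for `%s`", query))
}

# Random queries over the synthetic schema, rendered to text.
random_query <- function(g, seed) {
  withr::with_seed(seed, {
    rels <- list(
      c("OVEREXPRESSES", "BodyPart", "Gene"),
      c("UNDEREXPRESSES", "BodyPart", "Gene"),
      c("ASSOCIATES_WITH", "Gene", "Disease"),
      c("TREATS", "Drug", "Disease"),
      c("BINDS", "Drug", "Gene"),
      c("PARTICIPATES_IN", "Gene", "Pathway")
    )
    any_name <- function() {
      nm <- vapply(g$nodes, function(n) n$properties$name, "")
      nm[[sample.int(length(nm), 1)]]
    }
    node_pat <- function(var, label) {
      lab <- if (stats::runif(1) < 0.7) paste0(":", label) else ""
      prop <- if (stats::runif(1) < 0.3) sprintf(' {name: "%s"}', any_name()) else ""
      sprintf("(%s%s%s)", var, lab, prop)
    }
    rel_pat <- function(type) {
      t <- if (stats::runif(1) < 0.85) paste0(":", type) else ""
      switch(sample(3, 1),
             sprintf("-[%s]->", t), sprintf("<-[%s]-", t), sprintf("-[%s]-", t))
    }
    n_hops <- sample(1:2, 1)
    r1 <- rels[[sample.int(6, 1)]]
    if (n_hops == 1L) {
      pat <- paste0(node_pat("a", r1[[2]]), rel_pat(r1[[1]]), node_pat("b", r1[[3]]))
      vars <- c("a", "b")
    } else {
      r2 <- rels[[sample.int(6, 1)]]
      pat <- paste0(node_pat("a", r1[[2]]), rel_pat(r1[[1]]),
                    node_pat("b", r1[[3]]), rel_pat(r2[[1]]),
                    node_pat("c", sample(c(r2[[2]], r2[[3]]), 1)))
      vars <- c("a", "b", "c")
    }
    where <- ""
    if (stats::runif(1) < 0.4) {
      v <- sample(vars, 1)
      where <- switch(sample(3, 1),
        sprintf(' WHERE %s.name <> "%s"', v, any_name()),
        sprintf(' WHERE %s.name IN ["%s", "%s"]', v, any_name(), any_name()),
        sprintf(' WHERE %s = "%s"', v, any_name())
      )
    }
    ret_vars <- sample(vars, sample(seq_along(vars), 1))
    items <- vapply(ret_vars, function(v) {
      if (stats::runif(1) < 0.7) paste0(v, ".name") else v
    }, "")
    distinct <- if (stats::runif(1) < 0.5) "DISTINCT " else ""
    limit <- if (stats::runif(1) < 0.25) sprintf(" LIMIT %d", sample(1:5, 1)) else ""
    sprintf("MATCH %s%s RETURN %s%s%s", pat, where, distinct,
            paste(items, collapse = ", "), limit)
  })
}
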