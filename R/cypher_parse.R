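# Parser for the supported Cypher subset:
#
#   MATCH (a:Label {key: "v"})-[r:TYPE]->(b:Label)[-[s:TYPE2]->(c)]
#   [WHERE <operand> (= | <>) <operand> | <operand> IN [lit, ...] [AND ...]]
#   RETURN [DISTINCT] a.prop | a [, ...] [LIMIT n]
#
# Linear patterns of one or two relationships, each hop directed left, right
# or undirected. Keywords are case-insensitive; labels and relationship types
# are case-sensitive. A bare variable in WHERE or RETURN stands for the
# node's `name` property.

cypher_tokenize <- function(query) {
  chars <- strsplit(query, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  push <- function(type, text, pos) toks[[length(toks) + 1L]] <<- list(type = type, text = text, pos = pos)
  while (i <= n) {
    ch <- chars[[i]]
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    if (grepl("[A-Za-z_]", ch)) {
      j <- i
      while (j <= n && grepl("[A-Za-z0-9_]", chars[[j]])) j <- j + 1L
      push("IDENT", paste(chars[i:(j - 1L)], collapse = ""), i)
      i <- j
      next
    }
    if (grepl("[0-9]", ch)) {
      j <- i
      while (j <= n && grepl("[0-9.]", chars[[j]])) j <- j + 1L
      push("NUMBER", paste(chars[i:(j - 1L)], collapse = ""), i)
      i <- j
      next
    }
    if (ch == "'" || ch == '"') {
      quote_ch <- ch
      j <- i + 1L
      out <- character()
      while (j <= n && chars[[j]] != quote_ch) {
        if (chars[[j]] == "\\" && j < n) j <- j + 1L
        out <- c(out, chars[[j]])
        j <- j + 1L
      }
      if (j > n) stop_query_syntax(sprintf("unterminated string starting at position %d", i), i)
      push("STRING", paste(out, collapse = ""), i)
      i <- j + 1L
      next
    }
    if (ch == "<") {
      nxt <- if (i < n) chars[[i + 1L]] else ""
      if (nxt == "-") { push("PUNCT", "<-", i); i <- i + 2L; next }
      if (nxt == ">") { push("PUNCT", "<>", i); i <- i + 2L; next }
      stop_query_syntax(sprintf("unexpected '<' at position %d", i), i)
    }
    if (ch == "-") {
      nxt <- if (i < n) chars[[i + 1L]] else ""
      if (nxt == ">") { push("PUNCT", "->", i); i <- i + 2L; next }
      push("PUNCT", "-", i)
      i <- i + 1L
      next
    }
    if (ch %in% c("(", ")", "[", "]", "{", "}", ":", ",", ".", "=", ">")) {
      push("PUNCT", ch, i)
      i <- i + 1L
      next
    }
    stop_query_syntax(sprintf("unexpected character '%s' at position %d", ch, i), i)
  }
  toks
}

# Recursive-descent parser over the token stream. Returns the query AST.
cypher_parse <- function(query) {
  toks <- cypher_tokenize(query)
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$i <- 1L

  peek <- function() if (state$i <= length(state$toks)) state$toks[[state$i]] else NULL
  advance <- function() { t <- peek(); state$i <- state$i + 1L; t }
  at_kw <- function(kw) {
    t <- peek()
    !is.null(t) && t$type == "IDENT" && toupper(t$text) == kw
  }
  expect_kw <- function(kw) {
    if (!at_kw(kw)) {
      t <- peek()
      stop_query_syntax(sprintf(
        "expected %s at position %d", kw, if (is.null(t)) nchar(query) + 1L else t$pos
      ), if (is.null(t)) nchar(query) + 1L else t$pos)
    }
    advance()
  }
  at_punct <- function(p) {
    t <- peek()
    !is.null(t) && t$type == "PUNCT" && t$text == p
  }
  expect_punct <- function(p) {
    if (!at_punct(p)) {
      t <- peek()
      stop_query_syntax(sprintf(
        "expected '%s' at position %d", p, if (is.null(t)) nchar(query) + 1L else t$pos
      ), if (is.null(t)) nchar(query) + 1L else t$pos)
    }
    advance()
  }
  expect_ident <- function(what) {
    t <- peek()
    if (is.null(t) || t$type != "IDENT") {
      stop_query_syntax(sprintf(
        "expected %s at position %d", what, if (is.null(t)) nchar(query) + 1L else t$pos
      ), if (is.null(t)) nchar(query) + 1L else t$pos)
    }
    advance()$text
  }

  keywords <- c("MATCH", "WHERE", "RETURN", "DISTINCT", "LIMIT", "AND", "IN",
                "TRUE", "FALSE")
  anon_counter <- 0L
  fresh_var <- function() {
    anon_counter <<- anon_counter + 1L
    sprintf("..anon%d", anon_counter)
  }

  parse_literal <- function() {
    t <- peek()
    if (is.null(t)) stop_query_syntax("expected a literal at end of query", nchar(query) + 1L)
    if (t$type == "STRING") { advance(); return(t$text) }
    if (t$type == "NUMBER") { advance(); return(as.numeric(t$text)) }
    if (t$type == "PUNCT" && t$text == "-") {
      advance()
      t2 <- peek()
      if (is.null(t2) || t2$type != "NUMBER") {
        stop_query_syntax(sprintf("expected a number after '-' at position %d", t$pos), t$pos)
      }
      advance()
      return(-as.numeric(t2$text))
    }
    if (t$type == "IDENT" && toupper(t$text) %in% c("TRUE", "FALSE")) {
      advance()
      return(toupper(t$text) == "TRUE")
    }
    stop_query_syntax(sprintf("expected a literal at position %d", t$pos), t$pos)
  }

  parse_prop_map <- function() {
    expect_punct("{")
    props <- list()
    repeat {
      key <- expect_ident("a property key")
      expect_punct(":")
      props[[key]] <- parse_literal()
      if (at_punct(",")) { advance(); next }
      break
    }
    expect_punct("}")
    props
  }

  parse_node_pattern <- function() {
    expect_punct("(")
    var <- NA_character_
    label <- NA_character_
    props <- list()
    t <- peek()
    if (!is.null(t) && t$type == "IDENT" && !(toupper(t$text) %in% keywords)) {
      var <- advance()$text
    }
    if (at_punct(":")) {
      advance()
      label <- expect_ident("a node label")
    }
    if (at_punct("{")) props <- parse_prop_map()
    expect_punct(")")
    if (is.na(var)) var <- fresh_var()
    list(var = var, label = label, props = props)
  }

  parse_rel_pattern <- function() {
    # Directions: -[..]->  (out), <-[..]-  (in), -[..]-  (both)
    dir <- NULL
    if (at_punct("<-")) {
      advance()
      dir <- "in"
    } else {
      expect_punct("-")
    }
    expect_punct("[")
    var <- NA_character_
    type <- NA_character_
    t <- peek()
    if (!is.null(t) && t$type == "IDENT") var <- advance()$text
    if (at_punct(":")) {
      advance()
      type <- toupper(expect_ident("a relationship type"))
    }
    expect_punct("]")
    if (is.null(dir)) {
      if (at_punct("->")) { advance(); dir <- "out" }
      else { expect_punct("-"); dir <- "both" }
    } else {
      expect_punct("-")
    }
    if (is.na(var)) var <- fresh_var()
    list(var = var, type = type, dir = dir)
  }

  parse_operand <- function(pattern_vars) {
    t <- peek()
    if (!is.null(t) && t$type == "IDENT" && !(toupper(t$text) %in% keywords)) {
      var <- advance()$text
      if (!(var %in% pattern_vars)) {
        stop_query_syntax(sprintf(
          "variable '%s' at position %d is not bound in the MATCH pattern", var, t$pos
        ), t$pos)
      }
      if (at_punct(".")) {
        advance()
        key <- expect_ident("a property key")
        return(list(kind = "prop", var = var, key = key))
      }
      return(list(kind = "name", var = var))
    }
    list(kind = "lit", value = parse_literal())
  }

  parse_condition <- function(pattern_vars) {
    lhs <- parse_operand(pattern_vars)
    if (at_kw("IN")) {
      advance()
      expect_punct("[")
      vals <- list()
      if (!at_punct("]")) {
        repeat {
          vals[[length(vals) + 1L]] <- parse_literal()
          if (at_punct(",")) { advance(); next }
          break
        }
      }
      expect_punct("]")
      return(list(op = "in", lhs = lhs, rhs = vals))
    }
    if (at_punct("=")) {
      advance()
      return(list(op = "eq", lhs = lhs, rhs = parse_operand(pattern_vars)))
    }
    if (at_punct("<>")) {
      advance()
      return(list(op = "neq", lhs = lhs, rhs = parse_operand(pattern_vars)))
    }
    t <- peek()
    stop_query_syntax(sprintf(
      "expected =, <> or IN at position %d", if (is.null(t)) nchar(query) + 1L else t$pos
    ), if (is.null(t)) nchar(query) + 1L else t$pos)
  }

  # --- query level ---
  expect_kw("MATCH")
  nodes <- list(parse_node_pattern())
  rels <- list()
  while (at_punct("-") || at_punct("<-")) {
    if (length(rels) == 2L) {
      t <- peek()
      stop_query_syntax(sprintf(
        "patterns longer than two relationships are not supported (position %d)", t$pos
      ), t$pos)
    }
    rels[[length(rels) + 1L]] <- parse_rel_pattern()
    nodes[[length(nodes) + 1L]] <- parse_node_pattern()
  }
  node_vars <- vapply(nodes, `[[`, "", "var")
  where <- list()
  if (at_kw("WHERE")) {
    advance()
    repeat {
      where[[length(where) + 1L]] <- parse_condition(node_vars)
      if (at_kw("AND")) { advance(); next }
      break
    }
  }
  expect_kw("RETURN")
  distinct <- FALSE
  if (at_kw("DISTINCT")) { advance(); distinct <- TRUE }
  items <- list()
  repeat {
    t <- peek()
    var <- expect_ident("a return item")
    if (!(var %in% node_vars)) {
      stop_query_syntax(sprintf(
        "return variable '%s' at position %d is not bound in the MATCH pattern", var, t$pos
      ), t$pos)
    }
    if (at_punct(".")) {
      advance()
      key <- expect_ident("a property key")
      items[[length(items) + 1L]] <- list(var = var, key = key,
                                          colname = paste0(var, ".", key))
    } else {
      items[[length(items) + 1L]] <- list(var = var, key = NA_character_, colname = var)
    }
    if (at_punct(",")) { advance(); next }
    break
  }
  limit <- NA_integer_
  if (at_kw("LIMIT")) {
    advance()
    t <- peek()
    if (is.null(t) || t$type != "NUMBER") {
      stop_query_syntax(sprintf(
        "expected a number after LIMIT at position %d",
        if (is.null(t)) nchar(query) + 1L else t$pos
      ), if (is.null(t)) nchar(query) + 1L else t$pos)
    }
    advance()
    limit <- as.integer(as.numeric(t$text))
  }
  t <- peek()
  if (!is.null(t)) {
    stop_query_syntax(sprintf("unexpected trailing input at position %d", t$pos), t$pos)
  }
  list(nodes = nodes, rels = rels, where = where, items = items,
       distinct = distinct, limit = limit)
}
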