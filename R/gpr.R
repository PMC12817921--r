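# Gene-protein-reaction (GPR) rules as boolean expression trees.
#
# A GPR is a recursive list with an `op` field:
#   "leaf"  - a single gene id (field `gene`)
#   "and"   - an enzyme complex: all children required (field `children`, >= 2)
#   "or"    - isoforms: any child suffices (field `children`, >= 2)
#   "empty" - no gene requirement (the reaction is retained unconditionally)
#   "unsat" - unsatisfiable marker produced by substitution when a complex
#             loses a member; such reactions are removed during derivation.

new_gpr <- function(op, gene = NULL, children = NULL) {
  structure(list(op = op, gene = gene, children = children), class = "gpr")
}

#' Build GPR nodes
#'
#' Constructors for the five node types of a GPR boolean tree: a gene leaf,
#' an AND node (enzyme complex, all members required), an OR node (isoforms,
#' any member suffices), the empty GPR (no gene requirement), and the
#' unsatisfiable marker returned by [gpr_substitute()] when a complex loses
#' all support.
#'
#' @param gene Single non-empty gene id (no whitespace).
#' @param ... Child GPR nodes (at least two) for `gpr_and()` / `gpr_or()`.
#'   A single list of nodes may also be supplied.
#' @return A `gpr` object.
#' @examples
#' gpr_and(gpr_leaf("g1"), gpr_or(gpr_leaf("g2"), gpr_leaf("g3")))
#' @name gpr_nodes
NULL

#' @rdname gpr_nodes
#' @export
gpr_leaf <- function(gene) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene),
            !grepl("\\s", gene))
  new_gpr("leaf", gene = gene)
}

gpr_node_list <- function(...) {
  ch <- list(...)
  if (length(ch) == 1L && !inherits(ch[[1L]], "gpr")) ch <- ch[[1L]]
  stopifnot(all(vapply(ch, inherits, logical(1), "gpr")))
  ch
}

#' @rdname gpr_nodes
#' @export
gpr_and <- function(...) {
  ch <- gpr_node_list(...)
  if (length(ch) < 2L) stop("AND nodes need at least 2 children")
  new_gpr("and", children = ch)
}

#' @rdname gpr_nodes
#' @export
gpr_or <- function(...) {
  ch <- gpr_node_list(...)
  if (length(ch) < 2L) stop("OR nodes need at least 2 children")
  new_gpr("or", children = ch)
}

#' @rdname gpr_nodes
#' @export
gpr_empty <- function() new_gpr("empty")

#' @rdname gpr_nodes
#' @export
gpr_unsat <- function() new_gpr("unsat")

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", if (x$op == "unsat") "UNSATISFIABLE" else gpr_serialize(x),
      "\n", sep = "")
  invisible(x)
}

is_gpr <- function(x) inherits(x, "gpr")

#' Test whether a GPR is the empty rule or the unsatisfiable marker
#' @param gpr A `gpr` object.
#' @return Logical scalar.
#' @export
gpr_is_empty <- function(gpr) is_gpr(gpr) && gpr$op == "empty"

#' @rdname gpr_is_empty
#' @export
gpr_is_unsat <- function(gpr) is_gpr(gpr) && gpr$op == "unsat"

#' List the gene ids appearing in a GPR
#' @param gpr A `gpr` object.
#' @return Character vector of unique gene ids (empty for EMPTY/UNSAT rules).
#' @export
gpr_genes <- function(gpr) {
  stopifnot(is_gpr(gpr))
  switch(gpr$op,
    leaf = gpr$gene,
    and = ,
    or = unique(unlist(lapply(gpr$children, gpr_genes))),
    character(0)
  )
}

# ---- parsing ----------------------------------------------------------------

gpr_tokenize <- function(text) {
  # returns tibble(token, pos); "and"/"or" matched case-insensitively
  pat <- "\\(|\\)|[^()\\s]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(data.frame(token = character(0), pos = integer(0)))
  data.frame(
    token = regmatches(text, gregexpr(pat, text, perl = TRUE))[[1L]],
    pos = as.integer(m),
    stringsAsFactors = FALSE
  )
}

gpr_parse_error <- function(msg, pos) {
  stop(sprintf("GPR parse error at position %d: %s", pos, msg), call. = FALSE)
}

#' Parse a GPR string into a boolean tree
#'
#' Grammar: `expr := term ('or' term)*`, `term := factor ('and' factor)*`,
#' `factor := '(' expr ')' | gene`. `and` binds tighter than `or`; both
#' keywords are matched case-insensitively. Gene ids are any whitespace-free
#' tokens other than parentheses and the two keywords. The empty (or
#' all-whitespace) string parses to the EMPTY rule. Chains of the same
#' operator are flattened into one n-ary node.
#'
#' @param text GPR string, e.g. `"g1 and (g2 or g3)"`.
#' @return A `gpr` object.
#' @seealso [gpr_serialize()] for the inverse.
#' @export
gpr_parse <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(gpr_empty())
  toks <- gpr_tokenize(text)
  i <- 1L
  n <- nrow(toks)
  peek <- function() if (i <= n) toks$token[i] else NA_character_
  pos <- function() if (i <= n) toks$pos[i] else nchar(text) + 1L
  advance <- function() i <<- i + 1L
  is_kw <- function(tok, kw) !is.na(tok) && tolower(tok) == kw

  parse_expr <- function() {
    terms <- list(parse_term())
    while (is_kw(peek(), "or")) {
      advance()
      terms <- c(terms, list(parse_term()))
    }
    if (length(terms) == 1L) terms[[1L]] else flatten_op("or", terms)
  }
  parse_term <- function() {
    factors <- list(parse_factor())
    while (is_kw(peek(), "and")) {
      advance()
      factors <- c(factors, list(parse_factor()))
    }
    if (length(factors) == 1L) factors[[1L]] else flatten_op("and", factors)
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.na(tok)) gpr_parse_error("unexpected end of input", pos())
    if (tok == "(") {
      advance()
      node <- parse_expr()
      if (!identical(peek(), ")")) {
        gpr_parse_error(sprintf("expected ')' but found '%s'",
                                ifelse(is.na(peek()), "end of input", peek())),
                        pos())
      }
      advance()
      return(node)
    }
    if (tok == ")" || is_kw(tok, "and") || is_kw(tok, "or")) {
      gpr_parse_error(sprintf("unexpected token '%s'", tok), pos())
    }
    advance()
    gpr_leaf(tok)
  }
  flatten_op <- function(op, nodes) {
    flat <- list()
    for (nd in nodes) {
      if (nd$op == op) flat <- c(flat, nd$children) else flat <- c(flat, list(nd))
    }
    new_gpr(op, children = flat)
  }

  out <- parse_expr()
  if (i <= n) gpr_parse_error(sprintf("unexpected token '%s'", peek()), pos())
  out
}

#' Serialize a GPR tree to its string form
#'
#' Inverse of [gpr_parse()]: `gpr_parse(gpr_serialize(g))` is structurally
#' identical to `g` for any tree in which AND/OR nodes have two or more
#' children and same-operator nodes are not directly nested. The EMPTY rule
#' serializes to `""`. The UNSATISFIABLE marker has no string form and is an
#' error to serialize.
#'
#' @param gpr A `gpr` object.
#' @return A single string.
#' @export
gpr_serialize <- function(gpr) {
  stopifnot(is_gpr(gpr))
  ser <- function(g, parent_op) {
    switch(g$op,
      empty = "",
      unsat = stop("the UNSATISFIABLE marker cannot be serialized", call. = FALSE),
      leaf = g$gene,
      and = {
        s <- paste(vapply(g$children, ser, character(1), parent_op = "and"),
                   collapse = " and ")
        if (parent_op == "or") s else s
      },
      or = {
        s <- paste(vapply(g$children, ser, character(1), parent_op = "or"),
                   collapse = " or ")
        if (parent_op == "and") paste0("(", s, ")") else s
      }
    )
  }
  ser(gpr, parent_op = "top")
}

# ---- evaluation and substitution -------------------------------------------

#' Evaluate a GPR against a set of present genes
#'
#' The EMPTY rule evaluates `TRUE` (no gene requirement blocks retention);
#' the UNSATISFIABLE marker evaluates `FALSE`. AND is true iff all children
#' are true, OR iff any child is.
#'
#' @param gpr A `gpr` object.
#' @param present Character vector of gene ids deemed present.
#' @return Logical scalar.
#' @examples
#' gpr_evaluate(gpr_parse("g1 and (g2 or g3)"), c("g1", "g3"))
#' @export
gpr_evaluate <- function(gpr, present) {
  stopifnot(is_gpr(gpr))
  switch(gpr$op,
    empty = TRUE,
    unsat = FALSE,
    leaf = gpr$gene %in% present,
    and = all(vapply(gpr$children, gpr_evaluate, logical(1), present = present)),
    or = any(vapply(gpr$children, gpr_evaluate, logical(1), present = present))
  )
}

#' Substitute GPR leaves by replacement gene sets
#'
#' Each leaf found in `mapping` is replaced by the OR of its replacement
#' genes; an empty replacement set makes the leaf false. Leaves absent from
#' `mapping` are kept unchanged. The result is simplified: false children are
#' pruned from OR nodes and propagate through AND nodes, single-child nodes
#' collapse, and a tree that is false everywhere becomes the UNSATISFIABLE
#' marker ([gpr_unsat()]).
#'
#' @param gpr A `gpr` object.
#' @param mapping Named list: gene id -> character vector of replacement gene
#'   ids (possibly `character(0)`).
#' @return A simplified `gpr` object (possibly the UNSAT marker).
#' @examples
#' gpr_substitute(gpr_parse("C1 and C2"), list(C1 = c("gA", "gB"), C2 = character(0)))
#' @export
gpr_substitute <- function(gpr, mapping) {
  stopifnot(is_gpr(gpr), is.list(mapping))
  sub <- function(g) {
    switch(g$op,
      empty = g,
      unsat = g,
      leaf = {
        if (!g$gene %in% names(mapping)) return(g)
        repl <- unique(as.character(mapping[[g$gene]]))
        if (length(repl) == 0L) gpr_unsat()
        else if (length(repl) == 1L) gpr_leaf(repl)
        else new_gpr("or", children = lapply(repl, gpr_leaf))
      },
      and = {
        ch <- lapply(g$children, sub)
        if (any(vapply(ch, gpr_is_unsat, logical(1)))) return(gpr_unsat())
        ch <- ch[!vapply(ch, gpr_is_empty, logical(1))]
        if (length(ch) == 0L) gpr_empty()
        else if (length(ch) == 1L) ch[[1L]]
        else new_gpr("and", children = ch)
      },
      or = {
        ch <- lapply(g$children, sub)
        if (any(vapply(ch, gpr_is_empty, logical(1)))) return(gpr_empty())
        ch <- ch[!vapply(ch, gpr_is_unsat, logical(1))]
        if (length(ch) == 0L) gpr_unsat()
        else if (length(ch) == 1L) ch[[1L]]
        else new_gpr("or", children = ch)
      }
    )
  }
  sub(gpr)
}

# Structural equality of two GPR trees (same ops, order-sensitive children).
gpr_identical <- function(a, b) {
  if (a$op != b$op) return(FALSE)
  if (a$op == "leaf") return(identical(a$gene, b$gene))
  if (a$op %in% c("empty", "unsat")) return(TRUE)
  if (length(a$children) != length(b$children)) return(FALSE)
  all(mapply(gpr_identical, a$children, b$children))
}
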