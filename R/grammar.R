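## Boolean algebra-like module-definition grammar
##
## A KEGG-style module definition is a Boolean expression over KO (KEGG
## Orthology) identifiers: space-delimited items are consecutive pathway
## elements ("and"), comma-separated items are alternatives ("or"), a plus
## sign joins subunits of a complex ("and") and a minus sign flags an
## optional item.  Precedence, tightest to loosest:
##   parentheses > "-" (optional) > "+" (complex) > "," (alternatives) > space
##
## The AST is a plain list with class "module_expr":
##   kind     : "ko" | "optional" | "complex" | "alt" | "seq"
##   children : list of module_expr (internal nodes; >= 2, optional exactly 1)
##   ko       : the identifier (leaves only)
##   grouped  : complex nodes only; TRUE when the complex was written in
##              parentheses.  A grouped complex inside a pathway step is one
##              counting block; a bare top-level plus-chain contributes one
##              block per subunit (structural-complex modules).

KO_REGEX <- "^K[0-9]{5}$"

#' Test whether strings are well-formed KO identifiers
#'
#' A KO (KEGG Orthology) identifier is an uppercase "K" followed by exactly
#' five digits, e.g. `"K00134"`.
#'
#' @param x character vector.
#' @return logical vector.
#' @export
is_ko_id <- function(x) {
  !is.na(x) & grepl(KO_REGEX, x)
}

ko_leaf <- function(id) {
  structure(list(kind = "ko", ko = id), class = "module_expr")
}

expr_node <- function(kind, children, grouped = FALSE) {
  node <- list(kind = kind, children = children)
  if (kind == "complex") node$grouped <- grouped
  structure(node, class = "module_expr")
}

## ---- tokenizer -------------------------------------------------------------

## Tokens: KO, "(", ")", ",", "+", "-", SP.  Runs of whitespace collapse to a
## single SP; SP adjacent to an operator (or an opening paren) is cosmetic and
## dropped, so "A , B" and "A,B" tokenize identically while "(...) K" keeps
## its step separator.
tokenize_definition <- function(text) {
  if (!is_string(text) || !nzchar(trimws(text))) {
    mc_stop("empty module definition", class = "modcomp_parse_error")
  }
  pat <- "[A-Za-z0-9_.]+|[(),+-]|[ \t]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  pieces <- regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]
  covered <- sum(attr(m, "match.length"))
  if (covered != nchar(text)) {
    # locate first uncovered character
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    pos <- 1L
    for (i in seq_along(m)) {
      if (as.integer(m)[i] > pos) break
      pos <- ends[i] + 1L
    }
    mc_stop("unexpected character '", substr(text, pos, pos),
            "' at position ", pos, class = "modcomp_parse_error")
  }
  type <- character(length(pieces))
  for (i in seq_along(pieces)) {
    p <- pieces[i]
    if (grepl("^[ \t]+$", p)) {
      type[i] <- "SP"
    } else if (p %in% c("(", ")", ",", "+", "-")) {
      type[i] <- p
    } else {
      if (!grepl(KO_REGEX, p)) {
        mc_stop("malformed KO identifier '", p, "' at position ",
                as.integer(m)[i], class = "modcomp_parse_error")
      }
      type[i] <- "KO"
    }
  }
  keep <- rep(TRUE, length(pieces))
  for (i in seq_along(pieces)) {
    if (type[i] != "SP") next
    prev <- if (i > 1L) type[i - 1L] else "^"
    nxt <- if (i < length(pieces)) type[i + 1L] else "$"
    if (prev %in% c("^", "(", ",", "+", "-") ||
        nxt %in% c("$", ")", ",", "+")) {
      keep[i] <- FALSE
    }
  }
  list(type = type[keep], text = pieces[keep], pos = as.integer(m)[keep])
}

## ---- recursive-descent parser ---------------------------------------------

#' Parse a module definition string
#'
#' Parses the Boolean algebra-like definition notation into an expression
#' tree.  Space-delimited items are sequential pathway elements,
#' comma-separated items (usually parenthesised) are alternatives, `+` joins
#' the subunits of a complex and `-` marks the immediately following item as
#' optional.
#'
#' @param text a single definition string, e.g.
#'   `"(K00001,K00002) K00003"`.
#' @return a `module_expr` tree.
#' @seealso [serialize_expression()], [top_level_blocks()]
#' @export
#' @examples
#' parse_definition("(K01652+K01653+K11258) K00052")
parse_definition <- function(text) {
  tok <- tokenize_definition(text)
  st <- new.env(parent = emptyenv())
  st$i <- 1L
  st$tok <- tok
  st$n <- length(tok$type)

  peek <- function() if (st$i <= st$n) st$tok$type[st$i] else "$"
  pos_here <- function() {
    if (st$i <= st$n) st$tok$pos[st$i] else nchar(text) + 1L
  }
  advance <- function() st$i <- st$i + 1L

  parse_primary <- function() {
    t <- peek()
    if (t == "KO") {
      node <- ko_leaf(st$tok$text[st$i])
      advance()
      return(node)
    }
    if (t == "(") {
      advance()
      inner <- parse_sequence()
      if (peek() != ")") {
        mc_stop("unbalanced parentheses: expected ')' at position ",
                pos_here(), class = "modcomp_parse_error")
      }
      advance()
      # parentheses only persist on complexes, where they change block counting
      if (inner$kind == "complex") inner$grouped <- TRUE
      return(inner)
    }
    if (t %in% c(")", ",", "+", "-", "SP")) {
      mc_stop("dangling operator or empty item at position ", pos_here(),
              class = "modcomp_parse_error")
    }
    mc_stop("unexpected end of definition", class = "modcomp_parse_error")
  }

  parse_optional <- function() {
    if (peek() == "-") {
      advance()
      expr_node("optional", list(parse_primary()))
    } else {
      parse_primary()
    }
  }

  # "+" members; "-item" directly attached (K1+K2-K3) is an optional member
  parse_complex <- function() {
    parts <- list(parse_optional())
    while (peek() %in% c("+", "-")) {
      op <- peek()
      advance()
      child <- if (op == "-") expr_node("optional", list(parse_primary()))
               else parse_optional()
      parts <- c(parts, list(child))
    }
    if (length(parts) == 1L) parts[[1L]] else expr_node("complex", parts)
  }

  parse_alt <- function() {
    parts <- list(parse_complex())
    while (peek() == ",") {
      advance()
      if (peek() %in% c(",", ")", "$", "SP")) {
        mc_stop("empty alternative at position ", pos_here(),
                class = "modcomp_parse_error")
      }
      parts <- c(parts, list(parse_complex()))
    }
    if (length(parts) == 1L) parts[[1L]] else expr_node("alt", parts)
  }

  parse_sequence <- function() {
    parts <- list(parse_alt())
    while (peek() == "SP") {
      advance()
      parts <- c(parts, list(parse_alt()))
    }
    if (length(parts) == 1L) parts[[1L]] else expr_node("seq", parts)
  }

  out <- parse_sequence()
  if (st$i <= st$n) {
    mc_stop("unexpected token '", st$tok$text[st$i], "' at position ",
            pos_here(), class = "modcomp_parse_error")
  }
  out
}

## ---- serializer ------------------------------------------------------------

expr_precedence <- function(kind) {
  switch(kind, seq = 0L, alt = 1L, complex = 2L, optional = 3L, ko = 4L)
}

format_expr <- function(e, min_prec = 0L) {
  out <- switch(e$kind,
    ko = e$ko,
    optional = paste0("-", format_expr(e$children[[1L]], 3L)),
    complex = {
      s <- paste(vapply(e$children, format_expr, "", min_prec = 3L),
                 collapse = "+")
      if (isTRUE(e$grouped)) paste0("(", s, ")") else s
    },
    alt = paste(vapply(e$children, format_expr, "", min_prec = 2L),
                collapse = ","),
    seq = paste(vapply(e$children, format_expr, "", min_prec = 2L),
                collapse = " "),
    mc_stop("unknown expression kind '", e$kind, "'")
  )
  if (isTRUE(e$grouped) && e$kind == "complex") {
    return(out) # already parenthesised
  }
  if (expr_precedence(e$kind) < min_prec) paste0("(", out, ")") else out
}

#' Serialize an expression tree back to definition notation
#'
#' Produces the canonical text form: alternatives regain parentheses inside
#' sequences, parenthesised complexes keep them, and redundant whitespace and
#' parentheses are normalised away.  `parse_definition(serialize_expression(e))`
#' is structurally identical to `e`.
#'
#' @param expr a `module_expr`.
#' @return a single definition string.
#' @export
serialize_expression <- function(expr) {
  stopifnot(inherits(expr, "module_expr"))
  format_expr(expr, 0L)
}

#' @export
format.module_expr <- function(x, ...) serialize_expression(x)

#' @export
print.module_expr <- function(x, ...) {
  cat("<module_expr> ", serialize_expression(x), "\n", sep = "")
  invisible(x)
}

#' Extract all KO identifiers appearing in an expression
#'
#' @param expr a `module_expr`.
#' @return character vector of unique KO ids, in first-appearance order.
#' @export
expression_kos <- function(expr) {
  stopifnot(inherits(expr, "module_expr"))
  walk <- function(e) {
    if (e$kind == "ko") return(e$ko)
    unlist(lapply(e$children, walk))
  }
  unique(walk(expr))
}

## internal structural validator for hand-built ASTs
validate_expression <- function(e) {
  if (!inherits(e, "module_expr")) mc_stop("not a module_expr")
  if (e$kind == "ko") {
    if (!is_ko_id(e$ko)) mc_stop("invalid KO leaf '", e$ko, "'")
    return(invisible(TRUE))
  }
  n <- length(e$children)
  if (e$kind == "optional" && n != 1L) {
    mc_stop("optional node must have exactly 1 child")
  }
  if (e$kind != "optional" && n < 2L) {
    mc_stop(e$kind, " node must have >= 2 children")
  }
  for (ch in e$children) validate_expression(ch)
  invisible(TRUE)
}

## ---- module definitions ----------------------------------------------------

MODULE_TYPES <- c("pathway", "complex", "functional_set", "signature")

#' Construct a module definition
#'
#' @param module_id module identifier with submodule suffix, e.g. `"M00009_1"`.
#' @param definition either a definition string or a pre-parsed `module_expr`.
#' @param module_type one of `"pathway"`, `"complex"`, `"functional_set"`,
#'   `"signature"`.
#' @param name free-text module name.
#' @param category free-text functional category.
#' @return a `module_definition` object.
#' @export
#' @examples
#' m <- module_definition("M00002_1", "K90201 (K00134,K00150) K90202",
#'                        name = "glycolysis core (toy)")
#' n_blocks(m)
module_definition <- function(module_id, definition,
                              module_type = "pathway",
                              name = "", category = "") {
  if (!is_string(module_id) || !grepl("^M[0-9]{5}(_[0-9]+)?$", module_id)) {
    mc_stop("invalid module id '", module_id,
            "': expected M##### with optional _k suffix")
  }
  module_type <- match.arg(module_type, MODULE_TYPES)
  expr <- if (inherits(definition, "module_expr")) {
    validate_expression(definition)
    definition
  } else {
    parse_definition(definition)
  }
  m <- structure(
    list(module_id = module_id, name = name, module_type = module_type,
         category = category, expression = expr),
    class = "module_definition")
  # a module must decompose into at least one non-optional counting block
  top_level_blocks(m)
  m
}

#' @export
print.module_definition <- function(x, ...) {
  cat("<module_definition> ", x$module_id,
      if (nzchar(x$name)) paste0(" (", x$name, ")"), "\n",
      "  type: ", x$module_type,
      "  blocks: ", n_blocks(x), "\n",
      "  ", serialize_expression(x$expression), "\n", sep = "")
  invisible(x)
}

#' Decompose a module into its counting blocks
#'
#' Blocks are the units of the completion-ratio denominator: the top-level
#' space-delimited items of a pathway definition plus, for bare top-level
#' plus-chains (structural complexes), each subunit individually.  Optional
#' (`-`) items are excluded.  A parenthesised complex inside a pathway step
#' stays a single block.
#'
#' @param module a `module_definition` (or a raw `module_expr`).
#' @return list of `module_expr` blocks, in definition order.
#' @export
top_level_blocks <- function(module) {
  expr <- if (inherits(module, "module_definition")) module$expression
          else module
  stopifnot(inherits(expr, "module_expr"))
  items <- if (expr$kind == "seq") expr$children else list(expr)
  blocks <- list()
  for (item in items) {
    if (item$kind == "optional") next
    if (item$kind == "complex" && !isTRUE(item$grouped)) {
      for (ch in item$children) {
        if (ch$kind != "optional") blocks <- c(blocks, list(ch))
      }
    } else {
      blocks <- c(blocks, list(item))
    }
  }
  if (length(blocks) == 0L) {
    mc_stop("invalid module: no non-optional blocks",
            class = "modcomp_invalid_module")
  }
  blocks
}

#' Number of counting blocks of a module
#'
#' @param module a `module_definition` or `module_expr`.
#' @return integer block count.
#' @export
n_blocks <- function(module) length(top_level_blocks(module))

#' Bundle module definitions into a collection
#'
#' @param ... `module_definition` objects or lists of them.
#' @return a `module_collection` (named list keyed by module id).
#' @export
module_collection <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && !inherits(mods[[1L]], "module_definition")) {
    mods <- mods[[1L]]
  }
  ok <- vapply(mods, inherits, TRUE, what = "module_definition")
  if (!all(ok)) mc_stop("all elements must be module_definition objects")
  ids <- vapply(mods, `[[`, "", "module_id")
  if (anyDuplicated(ids)) {
    mc_stop("duplicate module ids: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(mods) <- ids
  structure(mods, class = "module_collection")
}

#' @export
print.module_collection <- function(x, ...) {
  cat("<module_collection> ", length(x), " modules\n", sep = "")
  for (m in x) {
    cat(sprintf("  %-10s %-14s %2d blocks  %s\n",
                m$module_id, m$module_type, n_blocks(m), m$name))
  }
  invisible(x)
}

#' @export
`[.module_collection` <- function(x, i) {
  structure(NextMethod(), class = "module_collection")
}

#' All KO identifiers used across a module collection
#'
#' @param modules a `module_collection`.
#' @return character vector of unique KO ids.
#' @export
collection_kos <- function(modules) {
  stopifnot(inherits(modules, "module_collection"))
  unique(unlist(lapply(modules, function(m) expression_kos(m$expression))))
}
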