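# Gene-protein-reaction rules: boolean AND/OR expressions over gene ids.
# OR separates isozyme alternatives; AND groups subunits of a complex.

# Tokenize a rule string. Accepts and/or (case-insensitive), &/&&, |/||,
# parentheses; gene ids are any other non-space runs.
tokenize_rule <- function(rule) {
  rule <- gsub("&&|&", " and ", rule)
  rule <- gsub("\\|\\||\\|", " or ", rule)
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a gene rule into an AST
#'
#' Recursive-descent parse of a boolean AND/OR expression with parentheses.
#' AND binds tighter than OR.
#'
#' @param rule gene rule string, e.g. `"(G1 and G2) or G3"`.
#' @return Nested list AST: `list(op = "and"|"or", args = ...)` or a gene id.
#' @export
parse_gene_rule <- function(rule) {
  toks <- tokenize_rule(rule)
  if (!length(toks)) return(NULL)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- toks[pos]; pos <<- pos + 1L; t
  }
  fail <- function() stop("unparseable gene rule: '", rule, "'", call. = FALSE)
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) fail()
    if (t == "(") {
      advance()
      e <- parse_expr()
      if (is.na(peek()) || peek() != ")") fail()
      advance()
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) fail()
    advance()
  }
  out <- parse_expr()
  if (pos <= length(toks)) fail()
  out
}

#' Disjunctive normal form of a gene rule
#'
#' Normalizes an arbitrary AND/OR rule to a list of AND-sets: each element is
#' a sorted character vector of gene ids that must be jointly present (one
#' catalytic unit); the units are alternatives. Duplicate units are removed.
#'
#' @param rule gene rule string (or an AST from [parse_gene_rule()]).
#' @return List of character vectors; empty list for an empty rule.
#' @export
gene_rule_dnf <- function(rule) {
  ast <- if (is.character(rule)) parse_gene_rule(rule) else rule
  if (is.null(ast)) return(list())
  expand <- function(node) {
    if (is.character(node)) return(list(node))
    if (node$op == "or") {
      return(do.call(c, lapply(node$args, expand)))
    }
    # and: cartesian product of the args' DNFs
    parts <- lapply(node$args, expand)
    out <- list(character(0))
    for (p in parts) {
      out <- do.call(c, lapply(out, function(acc)
        lapply(p, function(conj) union(acc, conj))))
    }
    out
  }
  units <- lapply(expand(ast), function(x) sort(unique(x)))
  unique(units)
}

# Render a DNF (list of AND-sets) back to a rule string.
dnf_to_rule <- function(dnf) {
  if (!length(dnf)) return("")
  terms <- vapply(dnf, function(u) {
    s <- paste(u, collapse = " and ")
    if (length(u) > 1 && length(dnf) > 1) paste0("(", s, ")") else s
  }, character(1))
  paste(terms, collapse = " or ")
}
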