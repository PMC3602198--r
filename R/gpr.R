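#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers that state which
#' gene products a reaction requires: `"and"` encodes enzyme complexes (all
#' subunits needed), `"or"` encodes isozymes (any one suffices). An empty or
#' blank rule denotes a spontaneous / gene-independent reaction and parses to
#' an always-active leaf.
#'
#' The grammar is the usual one: `expr := term ("or" term)*`,
#' `term := factor ("and" factor)*`, `factor := gene | "(" expr ")"`, with
#' case-insensitive keywords and gene tokens matching
#' `[A-Za-z0-9_.:-]+`.
#'
#' @param text Character scalar with the rule, e.g. `"(g1 or g2) and g3"`.
#' @return An object of class `gpr_tree`: a nested list with elements
#'   `kind` (one of `"GENE"`, `"AND"`, `"OR"`, `"ALWAYS_ACTIVE"`), `gene`
#'   (for `GENE` leaves) and `children` (for `AND`/`OR` nodes, always >= 2).
#' @examples
#' parse_gpr("ldhA")
#' parse_gpr("(budB or budA) and budC")
#' parse_gpr("")  # spontaneous
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L || is.na(text[1L]) ||
      !nzchar(trimws(text[1L]))) {
    return(structure(list(kind = "ALWAYS_ACTIVE"), class = "gpr_tree"))
  }
  text <- text[1L]
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st, text)
  if (st$pos <= nrow(st$toks)) {
    stop(sprintf("GPR parse error at offset %d: unexpected token '%s'",
                 st$toks$offset[st$pos], st$toks$value[st$pos]), call. = FALSE)
  }
  class(tree) <- "gpr_tree"
  tree
}

gpr_tokenize <- function(text) {
  value <- character()
  type <- character()
  offset <- integer()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(" || ch == ")") {
      value <- c(value, ch); type <- c(type, ch); offset <- c(offset, i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(text, i, n),
                    regexpr("^[A-Za-z0-9_.:-]+", substr(text, i, n)))
    if (length(m) == 0L) {
      stop(sprintf("GPR parse error at offset %d: unexpected character '%s'",
                   i, ch), call. = FALSE)
    }
    tk <- m[1L]
    lt <- tolower(tk)
    value <- c(value, tk)
    type <- c(type, if (lt %in% c("and", "or")) lt else "gene")
    offset <- c(offset, i)
    i <- i + nchar(tk)
  }
  data.frame(value = value, type = type, offset = offset,
             stringsAsFactors = FALSE)
}

gpr_peek <- function(st) {
  if (st$pos > nrow(st$toks)) NULL else st$toks[st$pos, ]
}

gpr_parse_or <- function(st, text) {
  children <- list(gpr_parse_and(st, text))
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "or") break
    st$pos <- st$pos + 1L
    children <- c(children, list(gpr_parse_and(st, text)))
  }
  if (length(children) == 1L) children[[1L]]
  else list(kind = "OR", children = children)
}

gpr_parse_and <- function(st, text) {
  children <- list(gpr_parse_factor(st, text))
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "and") break
    st$pos <- st$pos + 1L
    children <- c(children, list(gpr_parse_factor(st, text)))
  }
  if (length(children) == 1L) children[[1L]]
  else list(kind = "AND", children = children)
}

gpr_parse_factor <- function(st, text) {
  tk <- gpr_peek(st)
  if (is.null(tk)) {
    stop(sprintf("GPR parse error at offset %d: dangling operator",
                 nchar(text) + 1L), call. = FALSE)
  }
  if (tk$type == "(") {
    open_off <- tk$offset
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st, text)
    cl <- gpr_peek(st)
    if (is.null(cl) || cl$type != ")") {
      stop(sprintf("GPR parse error at offset %d: unbalanced parenthesis",
                   open_off), call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk$type != "gene") {
    stop(sprintf("GPR parse error at offset %d: unexpected token '%s'",
                 tk$offset, tk$value), call. = FALSE)
  }
  st$pos <- st$pos + 1L
  list(kind = "GENE", gene = tk$value)
}

#' Evaluate a GPR tree under a gene deletion
#'
#' A `GENE` leaf is active iff the gene is not deleted; `AND` requires all
#' children active, `OR` any child; `ALWAYS_ACTIVE` is always active. This is
#' the deletion semantics used by single-gene knockout simulation: reactions
#' whose rule evaluates to `FALSE` lose all flux capacity.
#'
#' @param tree A `gpr_tree` from [parse_gpr()].
#' @param deleted Character vector of deleted gene ids.
#' @return Logical scalar.
#' @examples
#' gpr_active(parse_gpr("g1 and g2"), "g1")  # FALSE: complex broken
#' gpr_active(parse_gpr("g1 or g2"), "g1")   # TRUE: isozyme retained
#' @export
gpr_active <- function(tree, deleted = character()) {
  switch(tree$kind,
    ALWAYS_ACTIVE = TRUE,
    GENE = !(tree$gene %in% deleted),
    AND = all(vapply(tree$children, gpr_active, logical(1L), deleted = deleted)),
    OR = any(vapply(tree$children, gpr_active, logical(1L), deleted = deleted)),
    stop("malformed GPR tree node kind: ", tree$kind)
  )
}

#' Genes referenced by a GPR tree
#' @param tree A `gpr_tree`.
#' @return Character vector of gene ids (unique, in order of appearance).
#' @export
gpr_genes <- function(tree) {
  if (tree$kind == "GENE") return(tree$gene)
  if (tree$kind %in% c("AND", "OR")) {
    return(unique(unlist(lapply(tree$children, gpr_genes))))
  }
  character()
}

#' Render a GPR tree back to normalized rule text
#' @param tree A `gpr_tree`.
#' @return Character scalar; `""` for an always-active rule.
#' @export
gpr_to_text <- function(tree) {
  render <- function(node, parent_kind) {
    if (node$kind == "GENE") return(node$gene)
    if (node$kind == "ALWAYS_ACTIVE") return("")
    op <- if (node$kind == "AND") " and " else " or "
    body <- paste(vapply(node$children, render, character(1L),
                         parent_kind = node$kind), collapse = op)
    need_paren <- (node$kind == "OR" && identical(parent_kind, "AND"))
    if (need_paren) paste0("(", body, ")") else body
  }
  render(tree, NA_character_)
}

#' @export
print.gpr_tree <- function(x, ...) {
  txt <- gpr_to_text(x)
  cat("<gpr_tree> ", if (nzchar(txt)) txt else "(always active)", "\n", sep = "")
  invisible(x)
}
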