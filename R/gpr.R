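## Boolean gene-protein-reaction rules. Grammar: OR-list of AND-terms with
## parentheses; AND binds tighter than OR. Isozymes are OR, complexes AND.
## Rules are stored as strings, e.g. "(g1 and g2) or g3"; empty string
## means no gene association (orphan reaction).

gprTokenize <- function(rule) {
  rule <- gsub("\\(", " ( ", rule)
  rule <- gsub("\\)", " ) ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

## Recursive-descent parse into nested list: list(op="or"/"and"/"gene", ...)
gprParse <- function(rule) {
  toks <- gprTokenize(rule)
  if (!length(toks)) return(NULL)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parseOr <- function() {
    left <- parseAnd()
    terms <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      terms <- c(terms, list(parseAnd()))
    }
    if (length(terms) == 1) left else list(op = "or", args = terms)
  }
  parseAnd <- function() {
    left <- parseAtom()
    terms <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      terms <- c(terms, list(parseAtom()))
    }
    if (length(terms) == 1) left else list(op = "and", args = terms)
  }
  parseAtom <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR parse error: unexpected end of rule: ", rule)
    if (t == "(") {
      advance()
      e <- parseOr()
      if (is.na(peek()) || peek() != ")")
        stop("GPR parse error: missing ')' in: ", rule)
      advance()
      e
    } else if (t == ")") {
      stop("GPR parse error: unexpected ')' in: ", rule)
    } else {
      advance()
      list(op = "gene", id = t)
    }
  }
  out <- parseOr()
  if (pos <= length(toks))
    stop("GPR parse error: trailing tokens in: ", rule)
  out
}

gprEvalTree <- function(tree, present) {
  if (is.null(tree)) return(NA)  # orphan: no statement
  switch(tree$op,
    gene = tree$id %in% present,
    and = all(vapply(tree$args, gprEvalTree, logical(1), present = present)),
    or = any(vapply(tree$args, gprEvalTree, logical(1), present = present)),
    stop("bad GPR node"))
}

#' Evaluate a GPR rule against a set of present genes
#'
#' AND binds tighter than OR; parentheses are honored. An empty rule
#' (orphan reaction) evaluates to `NA`.
#'
#' @param rule character GPR rule, e.g. `"(g1 and g2) or g3"`.
#' @param presentGenes character vector of gene ids considered present.
#' @return logical (`NA` for an empty rule).
#' @examples
#' evalGpr("(g1 and g2) or g3", "g3")   # TRUE
#' evalGpr("g1 and g2", "g1")           # FALSE
#' @export
evalGpr <- function(rule, presentGenes) {
  gprEvalTree(gprParse(rule), presentGenes)
}

## All gene ids mentioned in a rule.
gprGenes <- function(rule) {
  toks <- gprTokenize(rule)
  toks[!(tolower(toks) %in% c("and", "or", "(", ")")) & toks != "(" &
         toks != ")"]
}
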