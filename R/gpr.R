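#' Gene-protein-reaction boolean rules
#'
#' A GPR is a boolean expression over gene identifiers with `AND`
#' (enzyme complex) and `OR` (isozymes) connectives and parentheses;
#' keywords are case-insensitive. The empty rule means a spontaneous
#' reaction that no knockout can disable.
#'
#' @param gpr GPR string, e.g. `"(g1 AND g2) OR g3"`.
#' @return `parse_gpr()`: a parse tree; leaves are gene ids, internal
#'   nodes are `list(op = "and"/"or", args = ...)`. `NULL` for the
#'   empty rule.
#' @export
parse_gpr <- function(gpr) {
  if (is.null(gpr) || is.na(gpr) || !nzchar(trimws(gpr))) return(NULL)
  tokens <- regmatches(gpr, gregexpr("\\(|\\)|[^()[:space:]]+", gpr))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) == kw
  parse_or <- function() {
    args <- list(parse_and())
    while (is_kw(peek(), "or")) { take(); args <- c(args, list(parse_and())) }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (is_kw(peek(), "and")) { take(); args <- c(args, list(parse_atom())) }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- take()
    if (is.na(t)) stop("malformed GPR (unexpected end): ", gpr)
    if (t == "(") {
      e <- parse_or()
      if (!identical(take(), ")")) stop("malformed GPR (missing ')'): ", gpr)
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) {
      stop("malformed GPR (unexpected '", t, "'): ", gpr)
    }
    t
  }
  tree <- parse_or()
  if (pos <= length(tokens)) stop("malformed GPR (trailing tokens): ", gpr)
  tree
}

#' @rdname parse_gpr
#' @return `gpr_genes()`: character vector of the distinct gene ids in
#'   the rule.
#' @export
gpr_genes <- function(gpr) {
  tree <- if (is.character(gpr) || is.null(gpr) || all(is.na(gpr))) parse_gpr(gpr) else gpr
  walk <- function(node) {
    if (is.null(node)) return(character(0))
    if (is.character(node)) return(node)
    unlist(lapply(node$args, walk))
  }
  unique(walk(tree))
}

#' @rdname parse_gpr
#' @param deleted_genes character vector of knocked-out gene ids.
#' @return `evaluate_gpr()`: logical, is the reaction still active with
#'   the given genes deleted? The empty rule is always active.
#' @examples
#' evaluate_gpr("g1 OR g2", "g1")             # TRUE  (isozyme)
#' evaluate_gpr("g1 AND g2", "g1")            # FALSE (complex subunit)
#' @export
evaluate_gpr <- function(gpr, deleted_genes = character(0)) {
  tree <- if (is.character(gpr) || is.null(gpr) || all(is.na(gpr))) parse_gpr(gpr) else gpr
  if (is.null(tree)) return(TRUE)
  ev <- function(node) {
    if (is.character(node)) return(!(node %in% deleted_genes))
    vals <- vapply(node$args, ev, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  ev(tree)
}
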