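#' Parse a boolean combination formula over indicator matrices
#'
#' The formula combines per-matrix activity literals with the binary operators
#' `AND`, `OR` and `XOR` (case-insensitive), e.g.
#' `"(M1 AND M2) OR (M3 AND M4)"` to pair up-expression with hypo-methylation
#' and down-expression with hyper-methylation. Operator chains without
#' parentheses associate left with no precedence between operators:
#' `"M1 AND M2 OR M3"` parses as `((M1 AND M2) OR M3)`. Parentheses override.
#'
#' @param text Formula string.
#' @param matrix_names Optional character vector of available matrix names;
#'   when given, a leaf naming an unknown matrix is an error, as is a supplied
#'   matrix that never appears in the formula.
#' @return An object of class `kp_formula`: a binary expression tree whose
#'   leaves are matrix names.
#' @export
kp_parse_formula <- function(text, matrix_names = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty formula", call. = FALSE)
  toks <- kp_formula_tokens(text)
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$pos <- 1L
  tree <- kp_parse_expr(state)
  if (state$pos <= length(state$toks)) {
    t <- state$toks[[state$pos]]
    if (t$type == "rparen") {
      stop("formula parse error at position ", t$at, ": unbalanced parentheses", call. = FALSE)
    }
    stop("formula parse error at position ", t$at, ": unexpected '", t$text, "'", call. = FALSE)
  }
  leaves <- kp_formula_leaves(tree)
  if (!is.null(matrix_names)) {
    unknown <- setdiff(leaves, matrix_names)
    if (length(unknown)) {
      stop("formula names unknown matrix: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    unused <- setdiff(matrix_names, leaves)
    if (length(unused)) {
      stop("matrix supplied but absent from formula: ", paste(unused, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(tree, class = "kp_formula")
}

kp_formula_tokens <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("[ \t]", ch)) { i <- i + 1L; next }
    if (ch == "(") { toks[[length(toks) + 1L]] <- list(type = "lparen", text = "(", at = i); i <- i + 1L; next }
    if (ch == ")") { toks[[length(toks) + 1L]] <- list(type = "rparen", text = ")", at = i); i <- i + 1L; next }
    m <- regmatches(substr(text, i, n), regexpr("^[A-Za-z0-9_.-]+", substr(text, i, n)))
    if (length(m) == 0L) {
      stop("formula parse error at position ", i, ": unknown token '", ch, "'", call. = FALSE)
    }
    type <- if (toupper(m) %in% c("AND", "OR", "XOR")) "op" else "name"
    toks[[length(toks) + 1L]] <- list(type = type, text = if (type == "op") toupper(m) else m, at = i)
    i <- i + nchar(m)
  }
  toks
}

kp_parse_expr <- function(state) {
  node <- kp_parse_primary(state)
  while (state$pos <= length(state$toks) && state$toks[[state$pos]]$type == "op") {
    op <- state$toks[[state$pos]]$text
    state$pos <- state$pos + 1L
    rhs <- kp_parse_primary(state)
    node <- list(type = "op", op = op, left = node, right = rhs)
  }
  node
}

kp_parse_primary <- function(state) {
  if (state$pos > length(state$toks)) {
    stop("formula parse error: unexpected end of formula", call. = FALSE)
  }
  t <- state$toks[[state$pos]]
  if (t$type == "name") {
    state$pos <- state$pos + 1L
    return(list(type = "leaf", name = t$text))
  }
  if (t$type == "lparen") {
    state$pos <- state$pos + 1L
    node <- kp_parse_expr(state)
    if (state$pos > length(state$toks) || state$toks[[state$pos]]$type != "rparen") {
      stop("formula parse error at position ", t$at, ": unbalanced parentheses", call. = FALSE)
    }
    state$pos <- state$pos + 1L
    return(node)
  }
  stop("formula parse error at position ", t$at, ": unexpected '", t$text, "'", call. = FALSE)
}

kp_formula_leaves <- function(node) {
  if (node$type == "leaf") return(node$name)
  unique(c(kp_formula_leaves(node$left), kp_formula_leaves(node$right)))
}

kp_deparse_formula <- function(node) {
  if (node$type == "leaf") return(node$name)
  paste0("(", kp_deparse_formula(node$left), " ", node$op, " ",
         kp_deparse_formula(node$right), ")")
}

#' @export
format.kp_formula <- function(x, ...) kp_deparse_formula(x)

#' @export
print.kp_formula <- function(x, ...) {
  cat("<formula ", format(x), ">\n", sep = "")
  invisible(x)
}

#' Evaluate a combination formula over per-matrix activity literals
#'
#' `AND` is conjunction, `OR` disjunction and `XOR` exclusive-or of the two
#' operand values, applied gene-wise.
#'
#' @param formula A [kp_parse_formula()] tree (or formula text, parsed on the
#'   fly against the literal names).
#' @param literals Named list mapping each matrix name to a named logical
#'   vector over the same gene universe (from [kp_matrix_activity()]).
#' @return Named logical activity vector over the gene universe.
#' @export
kp_evaluate_formula <- function(formula, literals) {
  if (is.character(formula)) formula <- kp_parse_formula(formula, names(literals))
  genes <- names(literals[[1L]])
  for (lit in literals) stopifnot(identical(names(lit), genes))
  kp_eval_node(formula, literals)
}

kp_eval_node <- function(node, literals) {
  if (node$type == "leaf") {
    lit <- literals[[node$name]]
    if (is.null(lit)) stop("formula names unknown matrix: ", node$name, call. = FALSE)
    return(lit)
  }
  l <- kp_eval_node(node$left, literals)
  r <- kp_eval_node(node$right, literals)
  switch(node$op, AND = l & r, OR = l | r, XOR = xor(l, r))
}

#' Compute the activity profile of every network node
#'
#' Resolves each matrix's case-exception threshold, evaluates each gene's
#' per-matrix activity literal, and combines the literals through the
#' formula. The universe is the network's node set; genes missing from a
#' matrix count all cases as non-active there. Activity is computed once, up
#' front — the search algorithms never re-touch the matrices.
#'
#' @param network Undirected igraph graph with named vertices.
#' @param matrices List of [kp_indicator_matrix()] objects (names taken from
#'   each matrix's `name` field).
#' @param l Named list/vector of per-matrix thresholds ([kp_l()] specs,
#'   `"25%"` strings, or counts), one per matrix.
#' @param formula Formula text or [kp_parse_formula()] tree; may be omitted
#'   when a single matrix is supplied.
#' @return Named logical vector over the network's nodes (`TRUE` = active).
#' @export
kp_activity_profile <- function(network, matrices, l, formula = NULL) {
  if (inherits(matrices, "kp_matrix")) matrices <- list(matrices)
  names(matrices) <- vapply(matrices, function(m) m$name, "")
  if (anyDuplicated(names(matrices))) stop("duplicate matrix names", call. = FALSE)
  if (is.null(names(l)) && length(l) == length(matrices)) names(l) <- names(matrices)
  missing_l <- setdiff(names(matrices), names(l))
  if (length(missing_l)) {
    stop("no case-exception threshold supplied for matrix: ",
         paste(missing_l, collapse = ", "), call. = FALSE)
  }
  if (is.null(formula)) {
    if (length(matrices) != 1L) {
      stop("a combination formula is required for more than one matrix", call. = FALSE)
    }
    formula <- names(matrices)
  }
  genes <- igraph::V(network)$name
  literals <- lapply(names(matrices), function(nm) {
    kp_matrix_activity(matrices[[nm]], kp_l(l[[nm]]), genes)
  })
  names(literals) <- names(matrices)
  kp_evaluate_formula(formula, literals)
}
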