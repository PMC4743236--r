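# Boolean regulation functions: an ordered regulator list plus a truth
# table over the 2^k input combinations. Row order convention: the row
# index (0-based) is the integer whose binary digits are the regulator
# values in input order, first-listed regulator = most significant bit.

#' Create a Boolean regulation function
#'
#' A Boolean function maps the activation values of an ordered list of
#' regulators to the next value of a target gene. It is stored as a truth
#' table; optionally, an AND/OR/NOT expression over the regulator names may
#' be attached (and is compiled to the table).
#'
#' The truth-table row for regulator values `v` is the integer with binary
#' digits `v` in input order, the first-listed regulator being the most
#' significant bit. A function with zero inputs is a constant (table of
#' length 1).
#'
#' @param inputs character vector of regulator node names (may be empty).
#' @param table integer/logical vector of length `2^length(inputs)` with
#'   the output bit per row. Ignored when `expr` is given.
#' @param expr optional logic expression string in AND/OR/NOT notation,
#'   e.g. `"(G1 AND NOT G2) OR G3"`. When supplied without `inputs`, the
#'   regulators are taken in order of first appearance.
#' @return an object of class `nrbn_function` with elements `inputs`,
#'   `table` and (possibly `NULL`) `expr`.
#' @examples
#' f_and <- boolean_function(c("a", "b"), c(0, 0, 0, 1))
#' evaluate_function(f_and, c(1, 1))
#' f <- boolean_function(expr = "a AND NOT b")
#' f$table
#' @export
boolean_function <- function(inputs = character(), table = NULL, expr = NULL) {
  if (!is.null(expr)) {
    parsed <- parse_logic_expression(expr)
    if (length(inputs) == 0L) inputs <- parsed$inputs
    if (!all(parsed$inputs %in% inputs))
      stop("expression uses regulators not listed in `inputs`: ",
           paste(setdiff(parsed$inputs, inputs), collapse = ", "))
    table <- compile_expression(parsed$ast, inputs)
  }
  inputs <- as.character(inputs)
  if (anyDuplicated(inputs))
    stop("a regulator may appear at most once per function")
  table <- as.integer(table)
  if (length(table) != 2L^length(inputs))
    stop("table length ", length(table), " does not match 2^",
         length(inputs), " inputs")
  if (!all(table %in% c(0L, 1L))) stop("table entries must be 0 or 1")
  structure(list(inputs = inputs, table = table, expr = expr),
            class = "nrbn_function")
}

#' Evaluate a Boolean function on regulator values
#'
#' @param f an [boolean_function()] object.
#' @param regulator_values vector of 0/1 values, one per regulator, in
#'   input order.
#' @return the output bit (0 or 1).
#' @export
evaluate_function <- function(f, regulator_values) {
  stopifnot(inherits(f, "nrbn_function"))
  v <- as.integer(regulator_values)
  if (length(v) != length(f$inputs))
    stop("expected ", length(f$inputs), " regulator values, got ", length(v))
  if (!all(v %in% c(0L, 1L))) stop("regulator values must be 0 or 1")
  f$table[table_row_index(v) + 1L]
}

# 0-based truth-table row for a value vector (first input = MSB)
table_row_index <- function(v) {
  k <- length(v)
  if (k == 0L) return(0L)
  sum(v * 2L^((k - 1L):0L))
}

#' Fraction of 1-outputs of a Boolean function's truth table
#'
#' The bias of a function is the proportion of input combinations mapped
#' to 1; together with the mean connectivity it controls the dynamical
#' regime of a random network.
#'
#' @param f an [boolean_function()] object.
#' @return a value in \[0, 1\].
#' @export
function_bias <- function(f) {
  stopifnot(inherits(f, "nrbn_function"))
  mean(f$table)
}

#' @export
print.nrbn_function <- function(x, ...) {
  k <- length(x$inputs)
  cat("Boolean function: ", k, " input", if (k != 1) "s", sep = "")
  if (k > 0) cat(" (", paste(x$inputs, collapse = ", "), ")", sep = "")
  cat("\n")
  if (!is.null(x$expr)) cat("  expr: ", x$expr, "\n", sep = "")
  cat("  table: ", paste(x$table, collapse = ""),
      "  bias: ", format(mean(x$table)), "\n", sep = "")
  invisible(x)
}

## ---- logic expressions -----------------------------------------------

# Tokenize an AND/OR/NOT expression. Operators are case-insensitive words;
# parentheses group. Names use the charset [A-Za-z0-9_.-].
tokenize_expression <- function(expr) {
  out <- character()
  s <- expr
  pat_name <- "^[A-Za-z0-9_.-]+"
  while (nzchar(s <- sub("^\\s+", "", s))) {
    ch <- substr(s, 1, 1)
    if (ch %in% c("(", ")")) {
      out <- c(out, ch)
      s <- substr(s, 2, nchar(s))
    } else if (grepl(pat_name, s)) {
      m <- regmatches(s, regexpr(pat_name, s))
      out <- c(out, m)
      s <- substr(s, nchar(m) + 1L, nchar(s))
    } else {
      stop("cannot tokenize expression near: ", s)
    }
  }
  out
}

# Recursive-descent parser. Grammar:
#   expr   := term (OR term)*
#   term   := factor (AND factor)*
#   factor := NOT factor | '(' expr ')' | name
# Returns list(ast, inputs) with inputs in order of first appearance.
parse_logic_expression <- function(expr) {
  toks <- tokenize_expression(expr)
  if (length(toks) == 0L) stop("empty expression")
  pos <- 1L
  inputs <- character()
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  is_op <- function(t, op) !is.na(t) && toupper(t) == op

  parse_expr <- function() {
    node <- parse_term()
    while (is_op(peek(), "OR")) {
      take()
      node <- list(op = "OR", a = node, b = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (is_op(peek(), "AND")) {
      take()
      node <- list(op = "AND", a = node, b = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of expression")
    if (is_op(t, "NOT")) {
      take()
      return(list(op = "NOT", a = parse_factor()))
    }
    if (t == "(") {
      take()
      node <- parse_expr()
      if (!identical(peek(), ")")) stop("missing closing parenthesis")
      take()
      return(node)
    }
    if (t == ")") stop("unexpected ')'")
    if (toupper(t) %in% c("AND", "OR")) stop("unexpected operator: ", t)
    take()
    if (!(t %in% inputs)) inputs <<- c(inputs, t)
    list(op = "VAR", name = t)
  }

  ast <- parse_expr()
  if (pos <= length(toks)) stop("trailing tokens in expression: ",
                                paste(toks[pos:length(toks)], collapse = " "))
  list(ast = ast, inputs = inputs)
}

eval_ast <- function(ast, env) {
  switch(ast$op,
         VAR = env[[ast$name]],
         NOT = 1L - eval_ast(ast$a, env),
         AND = eval_ast(ast$a, env) & eval_ast(ast$b, env),
         OR  = eval_ast(ast$a, env) | eval_ast(ast$b, env))
}

# Compile an AST to a truth table over `inputs` (first input = MSB).
compile_expression <- function(ast, inputs) {
  k <- length(inputs)
  n_rows <- 2L^k
  out <- integer(n_rows)
  for (r in seq_len(n_rows) - 1L) {
    v <- bits_of_row(r, k)
    env <- as.list(setNames(as.integer(v), inputs))
    out[r + 1L] <- as.integer(as.logical(eval_ast(ast, env)))
  }
  out
}

# digits of 0-based row r over k inputs, first input = MSB
bits_of_row <- function(r, k) {
  if (k == 0L) return(integer())
  as.integer(bitwAnd(bitwShiftR(r, (k - 1L):0L), 1L))
}

#' Generate a random AND/OR/NOT expression over given regulators
#'
#' Builds a random binary operator tree in which every regulator appears
#' exactly once; leaves are negated with probability `p_not`. Used by the
#' "logic" function-generation scheme.
#'
#' @param inputs character vector of regulator names (at least one).
#' @param p_not probability of negating each leaf.
#' @return an expression string parseable by [boolean_function()].
#' @export
random_logic_expression <- function(inputs, p_not = 0.3) {
  stopifnot(length(inputs) >= 1)
  build <- function(vars) {
    if (length(vars) == 1L) {
      leaf <- vars
      if (runif(1) < p_not) leaf <- paste("NOT", leaf)
      return(leaf)
    }
    split <- sample(length(vars) - 1L, 1L)
    op <- sample(c("AND", "OR"), 1L)
    paste0("(", build(vars[seq_len(split)]), " ", op, " ",
           build(vars[-seq_len(split)]), ")")
  }
  build(sample(inputs))
}
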