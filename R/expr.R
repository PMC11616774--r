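# Boolean expression trees: the rule language shared by both model formats.
#
# An expression is a plain list with a `type` field:
#   var   -- list(type = "var",   name  = <node name>)
#   const -- list(type = "const", value = 0L or 1L)
#   not   -- list(type = "not",   arg   = <expr>)
#   and   -- list(type = "and",   args  = list(<expr>, ..., >= 2 children))
#   or    -- list(type = "or",    args  = list(<expr>, ..., >= 2 children))

bn_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "bnscreen_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

bn_var <- function(name) list(type = "var", name = name)
bn_const <- function(value) list(type = "const", value = as.integer(value))
bn_not <- function(arg) list(type = "not", arg = arg)
bn_and <- function(args) {
  if (length(args) == 1L) args[[1L]] else list(type = "and", args = args)
}
bn_or <- function(args) {
  if (length(args) == 1L) args[[1L]] else list(type = "or", args = args)
}

#' @noRd
tokenize_rule <- function(text, line = NA_integer_) {
  pattern <- "[A-Za-z_][A-Za-z0-9_.]*|[0-9]+|[!&|()]|\\s+"
  tokens <- character(0)
  pos <- 1L
  nch <- nchar(text)
  while (pos <= nch) {
    m <- regexpr(pattern, substr(text, pos, nch))
    if (m != 1L) {
      bn_stop(
        sprintf(
          "parse error%s: unexpected character '%s'",
          if (is.na(line)) "" else sprintf(" on line %d", line),
          substr(text, pos, pos)
        ),
        "bn_parse_error"
      )
    }
    len <- attr(m, "match.length")
    tok <- substr(text, pos, pos + len - 1L)
    if (!grepl("^\\s+$", tok)) tokens <- c(tokens, tok)
    pos <- pos + len
  }
  tokens
}

# Recursive-descent parser; precedence ! > & > |, n-ary AND/OR flattened.
parse_bool_expr <- function(text, line = NA_integer_) {
  tokens <- tokenize_rule(text, line)
  pos <- 1L
  where <- if (is.na(line)) "" else sprintf(" on line %d", line)

  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() {
    tok <- peek()
    pos <<- pos + 1L
    tok
  }
  fail <- function(got) {
    bn_stop(
      sprintf(
        "parse error%s: %s", where,
        if (is.null(got)) "unexpected end of expression" else
          sprintf("unexpected token '%s'", got)
      ),
      "bn_parse_error"
    )
  }

  parse_or <- function() {
    args <- list(parse_and())
    while (identical(peek(), "|")) {
      advance()
      args <- c(args, list(parse_and()))
    }
    bn_or(args)
  }
  parse_and <- function() {
    args <- list(parse_unary())
    while (identical(peek(), "&")) {
      advance()
      args <- c(args, list(parse_unary()))
    }
    bn_and(args)
  }
  parse_unary <- function() {
    tok <- peek()
    if (identical(tok, "!")) {
      advance()
      return(bn_not(parse_unary()))
    }
    parse_atom()
  }
  parse_atom <- function() {
    tok <- advance()
    if (is.null(tok)) fail(tok)
    if (tok == "(") {
      e <- parse_or()
      if (!identical(advance(), ")")) fail(peek())
      return(e)
    }
    if (tok %in% c("0", "1")) return(bn_const(tok))
    if (grepl("^[A-Za-z_]", tok)) {
      # call syntax marks BoolNet extensions (temporal/ensemble operators)
      if (identical(peek(), "(")) {
        bn_stop(
          sprintf("parse error%s: unsupported construct '%s(...)'", where, tok),
          "bn_parse_error"
        )
      }
      return(bn_var(tok))
    }
    fail(tok)
  }

  e <- parse_or()
  if (!is.null(peek())) fail(peek())
  e
}

# Variables referenced by an expression, in first-occurrence order.
expr_variables <- function(expr) {
  switch(expr$type,
    var = expr$name,
    const = character(0),
    not = expr_variables(expr$arg),
    unique(unlist(lapply(expr$args, expr_variables)))
  )
}

# Evaluate under a named 0/1 assignment.
eval_expr <- function(expr, values) {
  switch(expr$type,
    const = expr$value,
    var = {
      v <- values[[expr$name]]
      if (is.null(v) || is.na(v)) {
        bn_stop(
          sprintf("unresolved symbol '%s' in rule expression", expr$name),
          "bn_symbol_error"
        )
      }
      as.integer(v)
    },
    not = 1L - eval_expr(expr$arg, values),
    and = {
      for (a in expr$args) if (eval_expr(a, values) == 0L) return(0L)
      1L
    },
    or = {
      for (a in expr$args) if (eval_expr(a, values) == 1L) return(1L)
      0L
    }
  )
}

# Render in BoolNet syntax with minimal parentheses.
deparse_expr <- function(expr) {
  prec <- function(e) switch(e$type, or = 1L, and = 2L, not = 3L, 4L)
  wrap <- function(e, min_prec) {
    s <- deparse_expr(e)
    if (prec(e) < min_prec) paste0("(", s, ")") else s
  }
  switch(expr$type,
    const = as.character(expr$value),
    var = expr$name,
    not = paste0("!", wrap(expr$arg, 4L)),
    and = paste(vapply(expr$args, wrap, "", min_prec = 2L), collapse = " & "),
    or = paste(vapply(expr$args, wrap, "", min_prec = 1L), collapse = " | ")
  )
}

# Synthesize a minterm (sum-of-products) expression from a truth table, used
# for rules whose native form is not an expression (SBML transitions,
# generated random tables, constant perturbations).
expr_from_table <- function(table, inputs) {
  k <- length(inputs)
  stopifnot(length(table) == 2^k)
  if (all(table == 0L)) return(bn_const(0L))
  if (all(table == 1L)) return(bn_const(1L))
  minterms <- lapply(which(table == 1L) - 1L, function(b) {
    lits <- lapply(seq_len(k), function(j) {
      v <- bn_var(inputs[[j]])
      if (bitwAnd(b, bitwShiftL(1L, j - 1L)) != 0L) v else bn_not(v)
    })
    bn_and(lits)
  })
  bn_or(minterms)
}
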