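#' Parse an arithmetic expression over named parameters
#'
#' pSVG glyph files embed coordinates as small arithmetic formulas over the
#' glyph's named parameters, e.g. `"width - arrowhead_width"` or
#' `"height/2"`. `parse_expression()` turns such a string into an abstract
#' syntax tree that [evaluate_expression()] can evaluate against a parameter
#' binding.
#'
#' The grammar is conventional infix arithmetic: `+ - * /` with the usual
#' precedence (unary minus binds tighter than `*` and `/`, which bind
#' tighter than `+` and `-`), left associativity, parentheses, decimal
#' literals with optional fraction and exponent, and a fixed function table
#' `sin`, `cos`, `tan`, `sqrt`, `abs` (one argument; trigonometry in
#' radians) plus `min`, `max` (two arguments). Whitespace is insignificant.
#' Parameter names match `[A-Za-z_][A-Za-z0-9_]*`; whether a parameter is
#' actually bound is checked at evaluation time, not here, so a glyph
#' library can be parsed before any values exist.
#'
#' @param text A single non-empty expression string.
#' @return An object of class `psvg_expression` (the syntax tree).
#' @examples
#' e <- parse_expression("width - arrowhead_width")
#' evaluate_expression(e, c(width = 30, arrowhead_width = 10))
#' @export
parse_expression <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("expression text must be a single non-empty string", call. = FALSE)
  }
  toks <- expr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  st$text <- text
  node <- expr_parse_sum(st)
  tk <- expr_peek(st)
  if (!is.null(tk)) {
    expr_parse_error(st, sprintf("unexpected token '%s'", tk$value))
  }
  structure(node, class = "psvg_expression")
}

# one-argument and two-argument function tables, radians throughout
.expr_fun1 <- list(sin = sin, cos = cos, tan = tan, sqrt = sqrt, abs = abs)
.expr_fun2 <- list(min = min, max = max)

expr_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^[[:space:]]$", ch)) {
      i <- i + 1L
      next
    }
    if (ch %in% c("+", "-", "*", "/", "(", ")", ",")) {
      toks[[length(toks) + 1L]] <- list(type = "op", value = ch, pos = i)
      i <- i + 1L
      next
    }
    rest <- substr(text, i, nchar(text))
    m <- regmatches(rest, regexpr("^([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?", rest))
    if (length(m) == 1L && nzchar(m)) {
      toks[[length(toks) + 1L]] <- list(type = "num", value = m, pos = i)
      i <- i + nchar(m)
      next
    }
    m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
    if (length(m) == 1L && nzchar(m)) {
      toks[[length(toks) + 1L]] <- list(type = "ident", value = m, pos = i)
      i <- i + nchar(m)
      next
    }
    stop(sprintf("expression parse error at position %d: unexpected character '%s' in \"%s\"",
                 i, ch, text), call. = FALSE)
  }
  toks
}

expr_peek <- function(st) {
  if (st$pos > length(st$toks)) NULL else st$toks[[st$pos]]
}

expr_advance <- function(st) {
  tk <- expr_peek(st)
  st$pos <- st$pos + 1L
  tk
}

expr_parse_error <- function(st, msg) {
  tk <- expr_peek(st)
  where <- if (is.null(tk)) "end of input" else sprintf("position %d", tk$pos)
  stop(sprintf("expression parse error at %s: %s in \"%s\"", where, msg, st$text),
       call. = FALSE)
}

expr_parse_sum <- function(st) {
  node <- expr_parse_term(st)
  repeat {
    tk <- expr_peek(st)
    if (is.null(tk) || tk$type != "op" || !(tk$value %in% c("+", "-"))) break
    expr_advance(st)
    rhs <- expr_parse_term(st)
    node <- list(kind = "bin", op = tk$value, lhs = node, rhs = rhs)
  }
  node
}

expr_parse_term <- function(st) {
  node <- expr_parse_unary(st)
  repeat {
    tk <- expr_peek(st)
    if (is.null(tk) || tk$type != "op" || !(tk$value %in% c("*", "/"))) break
    expr_advance(st)
    rhs <- expr_parse_unary(st)
    node <- list(kind = "bin", op = tk$value, lhs = node, rhs = rhs)
  }
  node
}

expr_parse_unary <- function(st) {
  tk <- expr_peek(st)
  if (!is.null(tk) && tk$type == "op" && tk$value == "-") {
    expr_advance(st)
    return(list(kind = "neg", arg = expr_parse_unary(st)))
  }
  expr_parse_primary(st)
}

expr_parse_primary <- function(st) {
  tk <- expr_peek(st)
  if (is.null(tk)) expr_parse_error(st, "incomplete expression")
  if (tk$type == "num") {
    expr_advance(st)
    return(list(kind = "num", value = as.numeric(tk$value)))
  }
  if (tk$type == "ident") {
    expr_advance(st)
    nxt <- expr_peek(st)
    if (!is.null(nxt) && nxt$type == "op" && nxt$value == "(") {
      fname <- tk$value
      arity <- if (fname %in% names(.expr_fun1)) 1L
      else if (fname %in% names(.expr_fun2)) 2L
      else expr_parse_error(st, sprintf("unknown function '%s'", fname))
      expr_advance(st) # consume '('
      args <- list(expr_parse_sum(st))
      repeat {
        sep <- expr_peek(st)
        if (!is.null(sep) && sep$type == "op" && sep$value == ",") {
          expr_advance(st)
          args[[length(args) + 1L]] <- expr_parse_sum(st)
        } else break
      }
      cl <- expr_peek(st)
      if (is.null(cl) || cl$type != "op" || cl$value != ")") {
        expr_parse_error(st, sprintf("expected ')' closing call to '%s'", fname))
      }
      expr_advance(st)
      if (length(args) != arity) {
        stop(sprintf("expression parse error at position %d: function '%s' takes %d argument%s, got %d in \"%s\"",
                     tk$pos, fname, arity, if (arity == 1L) "" else "s",
                     length(args), st$text), call. = FALSE)
      }
      return(list(kind = "call", fn = fname, args = args))
    }
    return(list(kind = "param", name = tk$value))
  }
  if (tk$type == "op" && tk$value == "(") {
    expr_advance(st)
    node <- expr_parse_sum(st)
    cl <- expr_peek(st)
    if (is.null(cl) || cl$type != "op" || cl$value != ")") {
      expr_parse_error(st, "expected ')'")
    }
    expr_advance(st)
    return(node)
  }
  expr_parse_error(st, sprintf("unexpected token '%s'", tk$value))
}

#' Evaluate a parsed expression against a parameter binding
#'
#' @param expr A `psvg_expression` from [parse_expression()], or a string
#'   which is parsed first.
#' @param binding Named numeric vector or list mapping parameter names to
#'   finite values (glyph coordinate units; angles in radians).
#' @return A single numeric value.
#'
#' Every parameter referenced by the expression must be present in
#' `binding`; an unbound parameter is an error naming it. Division by zero
#' is an evaluation error, never an infinity.
#' @export
evaluate_expression <- function(expr, binding = numeric()) {
  if (is.character(expr)) expr <- parse_expression(expr)
  binding <- as_param_binding(binding)
  expr_eval_node(unclass(expr), binding)
}

#' Coerce and validate a parameter binding
#'
#' A binding maps parameter names to finite real values. Duplicate names and
#' non-finite values are rejected.
#' @param binding Named numeric vector or list (possibly empty).
#' @return A named numeric vector.
#' @export
as_param_binding <- function(binding) {
  if (is.null(binding)) return(stats::setNames(numeric(0), character(0)))
  if (is.list(binding)) binding <- unlist(binding)
  if (length(binding) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (!is.numeric(binding)) stop("parameter binding values must be numeric", call. = FALSE)
  nms <- names(binding)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("every parameter binding value must be named", call. = FALSE)
  }
  if (anyDuplicated(nms)) {
    stop(sprintf("duplicate parameter name(s): %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(binding))) {
    stop(sprintf("non-finite value for parameter(s): %s",
                 paste(nms[!is.finite(binding)], collapse = ", ")), call. = FALSE)
  }
  stats::setNames(as.numeric(binding), nms)
}

expr_eval_node <- function(node, binding) {
  switch(node$kind,
    num = node$value,
    param = {
      if (!(node$name %in% names(binding))) {
        stop(sprintf("unbound parameter '%s'", node$name), call. = FALSE)
      }
      unname(binding[[node$name]])
    },
    neg = -expr_eval_node(node$arg, binding),
    bin = {
      l <- expr_eval_node(node$lhs, binding)
      r <- expr_eval_node(node$rhs, binding)
      switch(node$op,
        "+" = l + r,
        "-" = l - r,
        "*" = l * r,
        "/" = {
          if (r == 0) stop("division by zero in expression", call. = FALSE)
          l / r
        })
    },
    call = {
      vals <- vapply(node$args, expr_eval_node, numeric(1), binding = binding)
      if (node$fn %in% names(.expr_fun1)) .expr_fun1[[node$fn]](vals[1])
      else .expr_fun2[[node$fn]](vals[1], vals[2])
    },
    stop(sprintf("corrupt expression node kind '%s'", node$kind), call. = FALSE))
}

#' List the parameters referenced by an expression
#'
#' @inheritParams evaluate_expression
#' @return Character vector of distinct parameter names (possibly empty).
#' @export
expression_parameters <- function(expr) {
  if (is.character(expr)) expr <- parse_expression(expr)
  unique(expr_collect_params(unclass(expr)))
}

expr_collect_params <- function(node) {
  switch(node$kind,
    num = character(0),
    param = node$name,
    neg = expr_collect_params(node$arg),
    bin = c(expr_collect_params(node$lhs), expr_collect_params(node$rhs)),
    call = unlist(lapply(node$args, expr_collect_params)),
    character(0))
}

#' @export
print.psvg_expression <- function(x, ...) {
  cat("<psvg expression>", expr_deparse(unclass(x)), "\n")
  invisible(x)
}

#' Render an expression tree back to its textual form
#'
#' Produces a fully parenthesized equivalent; parsing the result yields a
#' tree that evaluates identically.
#' @param expr A `psvg_expression`.
#' @return A single string.
#' @export
deparse_expression <- function(expr) {
  expr_deparse(unclass(expr))
}

expr_deparse <- function(node) {
  switch(node$kind,
    num = formatC(node$value, digits = 17, format = "g"),
    param = node$name,
    neg = paste0("-(", expr_deparse(node$arg), ")"),
    bin = paste0("(", expr_deparse(node$lhs), " ", node$op, " ",
                 expr_deparse(node$rhs), ")"),
    call = paste0(node$fn, "(",
                  paste(vapply(node$args, expr_deparse, character(1)), collapse = ", "),
                  ")"))
}
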