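## Symbolic expression trees.
##
## Expressions are trees over primary descriptor names with operators
## +, -, *, / and ^2.  Sum and product nodes are n-ary and flattened;
## their arguments are kept sorted by canonical string, so
## commutatively-equal trees map to a single canonical form.  The
## canonical prefix string doubles as the serialization format.

#' Construct a variable (leaf) expression
#' @param name descriptor name.
#' @return An `sr_expression` leaf.
#' @export
ex_var <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(op = NULL, name = name, str = name),
            class = "sr_expression")
}

#' Construct an operator expression
#'
#' `+` and `*` are n-ary (arguments flattened and canonically sorted);
#' `-` and `/` are binary; `^2` is unary.
#'
#' @param op one of `"+"`, `"-"`, `"*"`, `"/"`, `"^2"`.
#' @param ... argument expressions (or descriptor names, which are
#'   promoted to leaves).
#' @return An `sr_expression` node.
#' @export
ex_op <- function(op, ...) {
  args <- lapply(list(...), function(a)
    if (inherits(a, "sr_expression")) a else ex_var(a))
  if (!op %in% c("+", "-", "*", "/", "^2")) {
    stop("unsupported operator: '", op, "'", call. = FALSE)
  }
  if (op == "^2") {
    stopifnot(length(args) == 1L)
  } else if (op %in% c("-", "/")) {
    stopifnot(length(args) == 2L)
  } else {
    stopifnot(length(args) >= 2L)
    ## flatten nested n-ary nodes of the same op
    flat <- list()
    for (a in args) {
      if (!is.null(a$op) && identical(a$op, op)) {
        flat <- c(flat, a$args)
      } else {
        flat <- c(flat, list(a))
      }
    }
    args <- flat[order(vapply(flat, `[[`, character(1), "str"),
                       method = "radix")]
  }
  str <- paste0("(", op, " ",
                paste(vapply(args, `[[`, character(1), "str"),
                      collapse = " "), ")")
  structure(list(op = op, args = args, str = str), class = "sr_expression")
}

#' Canonical prefix string of an expression
#'
#' Commutative operands are sorted, so two trees equal up to
#' commutativity format identically.
#'
#' @param x an `sr_expression`.
#' @return A character scalar, e.g. `"(* dG_solv (- Xp4dv Xp6dv))"`.
#' @export
format_expression <- function(x) {
  stopifnot(inherits(x, "sr_expression"))
  x$str
}

#' @export
print.sr_expression <- function(x, ...) {
  cat(format_expression(x), "\n")
  invisible(x)
}

#' Node-count complexity of an expression
#'
#' Leaves count 1 each; an n-ary sum/product of k arguments counts as
#' k - 1 binary operations, so complexity is independent of how an
#' associative chain is bracketed.
#'
#' @param x an `sr_expression`.
#' @return Integer complexity (>= 1).
#' @export
expression_complexity <- function(x) {
  stopifnot(inherits(x, "sr_expression"))
  if (is.null(x$op)) return(1L)
  k <- length(x$args)
  ops <- if (x$op %in% c("+", "*")) k - 1L else 1L
  ops + sum(vapply(x$args, expression_complexity, integer(1)))
}

#' Primary descriptor names referenced by an expression
#' @param x an `sr_expression`.
#' @return Character vector of unique names.
#' @export
expression_vars <- function(x) {
  stopifnot(inherits(x, "sr_expression"))
  if (is.null(x$op)) return(x$name)
  sort(unique(unlist(lapply(x$args, expression_vars))))
}

#' Evaluate an expression on descriptor columns
#'
#' @param x an `sr_expression`.
#' @param data named list, data.frame or matrix with one column per
#'   referenced descriptor.
#' @return Numeric vector of values (may contain non-finite entries,
#'   e.g. from division by zero; callers decide how to guard).
#' @export
eval_expression <- function(x, data) {
  stopifnot(inherits(x, "sr_expression"))
  if (is.matrix(data)) data <- as.data.frame(data)
  rec <- function(e) {
    if (is.null(e$op)) {
      v <- data[[e$name]]
      if (is.null(v)) stop("missing descriptor column '", e$name, "'",
                           call. = FALSE)
      return(v)
    }
    vals <- lapply(e$args, rec)
    switch(e$op,
           "+" = Reduce(`+`, vals),
           "*" = Reduce(`*`, vals),
           "-" = vals[[1L]] - vals[[2L]],
           "/" = vals[[1L]] / vals[[2L]],
           "^2" = vals[[1L]]^2)
  }
  rec(x)
}

#' Parse a canonical prefix string back into an expression
#'
#' Inverse of [format_expression()].
#'
#' @param s a prefix string such as `"(- (* a b) c)"`.
#' @return An `sr_expression`.
#' @export
parse_expression <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  tokens <- strsplit(gsub("\\)", " ) ", gsub("\\(", " ( ", s)),
                     "\\s+")[[1L]]
  tokens <- tokens[nzchar(tokens)]
  pos <- 0L
  nxt <- function() {
    pos <<- pos + 1L
    if (pos > length(tokens)) stop("unexpected end of expression: ", s,
                                   call. = FALSE)
    tokens[pos]
  }
  rec <- function() {
    tok <- nxt()
    if (tok == "(") {
      op <- nxt()
      args <- list()
      repeat {
        if (pos >= length(tokens)) stop("unbalanced parentheses: ", s,
                                        call. = FALSE)
        if (tokens[pos + 1L] == ")") { pos <<- pos + 1L; break }
        args[[length(args) + 1L]] <- rec()
      }
      do.call(ex_op, c(list(op), args))
    } else if (tok == ")") {
      stop("unexpected ')' in: ", s, call. = FALSE)
    } else {
      ex_var(tok)
    }
  }
  out <- rec()
  if (pos != length(tokens)) stop("trailing tokens in: ", s, call. = FALSE)
  out
}
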