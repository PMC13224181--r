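test_that("canonical form identifies commutatively equal trees", {
  a <- ex_var("a"); b <- ex_var("b"); c <- ex_var("c")
  expect_equal(format_expression(ex_op("+", a, b)),
               format_expression(ex_op("+", b, a)))
  expect_equal(format_expression(ex_op("*", ex_op("+", a, b), c)),
               format_expression(ex_op("*", c, ex_op("+", b, a))))
  # associative chains flatten to one canonical n-ary form
  expect_equal(format_expression(ex_op("+", ex_op("+", a, b), c)),
               format_expression(ex_op("+", a, ex_op("+", c, b))))
  # non-commutative operands keep their order
  expect_false(format_expression(ex_op("-", a, b)) ==
                 format_expression(ex_op("-", b, a)))
})

test_that("canonicalization decided correctly on an enumerated tree set", {
  # oracle: evaluate both trees on random data; commutative-equal trees
  # must agree numerically AND canonically, others must differ in at
  # least one of the two
  set.seed(2)
  vars <- c("a", "b", "c")
  data <- as.data.frame(matrix(runif(300, 0.5, 2), 100, 3,
                               dimnames = list(NULL, vars)))
  pool <- list()
  for (v in vars) pool <- c(pool, list(ex_var(v)))
  ops2 <- c("+", "-", "*", "/")
  base_n <- length(pool)
  for (i in seq_len(base_n)) for (j in seq_len(base_n)) for (op in ops2) {
    pool <- c(pool, list(ex_op(op, pool[[i]], pool[[j]])))
  }
  pool <- c(pool, lapply(pool[1:3], function(e) ex_op("^2", e)))
  strs <- vapply(pool, format_expression, character(1))
  vals <- vapply(pool, eval_expression, numeric(100), data = data)
  for (i in seq_along(pool)) for (j in seq_along(pool)) {
    if (i >= j) next
    same_num <- isTRUE(all.equal(vals[, i], vals[, j], tolerance = 1e-12))
    if (strs[i] == strs[j]) {
      expect_true(same_num,
                  info = paste(strs[i], "vs", strs[j]))
    }
  }
  # every commutative duplicate collapses: a+b vs b+a etc. present once
  expect_lt(length(unique(strs)), length(strs))
})

test_that("complexity counts nodes independent of bracketing", {
  a <- ex_var("a"); b <- ex_var("b"); c <- ex_var("c")
  expect_equal(expression_complexity(a), 1L)
  expect_equal(expression_complexity(ex_op("-", a, b)), 3L)
  expect_equal(expression_complexity(ex_op("+", ex_op("+", a, b), c)),
               expression_complexity(ex_op("+", a, ex_op("+", b, c))))
  expect_equal(expression_complexity(ex_op("^2", ex_op("*", a, b))), 4L)
})

test_that("prefix serialization round-trips", {
  e <- ex_op("-", ex_op("*", "dG_solv", ex_op("-", "Xp4dv", "Xp6dv")),
             ex_op("/", "ASA", ex_op("^2", "JGI2")))
  s <- format_expression(e)
  back <- parse_expression(s)
  expect_equal(format_expression(back), s)
  expect_equal(expression_vars(back), expression_vars(e))
  expect_error(parse_expression("(+ a"), "unbalanced|end")
  expect_error(parse_expression("(+ a b) c"), "trailing")
})

test_that("evaluation agrees with an independent interpreter", {
  # second route: translate the canonical string into R syntax and eval
  to_r <- function(s) {
    expr <- parse_expression(s)   # reuse only for structure walk
    rec <- function(e) {
      if (is.null(e$op)) return(e$name)
      if (e$op == "^2") return(sprintf("(%s)^2", rec(e$args[[1]])))
      paste0("(", paste(vapply(e$args, rec, character(1)),
                        collapse = e$op), ")")
    }
    rec(expr)
  }
  set.seed(3)
  data <- as.data.frame(matrix(runif(500, 0.5, 3), 100, 5,
                               dimnames = list(NULL, paste0("v", 1:5))))
  exprs <- list(
    ex_op("*", "v1", ex_op("-", "v2", "v3")),
    ex_op("/", ex_op("+", "v1", "v2", "v4"), ex_op("^2", "v5")),
    ex_op("-", ex_op("*", "v1", "v2", "v3"), ex_op("/", "v4", "v5")))
  for (e in exprs) {
    direct <- eval_expression(e, data)
    via_r <- eval(parse(text = to_r(format_expression(e))), envir = data)
    expect_equal(direct, via_r, tolerance = 1e-12)
  }
})
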