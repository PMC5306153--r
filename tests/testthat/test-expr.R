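test_that("basic arithmetic, functions and booleans evaluate", {
  expect_equal(evaluate_expression("-a + u", list(a = 0, u = 2)), 2)
  expect_equal(evaluate_expression("exp(0)"), 1)
  expect_equal(evaluate_expression("pow(2, 10) / 4"), 256)
  expect_equal(evaluate_expression("2 ^ 3 ^ 2"), 512)  # right-assoc
  expect_equal(evaluate_expression("min(3, max(1, 2))"), 2)
  expect_equal(evaluate_expression("a > 1 && a < 3", list(a = 2)), 1)
  expect_equal(evaluate_expression("!(a > 1)", list(a = 2)), 0)
})

test_that("unbound identifiers and malformed text raise classed errors", {
  expect_error(evaluate_expression("a + q", list(a = 1)),
               class = "spml_symbol_error")
  err <- tryCatch(evaluate_expression("a + q", list(a = 1)),
                  error = function(e) e)
  expect_match(conditionMessage(err), "q")
  expect_error(evaluate_expression("a + * 2", list(a = 1)),
               class = "spml_parse_error")
  expect_error(evaluate_expression("system('ls')"),
               class = "spml_grammar_error")
  expect_error(evaluate_expression("x[1]", list(x = 1)),
               class = "spml_grammar_error")
  # rand() only allowed where explicitly enabled
  expect_error(evaluate_expression("rand()"), class = "spml_grammar_error")
  expect_silent(evaluate_expression("rand()", allow_rand = TRUE,
                                    rand_fn = function() 0.5))
})

test_that("engine agrees with an independent AST evaluator on random expressions", {
  # independent oracle: build random expression trees, evaluate them by direct
  # recursion, then render to text and compare with the parsing engine
  ops <- c("+", "-", "*", "/")
  funs <- c("exp", "sin", "cos", "sqrt", "abs")
  gen <- function(depth) {
    pick <- stats::runif(1)
    if (depth <= 0 || pick < 0.3) {
      if (stats::runif(1) < 0.5) list(kind = "num", value = round(stats::runif(1, 0.1, 5), 3))
      else list(kind = "sym", name = sample(c("a", "b", "c"), 1))
    } else if (pick < 0.75) {
      list(kind = "op", op = sample(ops, 1), l = gen(depth - 1), r = gen(depth - 1))
    } else {
      list(kind = "fun", fun = sample(funs, 1), arg = gen(depth - 1))
    }
  }
  eval_ast <- function(node, env) {
    switch(node$kind,
      num = node$value,
      sym = env[[node$name]],
      op = switch(node$op,
        "+" = eval_ast(node$l, env) + eval_ast(node$r, env),
        "-" = eval_ast(node$l, env) - eval_ast(node$r, env),
        "*" = eval_ast(node$l, env) * eval_ast(node$r, env),
        "/" = eval_ast(node$l, env) / eval_ast(node$r, env)),
      fun = switch(node$fun,
        exp = exp(eval_ast(node$arg, env)), sin = sin(eval_ast(node$arg, env)),
        cos = cos(eval_ast(node$arg, env)),
        sqrt = sqrt(abs(eval_ast(node$arg, env))),
        abs = abs(eval_ast(node$arg, env))))
  }
  render <- function(node) {
    switch(node$kind,
      num = format(node$value, digits = 15),
      sym = node$name,
      op = sprintf("(%s %s %s)", render(node$l), node$op, render(node$r)),
      fun = if (node$fun == "sqrt")
        sprintf("sqrt(abs(%s))", render(node$arg))
      else sprintf("%s(%s)", node$fun, render(node$arg)))
  }
  set.seed(42)
  bindings <- list(a = 1.5, b = -0.75, c = 2.25)
  for (i in 1:1000) {
    ast <- gen(4)
    expected <- suppressWarnings(eval_ast(ast, bindings))  # NaN from domain edges
    got <- suppressWarnings(evaluate_expression(render(ast), bindings))
    if (is.finite(expected)) expect_equal(got, expected, tolerance = 1e-12)
    else expect_identical(is.finite(got), FALSE)
  }
})
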