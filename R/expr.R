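# Math-expression engine shared by all layers.
#
# The grammar is deliberately small: + - * / ^ (right-assoc), unary minus,
# parentheses, the functions exp, log, sin, cos, sqrt, abs, pow, min, max,
# floor, comparisons and && || ! (plus their vectorised forms & |) in boolean
# contexts.  Expressions are parsed with R's parser and then the AST is walked
# against a whitelist, so nothing outside the grammar (indexing, assignment,
# arbitrary calls) can sneak into a model file.

.spml_binary_ops <- c("+", "-", "*", "/", "^",
                      "<", ">", "<=", ">=", "==", "!=",
                      "&&", "||", "&", "|")
.spml_unary_ops <- c("-", "+", "!")
.spml_funs <- c("exp", "log", "sin", "cos", "sqrt", "abs", "pow",
                "min", "max", "floor")

spml_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "spml_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

#' Parse a model expression
#'
#' Parses expression text against the restricted model grammar and returns the
#' parsed language object.  Fails with a classed `spml_parse_error` (carrying
#' the parser's position information) on malformed text, and with
#' `spml_grammar_error` if the text parses as R but uses constructs outside
#' the model grammar.
#'
#' @param text Expression text, e.g. `"(-v + R*I)/tau"`.
#' @param allow_rand Permit `rand()` (layout-engine expressions only).
#' @return A language object (or numeric constant).
#' @export
parse_expression <- function(text, allow_rand = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  e <- tryCatch(str2lang(text), error = function(err) {
    spml_error("spml_parse_error",
               sprintf("parse error in \"%s\": %s", text, conditionMessage(err)))
  })
  check_expr_grammar(e, text, allow_rand)
  e
}

check_expr_grammar <- function(e, text, allow_rand) {
  if (is.numeric(e) || is.name(e)) return(invisible(TRUE))
  if (!is.call(e))
    spml_error("spml_grammar_error",
               sprintf("disallowed construct in \"%s\"", text))
  head <- as.character(e[[1L]])
  args <- as.list(e)[-1L]
  ok <- (head == "(" && length(args) == 1L) ||
    (head %in% .spml_unary_ops && length(args) == 1L) ||
    (head %in% .spml_binary_ops && length(args) == 2L) ||
    (head %in% .spml_funs) ||
    (allow_rand && head == "rand" && length(args) == 0L)
  if (!ok)
    spml_error("spml_grammar_error",
               sprintf("disallowed operator or function \"%s\" in \"%s\"",
                       head, text))
  for (a in args) check_expr_grammar(a, text, allow_rand)
  invisible(TRUE)
}

#' Free identifiers of a model expression
#'
#' @param text Expression text.
#' @param allow_rand Permit `rand()`.
#' @return Character vector of identifiers (function names excluded).
#' @export
expression_symbols <- function(text, allow_rand = FALSE) {
  e <- parse_expression(text, allow_rand = allow_rand)
  unique(collect_symbols(e))
}

collect_symbols <- function(e) {
  if (is.name(e)) return(as.character(e))
  if (!is.call(e)) return(character())
  unlist(lapply(as.list(e)[-1L], collect_symbols))
}

expression_uses_rand <- function(text) {
  e <- parse_expression(text, allow_rand = TRUE)
  uses <- function(x) {
    if (is.call(x)) {
      if (identical(as.character(x[[1L]]), "rand")) return(TRUE)
      return(any(vapply(as.list(x)[-1L], uses, logical(1L))))
    }
    FALSE
  }
  uses(e)
}

# Function table injected into every evaluation environment.
spml_fun_env <- function(parent = emptyenv()) {
  env <- new.env(parent = parent)
  for (f in c("exp", "log", "sin", "cos", "sqrt", "abs", "floor",
              "+", "-", "*", "/", "^", "(", "<", ">", "<=", ">=", "==", "!=",
              "&&", "||", "&", "|", "!"))
    assign(f, get(f, baseenv()), envir = env)
  assign("pow", function(a, b) a^b, envir = env)
  # element-wise so population-wide vector evaluation works; identical to
  # min/max on scalars
  assign("min", function(...) do.call(pmin, list(...)), envir = env)
  assign("max", function(...) do.call(pmax, list(...)), envir = env)
  env
}

#' Evaluate a model expression
#'
#' Evaluates `expression` under `bindings`.  Every free identifier must be
#' bound, otherwise a classed `spml_symbol_error` naming the identifier is
#' raised.  Boolean results are coerced to 0/1.
#'
#' @param expression Expression text.
#' @param bindings Named list (or environment) of identifier values.
#' @param allow_rand Permit `rand()`; draws come from `rand_fn`.
#' @param rand_fn Zero-argument function returning a uniform \[0,1) draw;
#'   defaults to `runif(1)` from the current RNG stream.
#' @return Numeric value (vectors propagate through vector bindings).
#' @export
evaluate_expression <- function(expression, bindings = list(),
                                allow_rand = FALSE, rand_fn = NULL) {
  e <- parse_expression(expression, allow_rand = allow_rand)
  syms <- unique(collect_symbols(e))
  unbound <- setdiff(syms, names(bindings))
  if (length(unbound) > 0L)
    spml_error("spml_symbol_error",
               sprintf("unbound identifier \"%s\" in \"%s\"",
                       unbound[[1L]], expression),
               identifier = unbound[[1L]])
  env <- new.env(parent = spml_fun_env())
  for (nm in names(bindings)) assign(nm, bindings[[nm]], envir = env)
  if (allow_rand)
    assign("rand", if (is.null(rand_fn)) function() stats::runif(1L) else rand_fn,
           envir = env)
  val <- eval(e, env)
  if (is.logical(val)) val <- as.numeric(val)
  val
}

# Rewrite scalar boolean operators to their vectorised forms so one eval can
# cover a whole population.
vectorise_booleans <- function(e) {
  if (!is.call(e)) return(e)
  head <- as.character(e[[1L]])
  if (head == "&&") e[[1L]] <- as.name("&")
  if (head == "||") e[[1L]] <- as.name("|")
  for (i in seq_along(e)[-1L]) e[[i]] <- vectorise_booleans(e[[i]])
  e
}

# Pre-compile an expression for repeated evaluation (simulator hot path).
compile_expression <- function(text, allow_rand = FALSE) {
  vectorise_booleans(parse_expression(text, allow_rand = allow_rand))
}

eval_compiled <- function(e, env) {
  val <- eval(e, env)
  if (is.logical(val)) as.numeric(val) else val
}
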