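# Procedural 3D layout engine.
#
# A layout rule assigns coordinates to population members like frames of an
# animation: frame 0 is the initial state (all variables 0) and the equations
# describe the transition to each subsequent frame.  For p = 1, ..., n-1 the
# equations are evaluated in declared order with the frame index bound to p;
# reading a variable yields its previous-frame value unless it has already
# been assigned earlier in the current frame.  Equations may call rand(), a
# uniform [0,1) draw from a stream seeded by the rule's seed, and a minimum
# pairwise distance can be enforced by rejection: a frame whose point lands
# too close to an accepted point is re-evaluated wholesale (all of its
# rand() draws refreshed) up to a retry cap.

#' Define a procedural layout rule
#'
#' @param name Identifier.
#' @param equations Ordered named list: variable -> expression text over the
#'   declared variables, the iteration index `p`, `rand()` and numeric
#'   literals.  Coordinates are in micrometres.
#' @param variables Declared variables; always includes `x`, `y`, `z` (added
#'   if missing).  Extra state variables may be declared to carry values
#'   between iterations.
#' @param seed Integer seed for the `rand()` stream.
#' @param min_distance Minimum pairwise Euclidean distance in micrometres
#'   (0 disables the constraint).
#' @export
layout_rule <- function(name, equations, variables = NULL, seed = 1L,
                        min_distance = 0) {
  if (min_distance < 0)
    spml_error("spml_validation_error", "min_distance must be >= 0")
  variables <- union(union(c("x", "y", "z"), names(equations)),
                     variables %||% character())
  for (v in names(equations)) {
    syms <- expression_symbols(equations[[v]], allow_rand = TRUE)
    bad <- setdiff(syms, c(variables, "p"))
    if (length(bad) > 0L)
      spml_error("spml_validation_error",
                 sprintf("layout equation for \"%s\" references undeclared \"%s\"",
                         v, bad[[1L]]))
  }
  structure(list(name = check_identifier(name),
                 variables = variables,
                 equations = lapply(as.list(equations), as.character),
                 seed = as.integer(seed),
                 min_distance = as.numeric(min_distance)),
            class = "spml_layout_rule")
}

layout_uses_rand <- function(rule) {
  any(vapply(rule$equations, expression_uses_rand, logical(1L)))
}

#' Generate coordinates from a layout rule
#'
#' @param rule A [layout_rule()].
#' @param n Population size (>= 1).
#' @param retry_cap Maximum re-draws per point under the minimum-distance
#'   constraint before a packing error is raised.
#' @return An `spml_coords` object: an `n x 3` matrix (columns x, y, z, in
#'   micrometres), index-aligned with neuron indices `0..n-1`.
#' @export
generate_layout <- function(rule, n, retry_cap = 10000L) {
  stopifnot(inherits(rule, "spml_layout_rule"), n >= 1L)
  compiled <- lapply(rule$equations, compile_expression, allow_rand = TRUE)
  uses_rand <- layout_uses_rand(rule)
  coords <- matrix(0, nrow = n, ncol = 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
  min_d2 <- rule$min_distance^2
  with_seed(rule$seed, {
    env <- new.env(parent = spml_fun_env())
    assign("rand", function() stats::runif(1L), envir = env)
    prev <- stats::setNames(rep(0, length(rule$variables)), rule$variables)
    # frame 0 is the initial state
    coords[1L, ] <- c(prev[["x"]], prev[["y"]], prev[["z"]])
    for (p in seq_len(n - 1L)) {
      tries <- 0L
      repeat {
        cur <- prev
        assign("p", p, envir = env)
        for (v in rule$variables) assign(v, prev[[v]], envir = env)
        for (v in names(compiled)) {
          cur[[v]] <- eval_compiled(compiled[[v]], env)
          assign(v, cur[[v]], envir = env)   # visible to later equations
        }
        pt <- c(cur[["x"]], cur[["y"]], cur[["z"]])
        ok <- TRUE
        if (min_d2 > 0) {
          d2 <- (coords[1:p, 1L] - pt[1L])^2 + (coords[1:p, 2L] - pt[2L])^2 +
            (coords[1:p, 3L] - pt[3L])^2
          ok <- all(d2 >= min_d2)
        }
        if (ok) break
        if (!uses_rand)
          spml_error("spml_constraint_error",
                     sprintf("deterministic layout \"%s\" violates min_distance at index %d",
                             rule$name, p))
        tries <- tries + 1L
        if (tries >= retry_cap)
          spml_error("spml_packing_error",
                     sprintf("layout \"%s\": could not place point %d within %d tries",
                             rule$name, p, retry_cap))
      }
      coords[p + 1L, ] <- c(cur[["x"]], cur[["y"]], cur[["z"]])
      prev <- cur
    }
  })
  structure(coords, class = "spml_coords", rule = rule$name,
            seed = rule$seed, min_distance = rule$min_distance)
}

#' @export
print.spml_coords <- function(x, ...) {
  cat(sprintf("<coordinate set: %d point(s)", nrow(x)))
  md <- attr(x, "min_distance")
  if (!is.null(md) && md > 0) cat(sprintf(", min distance %g um", md))
  cat(">\n")
  invisible(x)
}

#' Grid layout
#'
#' Points on a unit-spaced grid, filling rows of `row_length`:
#' `x = p mod row_length`, `y = floor(p / row_length)`, `z = 0` (times
#' `spacing`).  Realised through the generic layout-rule machinery.
#'
#' @param n Number of points.
#' @param row_length Points per row (>= 1).
#' @param spacing Grid spacing in micrometres (default 1).
#' @export
grid_layout <- function(n, row_length, spacing = 1) {
  stopifnot(n >= 1L, row_length >= 1L)
  rl <- xnum(row_length); sp <- xnum(spacing)
  rule <- layout_rule("grid", equations = list(
    x = sprintf("(p - %s * floor(p / %s)) * %s", rl, rl, sp),
    y = sprintf("floor(p / %s) * %s", rl, sp),
    z = "0"))
  generate_layout(rule, n)
}

#' Random box layout
#'
#' Coordinates drawn uniformly from `[0, side)^3` (default side 300 um, the
#' scale of the striatal-like cube fixture), deterministic under `seed`, with
#' optional minimum-distance rejection.
#'
#' @param n Number of points.
#' @param side Cube side length in micrometres.
#' @param seed Integer seed.
#' @param min_distance Minimum pairwise distance in micrometres.
#' @export
random_box_layout <- function(n, side = 300, seed = 1L, min_distance = 0) {
  stopifnot(n >= 1L, side > 0)
  s <- xnum(side)
  rule <- layout_rule("random_box", equations = list(
    x = sprintf("rand() * %s", s),
    y = sprintf("rand() * %s", s),
    z = sprintf("rand() * %s", s)),
    seed = seed, min_distance = min_distance)
  generate_layout(rule, n)
}

#' Export coordinates as CSV (`index,x,y,z`)
#' @param coords An `spml_coords`.
#' @param path Output file.
#' @export
write_coords_csv <- function(coords, path) {
  df <- data.frame(index = seq_len(nrow(coords)) - 1L,
                   x = coords[, 1L], y = coords[, 2L], z = coords[, 3L])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read coordinates from CSV
#' @param path CSV file with columns `index,x,y,z`.
#' @export
read_coords_csv <- function(path) {
  df <- utils::read.csv(path)
  m <- as.matrix(df[order(df$index), c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  structure(m, class = "spml_coords")
}

# Layout XML fragment inside the project file:
#   <Layout name= seed= minimum_distance=>
#     <Variable name="x"><Equation>..</Equation></Variable> ...
write_layout_xml <- function(parent, rule) {
  ln <- xml2::xml_add_child(parent, "Layout", name = rule$name,
                            seed = as.character(rule$seed),
                            minimum_distance = xnum(rule$min_distance))
  for (v in rule$variables) {
    vn <- xml2::xml_add_child(ln, "Variable", name = v)
    if (!is.null(rule$equations[[v]]))
      xml2::xml_add_child(vn, "Equation", rule$equations[[v]])
  }
  ln
}

read_layout_xml <- function(node) {
  eqs <- list(); vars <- character()
  for (vn in xml2::xml_find_all(node, "Variable")) {
    nm <- chr_attr(vn, "name")
    vars <- c(vars, nm)
    en <- xml2::xml_find_first(vn, "Equation")
    if (!inherits(en, "xml_missing")) eqs[[nm]] <- trimws(xml2::xml_text(en))
  }
  layout_rule(chr_attr(node, "name"), equations = eqs, variables = vars,
              seed = as.integer(num_attr(node, "seed", 1)),
              min_distance = num_attr(node, "minimum_distance", 0))
}
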