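# Pluggable connectivity generation.
#
# A generator script is a plain-text file holding metadata comments followed
# by an entry-point function whose first two arguments are `srclocs` and
# `dstlocs` (lists of (x, y, z) tuples).  Metadata comments:
#   #PARNAME: <label>     one per extra argument, in argument order
#   #LOC: <row>,<col>     grid cell for the parameter's input widget
#   #HASWEIGHT            the script returns per-connection weights
#   #HASDELAY             the script returns per-connection delays (ms)
# Scripts are executed in a whitelist sandbox (pure computation only; no
# file, network or system access).  The result is an explicit connection
# list stored together with its generation recipe, so a persisted model is
# always plain, fully explicit connectivity that any reader can load.

#' Parse generator-script metadata
#'
#' @param source_text Script text.
#' @return An `spml_generator`: entry name, ordered parameter table
#'   (label, grid_row, grid_col), `has_weight`, `has_delay`, and the source
#'   text.
#' @export
parse_generator_metadata <- function(source_text) {
  lines <- strsplit(source_text, "\n", fixed = TRUE)[[1L]]
  par_lines <- grep("^\\s*#PARNAME:", lines)
  labels <- trimws(sub("^\\s*#PARNAME:", "", lines[par_lines]))
  if (anyDuplicated(labels))
    spml_error("spml_validation_error", "duplicate #PARNAME labels")
  locs <- lapply(par_lines, function(i) {
    # the #LOC line for a parameter follows its #PARNAME line
    j <- i + 1L
    if (j <= length(lines) && grepl("^\\s*#LOC:", lines[[j]])) {
      rc <- as.integer(strsplit(trimws(sub("^\\s*#LOC:", "", lines[[j]])),
                                ",")[[1L]])
      c(row = rc[[1L]], col = rc[[2L]])
    } else c(row = NA_integer_, col = NA_integer_)
  })
  cells <- vapply(locs, function(l) paste(l, collapse = ","), "")
  if (anyDuplicated(cells[!grepl("NA", cells)]))
    spml_error("spml_layout_error", "duplicate #LOC grid cell")

  exprs <- tryCatch(parse(text = source_text),
                    error = function(e)
                      spml_error("spml_parse_error",
                                 sprintf("cannot parse generator script: %s",
                                         conditionMessage(e))))
  entry_name <- NULL; entry_formals <- NULL
  for (e in exprs) {
    if (is.call(e) && as.character(e[[1L]]) %in% c("<-", "=") &&
        is.call(e[[3L]]) && identical(as.character(e[[3L]][[1L]]), "function")) {
      fmls <- names(e[[3L]][[2L]])
      if (length(fmls) >= 2L && fmls[[1L]] == "srclocs" &&
          fmls[[2L]] == "dstlocs") {
        entry_name <- as.character(e[[2L]])
        entry_formals <- fmls
        break
      }
    }
  }
  if (is.null(entry_name))
    spml_error("spml_validation_error",
               "no entry point with leading arguments (srclocs, dstlocs) found")
  n_extra <- length(entry_formals) - 2L
  if (n_extra != length(labels))
    spml_error("spml_arity_error",
               sprintf("%d #PARNAME line(s) but entry point takes %d extra argument(s)",
                       length(labels), n_extra))
  params <- if (length(labels) > 0L)
    data.frame(label = labels,
               grid_row = vapply(locs, `[[`, 0L, "row"),
               grid_col = vapply(locs, `[[`, 0L, "col"),
               stringsAsFactors = FALSE)
  else data.frame(label = character(), grid_row = integer(),
                  grid_col = integer(), stringsAsFactors = FALSE)
  structure(list(source_text = source_text, entry_name = entry_name,
                 params = params,
                 has_weight = any(grepl("^\\s*#HASWEIGHT\\s*$", lines)),
                 has_delay = any(grepl("^\\s*#HASDELAY\\s*$", lines))),
            class = "spml_generator")
}

#' Load a generator script from a file
#' @param path Script file path.
#' @export
read_generator_script <- function(path) {
  parse_generator_metadata(paste(readLines(path, warn = FALSE),
                                 collapse = "\n"))
}

# Whitelisted functions available to generator scripts: arithmetic, control
# flow and vector plumbing, plus seeded RNG.  No file/network/system access.
generator_sandbox <- function() {
  env <- new.env(parent = emptyenv())
  allowed <- c("+", "-", "*", "/", "^", "%%", "%/%", "(", "{", "[", "[[",
               "<-", "=", "<", ">", "<=", ">=", "==", "!=", "&", "|", "&&",
               "||", "!", "if", "for", "while", "function", "return",
               "c", "list", "length", "seq_len", "seq_along", "seq", "rep",
               "numeric", "integer", "logical", "vapply", "sapply", "lapply",
               "unlist", "which", "sum", "prod", "cumsum", "min", "max",
               "pmin", "pmax", "abs", "sqrt", "exp", "log", "sin", "cos",
               "floor", "ceiling", "round", "outer", "matrix", "nrow",
               "ncol", "t", "as.numeric", "as.integer", "names", "is.null",
               "stopifnot", "ifelse", "do.call", "rbind", "cbind", "append")
  for (f in allowed) assign(f, get(f, baseenv()), envir = env)
  assign("set.seed", function(s)
    suppressWarnings(set.seed(as.integer(s), kind = "Mersenne-Twister",
                              normal.kind = "Inversion",
                              sample.kind = "Rejection")), envir = env)
  assign("runif", stats::runif, envir = env)
  assign("rnorm", stats::rnorm, envir = env)
  env
}

#' Generation recipe
#'
#' Everything needed to regenerate a connection list bit-exactly: the script
#' text, the ordered parameter values, the source and destination sizes, and
#' (for weight-generating scripts) the weight-update property the weights
#' fill.
#'
#' @param source_text,values,n_src,n_dst,weight_target See description.
#' @export
generation_recipe <- function(source_text, values, n_src, n_dst,
                              weight_target = NULL) {
  structure(list(source_text = as.character(source_text),
                 values = as.numeric(values),
                 n_src = as.integer(n_src), n_dst = as.integer(n_dst),
                 weight_target = weight_target),
            class = "spml_recipe")
}

recipe_cache_key <- function(recipe) {
  md5_of_text(paste(recipe$source_text,
                    paste(xnum(recipe$values), collapse = ","),
                    recipe$n_src, recipe$n_dst, sep = "\x1f"))
}

#' Run a generator script
#'
#' Executes the script's entry point on the two coordinate sets in the
#' sandbox.  The script must return a list with elements `src` and `dst`
#' (0-based indices), plus `delay` iff declared `#HASDELAY` (ms) and `weight`
#' iff declared `#HASWEIGHT`.  The resulting connection list carries its
#' generation recipe.
#'
#' @param script An `spml_generator` (or script text).
#' @param srclocs,dstlocs `spml_coords` (or n x 3 matrices).
#' @param values Numeric parameter values, one per `#PARNAME`, in order.
#' @param weight_target Name of the weight-update property the generated
#'   weights fill (required when the script has `#HASWEIGHT`).
#' @return An [connection_list()] with a recipe.
#' @export
run_generator <- function(script, srclocs, dstlocs, values = numeric(),
                          weight_target = NULL) {
  if (is.character(script)) script <- parse_generator_metadata(script)
  stopifnot(inherits(script, "spml_generator"))
  if (length(values) != nrow(script$params))
    spml_error("spml_arity_error",
               sprintf("script takes %d parameter(s), %d value(s) given",
                       nrow(script$params), length(values)))
  if (script$has_weight && is.null(weight_target))
    spml_error("spml_contract_error",
               "script generates weights: weight_target must name the property to fill")
  src_list <- lapply(seq_len(nrow(srclocs)), function(i) as.numeric(srclocs[i, 1:3]))
  dst_list <- lapply(seq_len(nrow(dstlocs)), function(i) as.numeric(dstlocs[i, 1:3]))

  env <- new.env(parent = generator_sandbox())
  ok <- tryCatch({ eval(parse(text = script$source_text), env); TRUE },
                 error = function(e)
                   spml_error("spml_execution_error",
                              sprintf("generator script failed to load: %s",
                                      conditionMessage(e))))
  entry <- get(script$entry_name, envir = env)
  res <- preserve_rng(
    tryCatch(do.call(entry, c(list(src_list, dst_list),
                              as.list(as.numeric(values)))),
             error = function(e)
               spml_error("spml_execution_error",
                          sprintf("generator script raised: %s",
                                  conditionMessage(e)))))
  src <- as.integer(res$src); dst <- as.integer(res$dst)
  if (length(src) > 0L &&
      (min(src) < 0L || max(src) >= nrow(srclocs) ||
       min(dst) < 0L || max(dst) >= nrow(dstlocs)))
    spml_error("spml_validation_error",
               "generator returned out-of-range neuron indices")
  delay <- if (script$has_delay) as.numeric(res$delay) else 0
  weights <- if (script$has_weight) as.numeric(res$weight) else NULL
  connection_list(src = src, dst = dst, delay = delay, weights = weights,
                  recipe = generation_recipe(script$source_text, values,
                                             nrow(srclocs), nrow(dstlocs),
                                             weight_target))
}

#' Does a stored connection list need regeneration?
#'
#' True iff the script text, the parameter values, or either population size
#' changed (exact equality; even a whitespace-only script edit triggers
#' regeneration).
#'
#' @param recipe The stored `spml_recipe`.
#' @param source_text,values,n_src,n_dst Current script text, values, sizes.
#' @export
needs_regeneration <- function(recipe, source_text, values, n_src, n_dst) {
  !(identical(recipe$source_text, as.character(source_text)) &&
      identical(recipe$values, as.numeric(values)) &&
      identical(recipe$n_src, as.integer(n_src)) &&
      identical(recipe$n_dst, as.integer(n_dst)))
}

# Recipe <-> XML (inside <Annotations> of a <ConnectionList>), under the
# annotations namespace so foreign readers can skip it.
write_recipe_xml <- function(parent, recipe) {
  rn <- xml2::xml_add_child(parent, "ann:Recipe",
                            n_src = as.character(recipe$n_src),
                            n_dst = as.character(recipe$n_dst))
  if (!is.null(recipe$weight_target))
    xml2::xml_set_attr(rn, "weight_target", recipe$weight_target)
  sn <- xml2::xml_add_child(rn, "ann:Script")
  xml2::xml_add_child(sn, xml2::xml_cdata(recipe$source_text))
  for (v in recipe$values)
    xml2::xml_add_child(rn, "ann:Value", value = xnum(v))
  rn
}

read_recipe_xml <- function(annotations_node) {
  rn <- xml2::xml_find_first(annotations_node, ".//*[local-name()='Recipe']")
  if (inherits(rn, "xml_missing")) return(NULL)
  sn <- xml2::xml_find_first(rn, ".//*[local-name()='Script']")
  vals <- vapply(xml2::xml_find_all(rn, ".//*[local-name()='Value']"),
                 function(n) num_attr(n, "value"), 0)
  generation_recipe(xml2::xml_text(sn), vals,
                    as.integer(num_attr(rn, "n_src")),
                    as.integer(num_attr(rn, "n_dst")),
                    weight_target = chr_attr(rn, "weight_target"))
}

#' Persist a connection list with its recipe as an XML fragment
#'
#' Emits a plain `<ConnectionList>` with every triplet explicit (so the file
#' is always valid, fully explicit connectivity) plus the recipe inside
#' `<Annotations>`.  [read_connection_fragment()] restores both without
#' regeneration.
#'
#' @param cl An [connection_list()].
#' @param recipe An `spml_recipe` (defaults to the list's own recipe).
#' @return XML text of the fragment.
#' @export
persist_with_recipe <- function(cl, recipe = cl$recipe) {
  doc <- xml2::xml_new_root("ConnectionListFragment")
  xml2::xml_set_attr(doc, "xmlns:ann", ann_ns)
  cl2 <- cl; cl2$recipe <- recipe
  node <- write_connection_list_xml(doc, cl2)
  xml2::xml_set_attr(node, "xmlns:ann", ann_ns)
  as.character(node)
}

#' Load a persisted connection-list fragment
#' @param text XML text or file path of a `<ConnectionList>` fragment.
#' @return An [connection_list()] (with recipe if present).
#' @export
read_connection_fragment <- function(text) {
  node <- xml2::xml_root(xml2::read_xml(text))
  if (xml2::xml_name(node) != "ConnectionList")
    spml_error("spml_parse_error",
               sprintf("expected <ConnectionList>, found <%s>",
                       xml2::xml_name(node)))
  read_connection_list_xml(node)
}

#' Regenerate a connection list from its recipe
#' @param recipe An `spml_recipe`.
#' @param srclocs,dstlocs Coordinate sets matching the recipe's sizes.
#' @export
regenerate_from_recipe <- function(recipe, srclocs, dstlocs) {
  if (nrow(srclocs) != recipe$n_src || nrow(dstlocs) != recipe$n_dst)
    spml_error("spml_contract_error",
               "coordinate set sizes do not match the recipe")
  run_generator(parse_generator_metadata(recipe$source_text), srclocs,
                dstlocs, recipe$values, weight_target = recipe$weight_target)
}

#' Path to a shipped builtin generator script
#' @param name `"fixed_radius"` or `"gaussian_field"`.
#' @export
builtin_generator_path <- function(name = c("fixed_radius", "gaussian_field")) {
  name <- match.arg(name)
  system.file("extdata", "generators", paste0(name, ".R"),
              package = "spineml", mustWork = TRUE)
}
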