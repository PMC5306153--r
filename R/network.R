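# Network layer: populations bound to components, projections (each with at
# least one synapse = connectivity + weight-update + postsynapse), generic
# inputs, and the property values that parameterise component instances.

#' Property value variants
#'
#' A property (a parameter or a state-variable initial value) of a population
#' or synapse component can be a fixed scalar, an explicit per-index list, or
#' a seeded draw from a uniform or normal distribution.
#'
#' @param value,values,indices,min,max,mean,variance,seed See variants.
#' @name property_value
NULL

#' @rdname property_value
#' @export
fixed_value <- function(value) {
  structure(list(variant = "fixed", value = as.numeric(value)),
            class = "spml_property_value")
}

#' @rdname property_value
#' @export
value_list <- function(indices, values) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices) || any(indices < 0L))
    spml_error("spml_validation_error",
               "value_list indices must be unique and 0-based")
  if (length(indices) != length(values))
    spml_error("spml_validation_error",
               "value_list indices and values differ in length")
  structure(list(variant = "value_list", indices = indices,
                 values = as.numeric(values)),
            class = "spml_property_value")
}

#' @rdname property_value
#' @export
uniform_value <- function(min, max, seed = NULL) {
  if (!(min < max))
    spml_error("spml_validation_error", "uniform distribution needs min < max")
  structure(list(variant = "uniform", min = as.numeric(min),
                 max = as.numeric(max),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "spml_property_value")
}

#' @rdname property_value
#' @export
normal_value <- function(mean, variance, seed = NULL) {
  if (variance < 0)
    spml_error("spml_validation_error", "normal distribution needs variance >= 0")
  structure(list(variant = "normal", mean = as.numeric(mean),
                 variance = as.numeric(variance),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "spml_property_value")
}

#' Sample n values from a property value
#'
#' Identical `(v, n, seed)` always yields identical output.  The `seed`
#' argument is the fallback stream seed used when the distribution carries no
#' seed of its own (in a full model run it is derived from the project master
#' seed by stable hashing of the property path).
#'
#' @param v An `spml_property_value`.
#' @param n Population (or instance) size, >= 1.
#' @param seed Fallback integer seed.
#' @return Numeric vector of length `n`.
#' @export
sample_property <- function(v, n, seed = 1L) {
  stopifnot(inherits(v, "spml_property_value"), n >= 1L)
  switch(v$variant,
    fixed = rep(v$value, n),
    value_list = {
      missing <- setdiff(0:(n - 1L), v$indices)
      if (length(missing) > 0L)
        spml_error("spml_coverage_error",
                   sprintf("value_list does not cover indices: %s",
                           paste(utils::head(missing, 5L), collapse = ", ")))
      if (any(v$indices >= n))
        spml_error("spml_coverage_error",
                   "value_list indices exceed the population size")
      out <- numeric(n)
      out[v$indices + 1L] <- v$values
      out
    },
    uniform = with_seed(v$seed %||% seed, stats::runif(n, v$min, v$max)),
    normal = with_seed(v$seed %||% seed,
                       stats::rnorm(n, v$mean, sqrt(v$variance))),
    spml_error("spml_contract_error", "unknown property variant"))
}

#' Define a population
#'
#' @param name Identifier, unique in the network.
#' @param size Number of neurons (>= 1).
#' @param component_ref Name of the component instantiated by each neuron.
#' @param properties Named list of `spml_property_value`s; names must be
#'   parameters or state variables of the component.
#' @param layout_ref Optional name of a layout rule (annotation).
#' @param colour Optional display colour (annotation).
#' @export
population <- function(name, size, component_ref, properties = list(),
                       layout_ref = NULL, colour = NULL) {
  if (size < 1L) spml_error("spml_validation_error", "population size must be >= 1")
  structure(list(name = check_identifier(name), size = as.integer(size),
                 component_ref = as.character(component_ref),
                 properties = as.list(properties),
                 layout_ref = layout_ref, colour = colour),
            class = "spml_population")
}

#' Connectivity schemes
#'
#' @param p Connection probability in \[0,1\].
#' @param seed Integer seed for the probabilistic scheme.
#' @param allow_self Keep self-pairs in recurrent fixed-probability
#'   connectivity (default drops (i,i) when source == destination).
#' @param triplets,delays,weights See [connection_list()].
#' @name connectivity
NULL

#' @rdname connectivity
#' @export
one_to_one <- function() {
  structure(list(variant = "one_to_one"), class = "spml_connectivity")
}

#' @rdname connectivity
#' @export
all_to_all <- function() {
  structure(list(variant = "all_to_all"), class = "spml_connectivity")
}

#' @rdname connectivity
#' @export
fixed_probability <- function(p, seed = NULL, allow_self = TRUE) {
  if (p < 0 || p > 1)
    spml_error("spml_validation_error", "fixed_probability needs 0 <= p <= 1")
  structure(list(variant = "fixed_probability", p = as.numeric(p),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 allow_self = isTRUE(allow_self)),
            class = "spml_connectivity")
}

#' Explicit connection list
#'
#' The fully explicit connectivity form: 0-based (source index, destination
#' index, delay-in-ms) triplets, optionally with a parallel weight vector and
#' a generation recipe annotation.  Duplicate (src, dst) pairs are permitted
#' (multi-synapses).
#'
#' @param src,dst 0-based integer index vectors.
#' @param delay Delays in ms (recycled scalar allowed), >= 0.
#' @param weights Optional numeric vector parallel to the triplets.
#' @param recipe Optional `spml_recipe` (see [run_generator()]).
#' @export
connection_list <- function(src = integer(), dst = integer(), delay = 0,
                            weights = NULL, recipe = NULL) {
  src <- as.integer(src); dst <- as.integer(dst)
  if (length(src) != length(dst))
    spml_error("spml_validation_error", "src and dst differ in length")
  delay <- rep_len(as.numeric(delay), length(src))
  if (length(src) > 0L && any(delay < 0))
    spml_error("spml_validation_error", "delays must be >= 0 ms")
  if (!is.null(weights) && length(weights) != length(src))
    spml_error("spml_validation_error",
               "weights must be parallel to the triplets")
  structure(list(variant = "connection_list", src = src, dst = dst,
                 delay = delay,
                 weights = if (is.null(weights)) NULL else as.numeric(weights),
                 recipe = recipe),
            class = c("spml_connection_list", "spml_connectivity"))
}

#' @export
print.spml_connection_list <- function(x, ...) {
  cat(sprintf("<connection list: %d connection(s)%s%s>\n", length(x$src),
              if (!is.null(x$weights)) " +weights" else "",
              if (!is.null(x$recipe)) " +recipe" else ""))
  invisible(x)
}

#' Expand a connectivity scheme into an explicit connection list
#'
#' `one_to_one` gives (i,i); `all_to_all` the full cross product in
#' (src-major, dst-minor) order; `fixed_probability` includes each ordered
#' pair independently with probability p from the seeded stream (self-pairs
#' are dropped for recurrent use when the scheme was built with
#' `allow_self = FALSE`); an explicit connection list is returned unchanged.
#' Delays default to 0 ms.
#'
#' @param scheme An `spml_connectivity`.
#' @param n_src,n_dst Population sizes (>= 1).
#' @param seed Fallback seed for `fixed_probability` without its own seed.
#' @param recurrent Source and destination are the same population.
#' @return An [connection_list()].
#' @export
instantiate_connectivity <- function(scheme, n_src, n_dst, seed = 1L,
                                     recurrent = FALSE) {
  stopifnot(inherits(scheme, "spml_connectivity"), n_src >= 1L, n_dst >= 1L)
  switch(scheme$variant,
    one_to_one = {
      if (n_src != n_dst)
        spml_error("spml_contract_error",
                   sprintf("one_to_one needs equal sizes (%d vs %d)",
                           n_src, n_dst))
      connection_list(src = 0:(n_src - 1L), dst = 0:(n_src - 1L))
    },
    all_to_all = {
      src <- rep(0:(n_src - 1L), each = n_dst)
      dst <- rep(0:(n_dst - 1L), times = n_src)
      connection_list(src = src, dst = dst)
    },
    fixed_probability = {
      src <- rep(0:(n_src - 1L), each = n_dst)
      dst <- rep(0:(n_dst - 1L), times = n_src)
      u <- with_seed(scheme$seed %||% seed, stats::runif(n_src * n_dst))
      keep <- u < scheme$p
      if (recurrent && !scheme$allow_self) keep <- keep & (src != dst)
      connection_list(src = src[keep], dst = dst[keep])
    },
    connection_list = scheme,
    spml_error("spml_contract_error", "unknown connectivity variant"))
}

#' Component binding (weight update or postsynapse of a synapse)
#' @param component_ref Component name.
#' @param properties Named list of `spml_property_value`s.
#' @export
component_binding <- function(component_ref, properties = list()) {
  structure(list(component_ref = as.character(component_ref),
                 properties = as.list(properties)),
            class = "spml_component_binding")
}

#' Define a synapse
#' @param connectivity An `spml_connectivity`.
#' @param weight_update [component_binding()] of kind `weight_update`.
#' @param postsynapse [component_binding()] of kind `postsynapse`.
#' @export
synapse <- function(connectivity, weight_update, postsynapse) {
  structure(list(connectivity = connectivity, weight_update = weight_update,
                 postsynapse = postsynapse),
            class = "spml_synapse")
}

#' Define a projection
#' @param source,destination Population names.
#' @param synapses Non-empty list of [synapse()]s.
#' @export
projection <- function(source, destination, synapses) {
  if (length(synapses) < 1L)
    spml_error("spml_validation_error", "a projection needs at least one synapse")
  structure(list(source = as.character(source),
                 destination = as.character(destination),
                 synapses = unname(as.list(synapses))),
            class = "spml_projection")
}

#' Define a generic input (direct port-to-port connection)
#' @param src_population,src_port Source population and send port.
#' @param dst_population,dst_port Destination population and receive port.
#' @param connectivity An `spml_connectivity`.
#' @export
generic_input <- function(src_population, src_port, dst_population, dst_port,
                          connectivity = one_to_one()) {
  structure(list(src_population = src_population, src_port = src_port,
                 dst_population = dst_population, dst_port = dst_port,
                 connectivity = connectivity),
            class = "spml_generic_input")
}

#' Define a network
#' @param name Identifier.
#' @param populations,projections,generic_inputs Lists of the respective
#'   elements.
#' @export
network <- function(name, populations = list(), projections = list(),
                    generic_inputs = list()) {
  structure(list(name = check_identifier(name),
                 populations = unname(as.list(populations)),
                 projections = unname(as.list(projections)),
                 generic_inputs = unname(as.list(generic_inputs))),
            class = "spml_network")
}

#' @export
print.spml_network <- function(x, ...) {
  cat(sprintf("<network \"%s\": %d population(s), %d projection(s), %d generic input(s)>\n",
              x$name, length(x$populations), length(x$projections),
              length(x$generic_inputs)))
  for (p in x$populations)
    cat(sprintf("  %s [%d x %s]\n", p$name, p$size, p$component_ref))
  for (pr in x$projections)
    cat(sprintf("  %s -> %s (%d synapse(s))\n", pr$source, pr$destination,
                length(pr$synapses)))
  invisible(x)
}

find_population <- function(net, name) {
  Find(function(p) p$name == name, net$populations)
}

find_port <- function(comp, name) Find(function(p) p$name == name, comp$ports)

#' Validate a network against a component set
#'
#' Checks reference integrity (component refs, projection endpoints,
#' connection-list index bounds, property names against the component's
#' parameters/state variables), synapse component kinds, and the port
#' compatibility of every generic input.
#'
#' @param net An `spml_network`.
#' @param components Named list of `spml_component`s.
#' @return List of violation records; empty iff valid.
#' @export
validate_network <- function(net, components) {
  v <- list()
  add <- function(el, rule, msg) v[[length(v) + 1L]] <<- violation(el, rule, msg)
  pop_names <- vapply(net$populations, `[[`, "", "name")
  for (d in unique(pop_names[duplicated(pop_names)]))
    add(d, "unique_population", sprintf("population \"%s\" declared twice", d))

  check_binding <- function(b, n, kind, where) {
    comp <- components[[b$component_ref]]
    if (is.null(comp)) {
      add(b$component_ref, "dangling_component_ref",
          sprintf("%s references missing component \"%s\"", where,
                  b$component_ref))
      return()
    }
    if (!is.null(kind) && comp$kind != kind)
      add(b$component_ref, "component_kind",
          sprintf("%s component \"%s\" has kind %s, expected %s", where,
                  b$component_ref, comp$kind, kind))
    known <- component_property_names(comp)
    for (nm in names(b$properties)) if (!(nm %in% known))
      add(nm, "unknown_property",
          sprintf("%s: property \"%s\" is not a parameter or state variable of \"%s\"",
                  where, nm, b$component_ref))
  }

  for (p in net$populations)
    check_binding(list(component_ref = p$component_ref,
                       properties = p$properties),
                  p$size, NULL, sprintf("population \"%s\"", p$name))

  for (pr in net$projections) {
    src <- find_population(net, pr$source)
    dst <- find_population(net, pr$destination)
    if (is.null(src))
      add(pr$source, "missing_population",
          sprintf("projection source \"%s\" not found", pr$source))
    if (is.null(dst))
      add(pr$destination, "missing_population",
          sprintf("projection destination \"%s\" not found", pr$destination))
    for (sy in pr$synapses) {
      check_binding(sy$weight_update, NULL, "weight_update",
                    sprintf("projection %s->%s weight update", pr$source,
                            pr$destination))
      check_binding(sy$postsynapse, NULL, "postsynapse",
                    sprintf("projection %s->%s postsynapse", pr$source,
                            pr$destination))
      if (inherits(sy$connectivity, "spml_connection_list") &&
          !is.null(src) && !is.null(dst)) {
        cl <- sy$connectivity
        if (length(cl$src) > 0L &&
            (max(cl$src) >= src$size || max(cl$dst) >= dst$size ||
             min(cl$src) < 0L || min(cl$dst) < 0L))
          add(sprintf("%s->%s", pr$source, pr$destination),
              "connection_index_bounds",
              "connection list indices outside population bounds")
      }
      if (sy$connectivity$variant == "one_to_one" && !is.null(src) &&
          !is.null(dst) && src$size != dst$size)
        add(sprintf("%s->%s", pr$source, pr$destination), "one_to_one_sizes",
            "one_to_one connectivity needs equal population sizes")
    }
  }

  for (gi in net$generic_inputs) {
    sp <- find_population(net, gi$src_population)
    dp <- find_population(net, gi$dst_population)
    if (is.null(sp) || is.null(dp)) {
      add(sprintf("%s->%s", gi$src_population, gi$dst_population),
          "missing_population", "generic input endpoint population not found")
      next
    }
    sc <- components[[sp$component_ref]]; dc <- components[[dp$component_ref]]
    if (is.null(sc) || is.null(dc)) next  # already reported above
    spo <- find_port(sc, gi$src_port); dpo <- find_port(dc, gi$dst_port)
    if (is.null(spo) || is.null(dpo) ||
        spo$direction != "send" || dpo$direction != "receive") {
      add(sprintf("%s.%s -> %s.%s", gi$src_population, gi$src_port,
                  gi$dst_population, gi$dst_port), "missing_port",
          "generic input references a missing or mis-directed port")
    } else if (!check_port_compatibility(spo, dpo)) {
      add(sprintf("%s.%s -> %s.%s", gi$src_population, gi$src_port,
                  gi$dst_population, gi$dst_port), "port_mismatch",
          sprintf("incompatible ports: %s/%s send vs %s/%s receive",
                  spo$kind, spo$dimension, dpo$kind, dpo$dimension))
    }
  }
  v
}

#' Copy the shared property configuration from one population to another
#'
#' For every property name shared by the two populations' components, the
#' destination takes the source's property value; other destination
#' properties are unchanged.  Non-shared source property names are skipped
#' and reported.
#'
#' @param src,dst `spml_population`s.
#' @param components Named list of components (to determine the shared names).
#' @return `list(population = <updated dst>, copied = <names>,
#'   skipped = <names>)`.
#' @export
copy_properties <- function(src, dst, components) {
  sc <- components[[src$component_ref]]; dc <- components[[dst$component_ref]]
  if (is.null(sc) || is.null(dc))
    spml_error("spml_contract_error", "both components must be supplied")
  shared <- intersect(component_property_names(sc),
                      component_property_names(dc))
  copied <- intersect(names(src$properties), shared)
  skipped <- setdiff(names(src$properties), shared)
  for (nm in copied) dst$properties[[nm]] <- src$properties[[nm]]
  list(population = dst, copied = copied, skipped = skipped)
}
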