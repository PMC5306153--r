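# Experiment layer: the separable description of what is done to a model —
# simulation duration and step, inputs, loggers and property overrides —
# analogous to an experimental paradigm applied to an animal.

#' Input specifications
#'
#' `constant_input` holds a fixed analog value; `time_varying_input` is a
#' piecewise-constant step signal (value of the latest step at or before t,
#' 0 before the first step; no interpolation); `regular_spike_input` emits
#' spikes at `start + k/rate` for `k >= 0` while the time is below `stop`.
#'
#' @param value Analog value.
#' @param steps Two-column structure of (t in s, value) pairs with strictly
#'   increasing times: a data.frame or a list of `c(t, value)`.
#' @param rate Spike rate in Hz (>= 0).
#' @param start,stop Window in seconds.
#' @param target Population name.
#' @param port Receive-port name on the target's component.
#' @param indices Optional 0-based index subset (default: all neurons).
#' @name input_spec
NULL

input_base <- function(variant, target, port, indices, extra) {
  structure(c(list(variant = variant, target = as.character(target),
                   port = as.character(port),
                   indices = if (is.null(indices)) NULL else as.integer(indices)),
              extra),
            class = "spml_input")
}

#' @rdname input_spec
#' @export
constant_input <- function(target, port, value, indices = NULL) {
  input_base("constant", target, port, indices, list(value = as.numeric(value)))
}

#' @rdname input_spec
#' @export
time_varying_input <- function(target, port, steps, indices = NULL) {
  if (is.data.frame(steps)) steps <- lapply(seq_len(nrow(steps)), function(i)
    c(steps[[1L]][[i]], steps[[2L]][[i]]))
  t <- vapply(steps, `[[`, 0, 1L)
  v <- vapply(steps, `[[`, 0, 2L)
  if (is.unsorted(t, strictly = TRUE))
    spml_error("spml_validation_error",
               "time_varying steps must have strictly increasing times")
  input_base("time_varying", target, port, indices,
             list(times = as.numeric(t), values = as.numeric(v)))
}

#' @rdname input_spec
#' @export
regular_spike_input <- function(target, port, rate, start = 0, stop = Inf,
                                indices = NULL) {
  if (rate < 0) spml_error("spml_validation_error", "rate must be >= 0")
  input_base("regular_spikes", target, port, indices,
             list(rate = as.numeric(rate), start = as.numeric(start),
                  stop = as.numeric(stop)))
}

#' Analog value of an input at time t
#' @param spec An `spml_input` (constant or time_varying).
#' @param t Time in seconds.
#' @export
input_value <- function(spec, t) {
  switch(spec$variant,
    constant = rep(spec$value, length(t)),
    time_varying = vapply(t, function(tt) {
      i <- findInterval(tt, spec$times)
      if (i == 0L) 0 else spec$values[[i]]
    }, 0),
    spml_error("spml_contract_error",
               sprintf("input_value is undefined for %s inputs", spec$variant)))
}

#' Spike times of a regular spike input
#' @param spec A [regular_spike_input()].
#' @return Times in seconds: `start + k/rate` for `k >= 0`, below `stop`.
#' @export
spike_times <- function(spec) {
  stopifnot(spec$variant == "regular_spikes")
  if (spec$rate == 0 || spec$stop <= spec$start) return(numeric())
  k_max <- ceiling((spec$stop - spec$start) * spec$rate) + 1L
  t <- spec$start + (0:k_max) / spec$rate
  t[t < spec$stop]
}

#' Define a logger
#'
#' @param target Population name.
#' @param port Port or state-variable name to record.
#' @param kind `"analog"` (continuous trace) or `"event"` (spike list).
#' @param indices Optional 0-based index subset.
#' @param name Output base name (defaults to `target_port`).
#' @export
logger <- function(target, port, kind = c("analog", "event"), indices = NULL,
                   name = NULL) {
  kind <- match.arg(kind)
  structure(list(target = as.character(target), port = as.character(port),
                 kind = kind,
                 indices = if (is.null(indices)) NULL else as.integer(indices),
                 name = name %||% paste0(target, "_", port)),
            class = "spml_logger")
}

#' Define a property override
#' @param population Target population name.
#' @param property Property name on the target's component.
#' @param value An `spml_property_value` replacing the model's value.
#' @export
property_change <- function(population, property, value) {
  stopifnot(inherits(value, "spml_property_value"))
  structure(list(population = as.character(population),
                 property = as.character(property), value = value),
            class = "spml_property_change")
}

#' Define an experiment
#'
#' @param name Identifier.
#' @param network_ref Name of the network the experiment applies to.
#' @param duration Simulated time in seconds (> 0).
#' @param dt Integration step in milliseconds (> 0).
#' @param inputs,loggers,property_changes Lists of the respective elements.
#' @param description Free-text description.
#' @export
experiment <- function(name, network_ref, duration, dt = 0.1,
                       inputs = list(), loggers = list(),
                       property_changes = list(), description = "") {
  if (duration <= 0) spml_error("spml_validation_error", "duration must be > 0")
  if (dt <= 0) spml_error("spml_validation_error", "dt must be > 0")
  structure(list(name = check_identifier(name), description = description,
                 network_ref = as.character(network_ref),
                 duration = as.numeric(duration), dt = as.numeric(dt),
                 inputs = unname(as.list(inputs)),
                 loggers = unname(as.list(loggers)),
                 property_changes = unname(as.list(property_changes))),
            class = "spml_experiment")
}

#' Validate an experiment against a network
#' @param exp An `spml_experiment`.
#' @param net The `spml_network` it targets.
#' @param components Named component list.
#' @return List of violation records.
#' @export
validate_experiment <- function(exp, net, components) {
  v <- list()
  add <- function(el, rule, msg) v[[length(v) + 1L]] <<- violation(el, rule, msg)
  resolve <- function(target, what) {
    pop <- find_population(net, target)
    if (is.null(pop)) {
      add(target, "missing_population",
          sprintf("%s targets missing population \"%s\"", what, target))
      return(NULL)
    }
    components[[pop$component_ref]]
  }
  for (inp in exp$inputs) {
    comp <- resolve(inp$target, "input")
    if (is.null(comp)) next
    p <- find_port(comp, inp$port)
    if (is.null(p) || p$direction != "receive")
      add(paste0(inp$target, ".", inp$port), "missing_port",
          sprintf("input targets missing receive port \"%s\" on \"%s\"",
                  inp$port, inp$target))
  }
  for (lg in exp$loggers) {
    comp <- resolve(lg$target, "logger")
    if (is.null(comp)) next
    p <- find_port(comp, lg$port)
    analog_ok <- lg$port %in% component_expr_scope(comp) ||
      (!is.null(p) && p$kind == "analog")
    if (lg$kind == "analog" && !analog_ok)
      add(paste0(lg$target, ".", lg$port), "logger_target",
          sprintf("analog logger targets no analog quantity \"%s\"", lg$port))
    if (lg$kind == "event" && (is.null(p) || p$kind != "event"))
      add(paste0(lg$target, ".", lg$port), "logger_target",
          sprintf("event logger targets no event port \"%s\"", lg$port))
  }
  for (pc in exp$property_changes) {
    comp <- resolve(pc$population, "property change")
    if (is.null(comp)) next
    if (!(pc$property %in% component_property_names(comp)))
      add(paste0(pc$population, ".", pc$property), "missing_property",
          sprintf("property change targets missing property \"%s\" on \"%s\"",
                  pc$property, pc$population))
  }
  v
}

#' Apply an experiment's property changes to a network
#'
#' Returns a resolved copy of the network with the listed properties
#' replaced; the original network value is untouched, so collaborators can
#' explore property values without changing the model.
#'
#' @param net An `spml_network`.
#' @param exp An `spml_experiment`.
#' @return The resolved `spml_network`.
#' @export
apply_property_changes <- function(net, exp) {
  for (pc in exp$property_changes) {
    idx <- which(vapply(net$populations, `[[`, "", "name") == pc$population)
    if (length(idx) != 1L)
      spml_error("spml_contract_error",
                 sprintf("property change targets missing population \"%s\"",
                         pc$population))
    net$populations[[idx]]$properties[[pc$property]] <- pc$value
  }
  net
}

# Experiment XML:
#   <Experiment name= description=>
#     <Model network_layer_url=/>
#     <Simulation duration= dt=/>
#     <ConstantInput target= port= value= indices=/>
#     <TimeVaryingInput target= port=><TimePointValue time= value=/>..
#     <RegularSpikeInput target= port= rate= start= stop=/>
#     <LogOutput target= port= kind= name= indices=/>
#     <PropertyChange population= property=><FixedValue../></PropertyChange>

indices_attr <- function(node, obj) {
  if (!is.null(obj$indices))
    xml2::xml_set_attr(node, "indices", paste(obj$indices, collapse = ","))
}

read_indices <- function(node) {
  v <- chr_attr(node, "indices")
  if (is.null(v)) NULL else as.integer(strsplit(v, ",")[[1L]])
}

#' Serialize an experiment to XML text
#' @param exp An `spml_experiment`.
#' @export
write_experiment_xml <- function(exp) {
  doc <- xml2::xml_new_root("Experiment", name = exp$name,
                            description = exp$description)
  xml2::xml_add_child(doc, "Model",
                      network_layer_url = paste0(exp$network_ref, ".xml"))
  xml2::xml_add_child(doc, "Simulation", duration = xnum(exp$duration),
                      dt = xnum(exp$dt))
  for (inp in exp$inputs) {
    n <- switch(inp$variant,
      constant = xml2::xml_add_child(doc, "ConstantInput", target = inp$target,
                                     port = inp$port, value = xnum(inp$value)),
      time_varying = {
        n <- xml2::xml_add_child(doc, "TimeVaryingInput", target = inp$target,
                                 port = inp$port)
        for (i in seq_along(inp$times))
          xml2::xml_add_child(n, "TimePointValue", time = xnum(inp$times[[i]]),
                              value = xnum(inp$values[[i]]))
        n
      },
      regular_spikes = xml2::xml_add_child(doc, "RegularSpikeInput",
                                           target = inp$target,
                                           port = inp$port,
                                           rate = xnum(inp$rate),
                                           start = xnum(inp$start),
                                           stop = xnum(inp$stop)))
    indices_attr(n, inp)
  }
  for (lg in exp$loggers) {
    n <- xml2::xml_add_child(doc, "LogOutput", target = lg$target,
                             port = lg$port, kind = lg$kind, name = lg$name)
    indices_attr(n, lg)
  }
  for (pc in exp$property_changes) {
    n <- xml2::xml_add_child(doc, "PropertyChange", population = pc$population,
                             property = pc$property)
    pv <- write_property_value_xml(n, pc$property, pc$value)
    # reuse Property writer but inline: drop the wrapping Property node name
    xml2::xml_set_name(pv, "Value")
  }
  as.character(doc)
}

#' Parse an experiment from XML text
#' @param text XML text or file path.
#' @export
read_experiment_xml <- function(text) {
  doc <- xml2::xml_root(xml2::read_xml(text))
  if (xml2::xml_name(doc) != "Experiment")
    spml_error("spml_parse_error",
               sprintf("expected <Experiment>, found <%s>",
                       xml2::xml_name(doc)))
  network_ref <- NULL; duration <- NULL; dt <- NULL
  inputs <- list(); loggers <- list(); pcs <- list()
  for (node in xml2::xml_children(doc)) {
    tag <- xml2::xml_name(node)
    if (tag == "Model") {
      network_ref <- strip_url(chr_attr(node, "network_layer_url"))
    } else if (tag == "Simulation") {
      duration <- num_attr(node, "duration"); dt <- num_attr(node, "dt")
    } else if (tag == "ConstantInput") {
      inputs[[length(inputs) + 1L]] <-
        constant_input(chr_attr(node, "target"), chr_attr(node, "port"),
                       num_attr(node, "value"), indices = read_indices(node))
    } else if (tag == "TimeVaryingInput") {
      tps <- xml2::xml_find_all(node, "TimePointValue")
      inputs[[length(inputs) + 1L]] <-
        time_varying_input(chr_attr(node, "target"), chr_attr(node, "port"),
                           data.frame(
                             t = vapply(tps, function(n) num_attr(n, "time"), 0),
                             v = vapply(tps, function(n) num_attr(n, "value"), 0)),
                           indices = read_indices(node))
    } else if (tag == "RegularSpikeInput") {
      inputs[[length(inputs) + 1L]] <-
        regular_spike_input(chr_attr(node, "target"), chr_attr(node, "port"),
                            num_attr(node, "rate"), num_attr(node, "start"),
                            num_attr(node, "stop"),
                            indices = read_indices(node))
    } else if (tag == "LogOutput") {
      loggers[[length(loggers) + 1L]] <-
        logger(chr_attr(node, "target"), chr_attr(node, "port"),
               chr_attr(node, "kind"), indices = read_indices(node),
               name = chr_attr(node, "name"))
    } else if (tag == "PropertyChange") {
      vn <- xml2::xml_child(node)
      xml2::xml_set_name(vn, "Property")
      pcs[[length(pcs) + 1L]] <-
        property_change(chr_attr(node, "population"),
                        chr_attr(node, "property"),
                        read_property_value_xml(vn))
    } else {
      spml_error("spml_parse_error",
                 sprintf("unknown tag <%s> inside <Experiment>", tag))
    }
  }
  experiment(chr_attr(doc, "name"), network_ref, duration, dt,
             inputs = inputs, loggers = loggers, property_changes = pcs,
             description = chr_attr(doc, "description", ""))
}

#' Write the XML descriptor accompanying a log file
#'
#' States the source, type and quantity of data logged: the data file, the
#' logger kind, the number of records (rows for analog, events for event
#' logs), the time step, and the recorded index subset.
#'
#' @param lg A [logger()].
#' @param record_count Number of records written.
#' @param dt Time step in ms.
#' @param data_file Name of the data file the descriptor describes.
#' @param path Optional output path; when given the XML is written there.
#' @return XML text.
#' @export
write_log_metadata <- function(lg, record_count, dt, data_file = NULL,
                               path = NULL) {
  doc <- xml2::xml_new_root("LogReport")
  n <- xml2::xml_add_child(doc, "Log",
                           target = paste0(lg$target, ".", lg$port),
                           kind = lg$kind,
                           records = as.character(record_count),
                           dt = xnum(dt))
  if (!is.null(data_file)) xml2::xml_set_attr(n, "file", data_file)
  if (!is.null(lg$indices))
    xml2::xml_set_attr(n, "indices", paste(lg$indices, collapse = ","))
  if (lg$kind == "analog" && !is.null(lg$indices))
    xml2::xml_set_attr(n, "columns", as.character(length(lg$indices)))
  out <- as.character(doc)
  if (!is.null(path)) writeLines(out, path)
  out
}
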