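# Component layer: hybrid dynamical systems with parameters, state variables,
# aliases, typed ports and regimes.  Components describe neuron bodies,
# weight-update rules, postsynaptic dynamics or generic processes, and are the
# reusable bottom layer of the three-layer model format.

#' Allowed dimension labels
#'
#' Unit handling is label-equality only: two quantities are compatible iff
#' their labels are identical.  `dimensionless` is the default.
#' @export
spml_dimensions <- c("mV", "pA", "nA", "nS", "ms", "s", "Hz", "dimensionless")

check_dimension <- function(dimension, what = "dimension") {
  if (!is.character(dimension) || length(dimension) != 1L ||
      !(dimension %in% spml_dimensions))
    spml_error("spml_validation_error",
               sprintf("%s must be one of %s (got \"%s\")", what,
                       paste(spml_dimensions, collapse = ", "),
                       paste(dimension, collapse = ",")))
  dimension
}

is_identifier <- function(name) {
  is.character(name) && length(name) == 1L &&
    grepl("^[A-Za-z][A-Za-z0-9_]*$", name)
}

check_identifier <- function(name, what = "name") {
  if (!is_identifier(name))
    spml_error("spml_validation_error",
               sprintf("%s \"%s\" is not a valid identifier", what,
                       paste(name, collapse = ",")))
  name
}

#' Declare a component parameter
#' @param name Identifier, unique among the component's symbols.
#' @param dimension One of [spml_dimensions].
#' @export
parameter <- function(name, dimension = "dimensionless") {
  structure(list(name = check_identifier(name),
                 dimension = check_dimension(dimension)),
            class = "spml_parameter")
}

#' Declare a component state variable
#' @inheritParams parameter
#' @export
state_variable <- function(name, dimension = "dimensionless") {
  structure(list(name = check_identifier(name),
                 dimension = check_dimension(dimension)),
            class = "spml_state_variable")
}

#' Declare an alias (derived quantity)
#'
#' Aliases are named expressions over parameters, state variables, receive
#' ports and other aliases; cycles are rejected at validation and evaluation
#' order is topological.
#' @param name Identifier.
#' @param expression Math-expression text.
#' @export
alias <- function(name, expression) {
  structure(list(name = check_identifier(name),
                 expression = as.character(expression)),
            class = "spml_alias")
}

#' Declare a typed port
#'
#' Ports are the communication endpoints of a component: analog ports carry a
#' continuous value, event ports a timestamped spike, impulse ports a spike
#' with a value attached.  Event ports are dimensionless by definition;
#' `reduce_rule = "sum"` is only meaningful for analog receive ports, where it
#' sums over all wired senders.
#'
#' @param name Identifier.  For analog and impulse send ports the name must
#'   match the component symbol whose value the port exposes.
#' @param direction `"send"` or `"receive"`.
#' @param kind `"analog"`, `"event"` or `"impulse"`.
#' @param dimension One of [spml_dimensions].
#' @param reduce_rule `"none"` or `"sum"`.
#' @export
port <- function(name, direction, kind, dimension = "dimensionless",
                 reduce_rule = "none") {
  direction <- match.arg(direction, c("send", "receive"))
  kind <- match.arg(kind, c("analog", "event", "impulse"))
  reduce_rule <- match.arg(reduce_rule, c("none", "sum"))
  structure(list(name = check_identifier(name), direction = direction,
                 kind = kind, dimension = check_dimension(dimension),
                 reduce_rule = reduce_rule),
            class = "spml_port")
}

#' Declare a regime transition
#'
#' @param trigger For condition transitions, boolean-expression text; for
#'   event/impulse transitions, the name of the triggering receive port.
#' @param assignments Named list: state variable -> expression text.
#' @param emits Character vector of send-port names fired on transition.
#' @param target_regime Regime entered after the transition.
#' @export
transition <- function(trigger, assignments = list(), emits = character(),
                       target_regime) {
  structure(list(trigger = as.character(trigger),
                 assignments = as.list(assignments),
                 emits = as.character(emits),
                 target_regime = check_identifier(target_regime, "target_regime")),
            class = "spml_transition")
}

#' Declare a regime
#'
#' A regime is one mode of the hybrid system, with its own time derivatives
#' (in units of the state variable per second) and outgoing transitions.
#'
#' @param name Identifier.
#' @param time_derivatives Named list: state variable -> expression text.
#' @param on_conditions,on_events,on_impulses Lists of [transition()]s.
#' @export
regime <- function(name, time_derivatives = list(), on_conditions = list(),
                   on_events = list(), on_impulses = list()) {
  structure(list(name = check_identifier(name),
                 time_derivatives = as.list(time_derivatives),
                 on_conditions = unname(as.list(on_conditions)),
                 on_events = unname(as.list(on_events)),
                 on_impulses = unname(as.list(on_impulses))),
            class = "spml_regime")
}

#' Build a component
#'
#' @param name Identifier.
#' @param kind One of `"neuron_body"`, `"weight_update"`, `"postsynapse"`,
#'   `"generic"`.
#' @param parameters,state_variables,aliases,ports,regimes Lists of the
#'   respective elements.
#' @param initial_regime Name of the starting regime (defaults to the first).
#' @return An object of class `spml_component`.
#' @export
component <- function(name, kind = "generic", parameters = list(),
                      state_variables = list(), aliases = list(),
                      ports = list(), regimes = list(),
                      initial_regime = NULL) {
  kind <- match.arg(kind, c("neuron_body", "weight_update", "postsynapse",
                            "generic"))
  if (length(regimes) == 0L)
    spml_error("spml_validation_error",
               sprintf("component \"%s\" must have at least one regime", name))
  if (is.null(initial_regime)) initial_regime <- regimes[[1L]]$name
  structure(list(name = check_identifier(name), kind = kind,
                 parameters = unname(as.list(parameters)),
                 state_variables = unname(as.list(state_variables)),
                 aliases = unname(as.list(aliases)),
                 ports = unname(as.list(ports)),
                 regimes = unname(as.list(regimes)),
                 initial_regime = as.character(initial_regime)),
            class = "spml_component")
}

#' @export
print.spml_component <- function(x, ...) {
  cat(sprintf("<component \"%s\" (%s)>\n", x$name, x$kind))
  cat(sprintf("  %d parameter(s), %d state variable(s), %d alias(es)\n",
              length(x$parameters), length(x$state_variables),
              length(x$aliases)))
  for (p in x$ports)
    cat(sprintf("  port %s: %s %s [%s]%s\n", p$name, p$kind, p$direction,
                p$dimension,
                if (p$reduce_rule == "sum") " reduce=sum" else ""))
  cat(sprintf("  regimes: %s (initial: %s)\n",
              paste(vapply(x$regimes, `[[`, "", "name"), collapse = ", "),
              x$initial_regime))
  invisible(x)
}

# Unique-name pool: owned symbols, receive ports and event send ports.
# Analog/impulse send ports are excluded — they NAME an owned symbol (the
# value they expose) rather than declare a new one.
component_symbol_names <- function(c) {
  named_ports <- Filter(function(p)
    p$direction == "receive" || p$kind == "event", c$ports)
  c(vapply(c$parameters, `[[`, "", "name"),
    vapply(c$state_variables, `[[`, "", "name"),
    vapply(c$aliases, `[[`, "", "name"),
    vapply(named_ports, `[[`, "", "name"))
}

component_owned_symbols <- function(c) {
  c(vapply(c$parameters, `[[`, "", "name"),
    vapply(c$state_variables, `[[`, "", "name"),
    vapply(c$aliases, `[[`, "", "name"))
}

component_property_names <- function(c) {
  c(vapply(c$parameters, `[[`, "", "name"),
    vapply(c$state_variables, `[[`, "", "name"))
}

# Symbols an expression inside the component may reference: parameters, state
# variables, aliases and (analog/impulse) receive-port names.
component_expr_scope <- function(c) {
  recv <- vapply(Filter(function(p) p$direction == "receive", c$ports),
                 `[[`, "", "name")
  c(vapply(c$parameters, `[[`, "", "name"),
    vapply(c$state_variables, `[[`, "", "name"),
    vapply(c$aliases, `[[`, "", "name"),
    recv)
}

violation <- function(element, rule, message) {
  list(element = element, rule = rule, message = message)
}

#' Validate a component
#'
#' Checks every structural invariant of the component layer: symbol
#' uniqueness, port typing (event ports dimensionless, reduce rules on analog
#' receive ports only), alias acyclicity, closure of every expression over the
#' declared symbols, and regime/transition reference integrity.  Violations
#' are returned, not raised, so an invalid component can still be inspected.
#'
#' @param c An `spml_component`.
#' @return A list of violation records `list(element, rule, message)`; empty
#'   iff the component is valid.  Components with zero state variables are
#'   valid (pure relays) but signalled with a warning.
#' @export
validate_component <- function(c) {
  v <- list()
  add <- function(el, rule, msg) v[[length(v) + 1L]] <<- violation(el, rule, msg)

  syms <- component_symbol_names(c)
  dup <- unique(syms[duplicated(syms)])
  for (d in dup)
    add(d, "unique_symbols", sprintf("symbol \"%s\" declared more than once", d))
  for (s in syms) if (!is_identifier(s))
    add(s, "identifier", sprintf("\"%s\" is not a valid identifier", s))

  for (p in c$ports) {
    if (p$kind == "event" && p$dimension != "dimensionless")
      add(p$name, "event_port_dimensionless",
          sprintf("event port \"%s\" must be dimensionless (has %s)",
                  p$name, p$dimension))
    if (p$reduce_rule == "sum" &&
        !(p$kind == "analog" && p$direction == "receive"))
      add(p$name, "reduce_rule",
          sprintf("port \"%s\": reduce_rule=sum is only allowed on analog receive ports",
                  p$name))
    # analog/impulse send ports expose the component symbol of the same name
    if (p$direction == "send" && p$kind %in% c("analog", "impulse")) {
      if (!(p$name %in% component_owned_symbols(c)))
        add(p$name, "send_port_symbol",
            sprintf("%s send port \"%s\" does not match any parameter, state variable or alias",
                    p$kind, p$name))
    }
  }

  # alias dependency graph: no cycles, references resolve
  scope <- component_expr_scope(c)
  alias_names <- vapply(c$aliases, `[[`, "", "name")
  deps <- lapply(c$aliases, function(a) {
    refs <- tryCatch(expression_symbols(a$expression), error = function(e) NULL)
    if (is.null(refs)) {
      add(a$name, "expression_parse",
          sprintf("alias \"%s\": cannot parse \"%s\"", a$name, a$expression))
      return(character())
    }
    bad <- setdiff(refs, scope)
    for (b in bad)
      add(a$name, "unresolved_symbol",
          sprintf("alias \"%s\" references undeclared \"%s\"", a$name, b))
    intersect(refs, alias_names)
  })
  names(deps) <- alias_names
  if (length(alias_names) > 0L && is.null(alias_topo_order(deps)))
    add(paste(alias_names, collapse = ","), "alias_cycle",
        "alias definitions form a cycle")

  regime_names <- vapply(c$regimes, `[[`, "", "name")
  sv_names <- vapply(c$state_variables, `[[`, "", "name")
  recv_ev <- vapply(Filter(function(p)
    p$direction == "receive" && p$kind == "event", c$ports), `[[`, "", "name")
  recv_imp <- vapply(Filter(function(p)
    p$direction == "receive" && p$kind == "impulse", c$ports), `[[`, "", "name")
  send_names <- vapply(Filter(function(p) p$direction == "send", c$ports),
                       `[[`, "", "name")

  if (!(c$initial_regime %in% regime_names))
    add(c$initial_regime, "initial_regime",
        sprintf("initial_regime \"%s\" does not name a regime", c$initial_regime))

  check_expr <- function(el, text, rule, extra_scope = character()) {
    refs <- tryCatch(expression_symbols(text), error = function(e) NA)
    if (length(refs) == 1L && is.na(refs[[1L]])) {
      add(el, "expression_parse", sprintf("cannot parse \"%s\"", text))
      return()
    }
    for (b in setdiff(refs, c(scope, extra_scope)))
      add(el, rule, sprintf("\"%s\" references undeclared \"%s\"", el, b))
  }

  check_transition <- function(tr, regime_name, type) {
    if (!(tr$target_regime %in% regime_names))
      add(tr$target_regime, "transition_target",
          sprintf("transition in regime \"%s\" targets missing regime \"%s\"",
                  regime_name, tr$target_regime))
    extra <- character()
    if (type == "condition") {
      check_expr(paste0(regime_name, "/trigger"), tr$trigger, "unresolved_symbol")
    } else {
      pool <- if (type == "event") recv_ev else recv_imp
      if (!(tr$trigger %in% pool))
        add(tr$trigger, "transition_trigger_port",
            sprintf("on_%s trigger \"%s\" is not a declared %s receive port",
                    type, tr$trigger, type))
      if (type == "impulse") extra <- tr$trigger # payload bound to port name
    }
    for (sv in names(tr$assignments)) {
      if (!(sv %in% sv_names))
        add(sv, "assignment_target",
            sprintf("assignment to undeclared state variable \"%s\"", sv))
      check_expr(paste0(regime_name, "/", sv), tr$assignments[[sv]],
                 "unresolved_symbol", extra)
    }
    for (em in tr$emits) if (!(em %in% send_names))
      add(em, "emit_port",
          sprintf("transition emits undeclared send port \"%s\"", em))
  }

  for (r in c$regimes) {
    td_vars <- names(r$time_derivatives)
    for (d in unique(td_vars[duplicated(td_vars)]))
      add(d, "duplicate_derivative",
          sprintf("regime \"%s\": state variable \"%s\" has two derivatives",
                  r$name, d))
    for (sv in td_vars) {
      if (!(sv %in% sv_names))
        add(sv, "derivative_target",
            sprintf("regime \"%s\": derivative for undeclared \"%s\"", r$name, sv))
      check_expr(paste0(r$name, "/d", sv), r$time_derivatives[[sv]],
                 "unresolved_symbol")
    }
    for (tr in r$on_conditions) check_transition(tr, r$name, "condition")
    for (tr in r$on_events) check_transition(tr, r$name, "event")
    for (tr in r$on_impulses) check_transition(tr, r$name, "impulse")
  }

  if (length(c$state_variables) == 0L)
    warning(sprintf("component \"%s\" has no state variables (pure relay)",
                    c$name), call. = FALSE)
  v
}

# Topological order of aliases, or NULL if cyclic.
alias_topo_order <- function(deps) {
  order <- character()
  remaining <- names(deps)
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(n)
      length(setdiff(deps[[n]], order)) == 0L, logical(1L))]
    if (length(ready) == 0L) return(NULL)
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' Can a send port drive a receive port?
#'
#' Compatible iff the port kinds are equal and the dimension labels are equal
#' (event ports are always dimensionless, so two event ports always match).
#'
#' @param send A send [port()].
#' @param receive A receive [port()].
#' @return Logical scalar.
#' @export
check_port_compatibility <- function(send, receive) {
  if (!inherits(send, "spml_port") || !inherits(receive, "spml_port") ||
      send$direction != "send" || receive$direction != "receive")
    spml_error("spml_contract_error",
               "check_port_compatibility() needs a send port and a receive port")
  send$kind == receive$kind && send$dimension == receive$dimension
}

#' Duplicate a component under a new name
#'
#' Deep copy with the same structure; the source is unchanged.  Commonly used
#' to derive families of related neuron types from one template.
#'
#' @param c An `spml_component`.
#' @param new_name Identifier, different from `c$name`.
#' @param existing Optional character vector of names already taken in the
#'   project; a collision is an error.
#' @export
duplicate_component <- function(c, new_name, existing = character()) {
  check_identifier(new_name, "new_name")
  if (identical(new_name, c$name))
    spml_error("spml_contract_error",
               sprintf("duplicate_component: new name \"%s\" equals the source name",
                       new_name))
  if (new_name %in% existing)
    spml_error("spml_contract_error",
               sprintf("component name \"%s\" already exists in the project",
                       new_name))
  out <- c   # R list semantics: full value copy
  out$name <- new_name
  out
}
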