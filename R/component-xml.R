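# Component XML dialect.
#
# One component per file:
#   <ComponentClass name= type= initial_regime=>
#     <Parameter name= dimension=/> <StateVariable name= dimension=/>
#     <Alias name=><MathInline>..</MathInline></Alias>
#     <AnalogSendPort|AnalogReceivePort|AnalogReducePort|EventSendPort|
#      EventReceivePort|ImpulseSendPort|ImpulseReceivePort name= dimension=/>
#     <Regime name=>
#       <TimeDerivative variable=><MathInline>..</MathInline></TimeDerivative>
#       <OnCondition target_regime=><Trigger><MathInline>..</MathInline></Trigger>
#         <StateAssignment variable=><MathInline>..</MathInline></StateAssignment>
#         <EventOut port=/> <ImpulseOut port=/>
#       </OnCondition>
#       <OnEvent src_port= target_regime=>..  <OnImpulse src_port= target_regime=>..
#     </Regime>
#   </ComponentClass>

port_tag_table <- data.frame(
  tag = c("AnalogSendPort", "AnalogReceivePort", "AnalogReducePort",
          "EventSendPort", "EventReceivePort",
          "ImpulseSendPort", "ImpulseReceivePort"),
  direction = c("send", "receive", "receive", "send", "receive", "send",
                "receive"),
  kind = c("analog", "analog", "analog", "event", "event", "impulse",
           "impulse"),
  reduce = c("none", "none", "sum", "none", "none", "none", "none"),
  stringsAsFactors = FALSE)

port_to_tag <- function(p) {
  hit <- port_tag_table$direction == p$direction &
    port_tag_table$kind == p$kind & port_tag_table$reduce == p$reduce_rule
  port_tag_table$tag[hit][[1L]]
}

math_child <- function(parent, tag, text, ...) {
  n <- xml2::xml_add_child(parent, tag, ...)
  xml2::xml_add_child(n, "MathInline", text)
  n
}

read_math <- function(node, tag = "MathInline") {
  m <- xml2::xml_find_first(node, tag)
  if (inherits(m, "xml_missing"))
    spml_error("spml_parse_error",
               sprintf("missing <%s> under <%s>", tag, xml2::xml_name(node)))
  trimws(xml2::xml_text(m))
}

#' Serialize a component to XML text
#' @param c An `spml_component`.
#' @return XML text (UTF-8).
#' @export
write_component_xml <- function(c) {
  doc <- xml2::xml_new_root("ComponentClass", name = c$name, type = c$kind,
                            initial_regime = c$initial_regime)
  for (p in c$parameters)
    xml2::xml_add_child(doc, "Parameter", name = p$name,
                        dimension = p$dimension)
  for (s in c$state_variables)
    xml2::xml_add_child(doc, "StateVariable", name = s$name,
                        dimension = s$dimension)
  for (a in c$aliases) math_child(doc, "Alias", a$expression, name = a$name)
  for (p in c$ports)
    xml2::xml_add_child(doc, port_to_tag(p), name = p$name,
                        dimension = p$dimension)
  for (r in c$regimes) {
    rn <- xml2::xml_add_child(doc, "Regime", name = r$name)
    for (sv in names(r$time_derivatives))
      math_child(rn, "TimeDerivative", r$time_derivatives[[sv]], variable = sv)
    write_transition <- function(tr, tag) {
      tn <- xml2::xml_add_child(rn, tag, target_regime = tr$target_regime)
      if (tag == "OnCondition") {
        trig <- xml2::xml_add_child(tn, "Trigger")
        xml2::xml_add_child(trig, "MathInline", tr$trigger)
      } else xml2::xml_set_attr(tn, "src_port", tr$trigger)
      for (sv in names(tr$assignments))
        math_child(tn, "StateAssignment", tr$assignments[[sv]], variable = sv)
      for (em in tr$emits) {
        p <- Find(function(pp) pp$name == em && pp$direction == "send", c$ports)
        tag_out <- if (!is.null(p) && p$kind == "impulse") "ImpulseOut"
        else "EventOut"
        xml2::xml_add_child(tn, tag_out, port = em)
      }
    }
    for (tr in r$on_conditions) write_transition(tr, "OnCondition")
    for (tr in r$on_events) write_transition(tr, "OnEvent")
    for (tr in r$on_impulses) write_transition(tr, "OnImpulse")
  }
  as.character(doc)
}

read_transition_node <- function(node) {
  tag <- xml2::xml_name(node)
  trigger <- if (tag == "OnCondition") {
    read_math(xml2::xml_find_first(node, "Trigger"))
  } else chr_attr(node, "src_port")
  assignments <- list()
  for (sa in xml2::xml_find_all(node, "StateAssignment"))
    assignments[[chr_attr(sa, "variable")]] <- read_math(sa)
  emits <- vapply(xml2::xml_find_all(node, "EventOut | ImpulseOut"),
                  function(n) chr_attr(n, "port"), "")
  transition(trigger = trigger, assignments = assignments,
             emits = as.character(emits),
             target_regime = chr_attr(node, "target_regime"))
}

#' Parse a component from XML text
#'
#' Unknown tags raise a `spml_parse_error` naming the tag; structural
#' invariant violations found on load are raised as a
#' `spml_validation_error` carrying the violation list.
#'
#' @param text XML text or a file path.
#' @param validate Run [validate_component()] on the result (default TRUE).
#' @return An `spml_component`.
#' @export
read_component_xml <- function(text, validate = TRUE) {
  doc <- xml2::xml_root(xml2::read_xml(text))
  if (xml2::xml_name(doc) != "ComponentClass")
    spml_error("spml_parse_error",
               sprintf("expected <ComponentClass>, found <%s>",
                       xml2::xml_name(doc)))
  parameters <- list(); svs <- list(); aliases <- list(); ports <- list()
  regimes <- list()
  for (node in xml2::xml_children(doc)) {
    tag <- xml2::xml_name(node)
    if (tag == "Parameter") {
      parameters[[length(parameters) + 1L]] <-
        parameter(chr_attr(node, "name"),
                  chr_attr(node, "dimension", "dimensionless"))
    } else if (tag == "StateVariable") {
      svs[[length(svs) + 1L]] <-
        state_variable(chr_attr(node, "name"),
                       chr_attr(node, "dimension", "dimensionless"))
    } else if (tag == "Alias") {
      aliases[[length(aliases) + 1L]] <-
        alias(chr_attr(node, "name"), read_math(node))
    } else if (tag %in% port_tag_table$tag) {
      row <- port_tag_table[port_tag_table$tag == tag, ]
      dim <- chr_attr(node, "dimension", "dimensionless")
      if (row$kind == "event" && dim != "dimensionless")
        spml_error("spml_validation_error",
                   sprintf("event port \"%s\" must be dimensionless (has \"%s\")",
                           chr_attr(node, "name"), dim),
                   violations = list(violation(chr_attr(node, "name"),
                                               "event_port_dimensionless",
                                               "event ports carry no dimension")))
      ports[[length(ports) + 1L]] <-
        port(chr_attr(node, "name"), row$direction, row$kind, dim, row$reduce)
    } else if (tag == "Regime") {
      td <- list(); oc <- list(); oe <- list(); oi <- list()
      for (child in xml2::xml_children(node)) {
        ctag <- xml2::xml_name(child)
        if (ctag == "TimeDerivative") {
          td[[chr_attr(child, "variable")]] <- read_math(child)
        } else if (ctag == "OnCondition") {
          oc[[length(oc) + 1L]] <- read_transition_node(child)
        } else if (ctag == "OnEvent") {
          oe[[length(oe) + 1L]] <- read_transition_node(child)
        } else if (ctag == "OnImpulse") {
          oi[[length(oi) + 1L]] <- read_transition_node(child)
        } else {
          spml_error("spml_parse_error",
                     sprintf("unknown tag <%s> inside <Regime>", ctag))
        }
      }
      regimes[[length(regimes) + 1L]] <-
        regime(chr_attr(node, "name"), time_derivatives = td,
               on_conditions = oc, on_events = oe, on_impulses = oi)
    } else if (tag == "Annotations") {
      # tool-specific annotations are ignored on components
    } else {
      spml_error("spml_parse_error",
                 sprintf("unknown tag <%s> inside <ComponentClass>", tag))
    }
  }
  comp <- component(chr_attr(doc, "name"),
                    kind = chr_attr(doc, "type", "generic"),
                    parameters = parameters, state_variables = svs,
                    aliases = aliases, ports = ports, regimes = regimes,
                    initial_regime = chr_attr(doc, "initial_regime"))
  if (validate) {
    viol <- suppressWarnings(validate_component(comp))
    if (length(viol) > 0L)
      spml_error("spml_validation_error",
                 sprintf("component \"%s\" is invalid: %s", comp$name,
                         paste(vapply(viol, `[[`, "", "message"),
                               collapse = "; ")),
                 violations = viol)
  }
  comp
}
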