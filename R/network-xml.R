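# Network and project file serialization.
#
# Network file:
#   <SpineMLNetwork name=>
#     <Population>
#       <Neuron name= size= url=COMPONENT.xml>
#         <Property name=><FixedValue|ValueList|UniformDistribution|
#                          NormalDistribution/></Property>
#       </Neuron>
#       <Projection dst_population=>
#         <Synapse>
#           <OneToOneConnection|AllToAllConnection|
#            FixedProbabilityConnection|ConnectionList/>
#           <WeightUpdate url=>..</WeightUpdate>
#           <PostSynapse url=>..</PostSynapse>
#         </Synapse>
#       </Projection>
#       <Annotations>..</Annotations>
#     </Population>
#     <GenericInput src_population= src_port= dst_population= dst_port=>..
#   </SpineMLNetwork>
#
# Tool-specific extras (display colour, layout reference, generation recipes)
# live inside <Annotations> under a dedicated namespace so that readers that
# ignore annotations still see a plain, valid network.

ann_ns <- "urn:layered-models:annotations"

write_property_value_xml <- function(parent, name, v) {
  pn <- xml2::xml_add_child(parent, "Property", name = name)
  switch(v$variant,
    fixed = xml2::xml_add_child(pn, "FixedValue", value = xnum(v$value)),
    value_list = {
      ln <- xml2::xml_add_child(pn, "ValueList")
      for (i in seq_along(v$indices))
        xml2::xml_add_child(ln, "Value", index = as.character(v$indices[[i]]),
                            value = xnum(v$values[[i]]))
    },
    uniform = {
      n <- xml2::xml_add_child(pn, "UniformDistribution",
                               minimum = xnum(v$min), maximum = xnum(v$max))
      if (!is.null(v$seed)) xml2::xml_set_attr(n, "seed", as.character(v$seed))
    },
    normal = {
      n <- xml2::xml_add_child(pn, "NormalDistribution", mean = xnum(v$mean),
                               variance = xnum(v$variance))
      if (!is.null(v$seed)) xml2::xml_set_attr(n, "seed", as.character(v$seed))
    })
  pn
}

read_property_value_xml <- function(pn) {
  child <- xml2::xml_child(pn)
  tag <- xml2::xml_name(child)
  switch(tag,
    FixedValue = fixed_value(num_attr(child, "value")),
    ValueList = {
      vals <- xml2::xml_find_all(child, "Value")
      value_list(vapply(vals, function(n) as.integer(num_attr(n, "index")), 0L),
                 vapply(vals, function(n) num_attr(n, "value"), 0))
    },
    UniformDistribution = uniform_value(num_attr(child, "minimum"),
                                        num_attr(child, "maximum"),
                                        seed = num_attr(child, "seed")),
    NormalDistribution = normal_value(num_attr(child, "mean"),
                                      num_attr(child, "variance"),
                                      seed = num_attr(child, "seed")),
    spml_error("spml_parse_error",
               sprintf("unknown property value tag <%s>", tag)))
}

write_properties_xml <- function(parent, properties) {
  for (nm in names(properties))
    write_property_value_xml(parent, nm, properties[[nm]])
}

read_properties_xml <- function(parent) {
  props <- list()
  for (pn in xml2::xml_find_all(parent, "Property"))
    props[[chr_attr(pn, "name")]] <- read_property_value_xml(pn)
  props
}

write_connectivity_xml <- function(parent, conn) {
  switch(conn$variant,
    one_to_one = xml2::xml_add_child(parent, "OneToOneConnection"),
    all_to_all = xml2::xml_add_child(parent, "AllToAllConnection"),
    fixed_probability = {
      n <- xml2::xml_add_child(parent, "FixedProbabilityConnection",
                               probability = xnum(conn$p),
                               allow_self = if (conn$allow_self) "true" else "false")
      if (!is.null(conn$seed)) xml2::xml_set_attr(n, "seed",
                                                  as.character(conn$seed))
      n
    },
    connection_list = write_connection_list_xml(parent, conn))
}

write_connection_list_xml <- function(parent, cl) {
  n <- xml2::xml_add_child(parent, "ConnectionList")
  for (i in seq_along(cl$src)) {
    cn <- xml2::xml_add_child(n, "Connection",
                              src_neuron = as.character(cl$src[[i]]),
                              dst_neuron = as.character(cl$dst[[i]]),
                              delay = xnum(cl$delay[[i]]))
    if (!is.null(cl$weights))
      xml2::xml_set_attr(cn, "weight", xnum(cl$weights[[i]]))
  }
  if (!is.null(cl$recipe)) {
    an <- xml2::xml_add_child(n, "Annotations")
    write_recipe_xml(an, cl$recipe)
  }
  n
}

read_connection_list_xml <- function(node) {
  conns <- xml2::xml_find_all(node, "Connection")
  src <- vapply(conns, function(n) as.integer(num_attr(n, "src_neuron")), 0L)
  dst <- vapply(conns, function(n) as.integer(num_attr(n, "dst_neuron")), 0L)
  delay <- vapply(conns, function(n) num_attr(n, "delay", 0), 0)
  w <- vapply(conns, function(n) num_attr(n, "weight", NA_real_), 0)
  weights <- if (length(w) > 0L && all(!is.na(w))) w else NULL
  recipe <- NULL
  an <- xml2::xml_find_first(node, "Annotations")
  if (!inherits(an, "xml_missing")) recipe <- read_recipe_xml(an)
  connection_list(src = src, dst = dst,
                  delay = if (length(src) > 0L) delay else 0,
                  weights = weights, recipe = recipe)
}

read_connectivity_xml <- function(node) {
  tag <- xml2::xml_name(node)
  switch(tag,
    OneToOneConnection = one_to_one(),
    AllToAllConnection = all_to_all(),
    FixedProbabilityConnection =
      fixed_probability(num_attr(node, "probability"),
                        seed = num_attr(node, "seed"),
                        allow_self = !identical(chr_attr(node, "allow_self"),
                                                "false")),
    ConnectionList = read_connection_list_xml(node),
    spml_error("spml_parse_error",
               sprintf("unknown connectivity tag <%s>", tag)))
}

#' Serialize a network to XML text
#' @param net An `spml_network`.
#' @return XML text.
#' @export
write_network_xml <- function(net) {
  doc <- xml2::xml_new_root("SpineMLNetwork", name = net$name)
  xml2::xml_set_attr(doc, "xmlns:ann", ann_ns)
  for (p in net$populations) {
    pn <- xml2::xml_add_child(doc, "Population")
    nn <- xml2::xml_add_child(pn, "Neuron", name = p$name,
                              size = as.character(p$size),
                              url = paste0(p$component_ref, ".xml"))
    write_properties_xml(nn, p$properties)
    for (pr in net$projections) {
      if (pr$source != p$name) next
      prn <- xml2::xml_add_child(pn, "Projection",
                                 dst_population = pr$destination)
      for (sy in pr$synapses) {
        sn <- xml2::xml_add_child(prn, "Synapse")
        write_connectivity_xml(sn, sy$connectivity)
        wu <- xml2::xml_add_child(sn, "WeightUpdate",
                                  url = paste0(sy$weight_update$component_ref,
                                               ".xml"))
        write_properties_xml(wu, sy$weight_update$properties)
        ps <- xml2::xml_add_child(sn, "PostSynapse",
                                  url = paste0(sy$postsynapse$component_ref,
                                               ".xml"))
        write_properties_xml(ps, sy$postsynapse$properties)
      }
    }
    if (!is.null(p$colour) || !is.null(p$layout_ref)) {
      an <- xml2::xml_add_child(pn, "Annotations")
      if (!is.null(p$colour))
        xml2::xml_add_child(an, "ann:Colour", value = p$colour)
      if (!is.null(p$layout_ref))
        xml2::xml_add_child(an, "ann:LayoutRef", name = p$layout_ref)
    }
  }
  for (gi in net$generic_inputs) {
    gn <- xml2::xml_add_child(doc, "GenericInput",
                              src_population = gi$src_population,
                              src_port = gi$src_port,
                              dst_population = gi$dst_population,
                              dst_port = gi$dst_port)
    write_connectivity_xml(gn, gi$connectivity)
  }
  as.character(doc)
}

strip_url <- function(url) sub("\\.xml$", "", url)

#' Parse a network from XML text
#' @param text XML text or file path.
#' @return An `spml_network`.
#' @export
read_network_xml <- function(text) {
  doc <- xml2::xml_root(xml2::read_xml(text))
  if (xml2::xml_name(doc) != "SpineMLNetwork")
    spml_error("spml_parse_error",
               sprintf("expected <SpineMLNetwork>, found <%s>",
                       xml2::xml_name(doc)))
  pops <- list(); projs <- list(); gis <- list()
  for (pn in xml2::xml_children(doc)) {
    tag <- xml2::xml_name(pn)
    if (tag == "Population") {
      nn <- xml2::xml_find_first(pn, "Neuron")
      colour <- NULL; layout_ref <- NULL
      an <- xml2::xml_find_first(pn, "Annotations")
      if (!inherits(an, "xml_missing")) {
        cn <- xml2::xml_find_first(an, ".//*[local-name()='Colour']")
        if (!inherits(cn, "xml_missing")) colour <- chr_attr(cn, "value")
        ln <- xml2::xml_find_first(an, ".//*[local-name()='LayoutRef']")
        if (!inherits(ln, "xml_missing")) layout_ref <- chr_attr(ln, "name")
      }
      pop <- population(chr_attr(nn, "name"),
                        as.integer(num_attr(nn, "size")),
                        strip_url(chr_attr(nn, "url")),
                        properties = read_properties_xml(nn),
                        layout_ref = layout_ref, colour = colour)
      pops[[length(pops) + 1L]] <- pop
      for (prn in xml2::xml_find_all(pn, "Projection")) {
        syns <- lapply(xml2::xml_find_all(prn, "Synapse"), function(sn) {
          wu <- xml2::xml_find_first(sn, "WeightUpdate")
          ps <- xml2::xml_find_first(sn, "PostSynapse")
          conn_node <- Find(function(x)
            xml2::xml_name(x) %in% c("OneToOneConnection", "AllToAllConnection",
                                     "FixedProbabilityConnection",
                                     "ConnectionList"),
            xml2::xml_children(sn))
          synapse(read_connectivity_xml(conn_node),
                  component_binding(strip_url(chr_attr(wu, "url")),
                                    read_properties_xml(wu)),
                  component_binding(strip_url(chr_attr(ps, "url")),
                                    read_properties_xml(ps)))
        })
        projs[[length(projs) + 1L]] <-
          projection(pop$name, chr_attr(prn, "dst_population"), syns)
      }
    } else if (tag == "GenericInput") {
      conn_node <- xml2::xml_child(pn)
      gis[[length(gis) + 1L]] <-
        generic_input(chr_attr(pn, "src_population"), chr_attr(pn, "src_port"),
                      chr_attr(pn, "dst_population"), chr_attr(pn, "dst_port"),
                      read_connectivity_xml(conn_node))
    } else {
      spml_error("spml_parse_error",
                 sprintf("unknown tag <%s> inside <SpineMLNetwork>", tag))
    }
  }
  network(chr_attr(doc, "name"), populations = pops, projections = projs,
          generic_inputs = gis)
}

#' In-memory project
#'
#' A project groups one network, its components, experiments and layout
#' definitions, mirroring one working directory of model files.
#'
#' @param name Project name.
#' @param network An `spml_network`.
#' @param components Named list of `spml_component`s.
#' @param experiments List of `spml_experiment`s.
#' @param layouts Named list of [layout_rule()]s.
#' @export
project <- function(name, network, components = list(), experiments = list(),
                    layouts = list()) {
  if (is.null(names(components)) && length(components) > 0L)
    names(components) <- vapply(components, `[[`, "", "name")
  if (is.null(names(layouts)) && length(layouts) > 0L)
    names(layouts) <- vapply(layouts, `[[`, "", "name")
  structure(list(name = name, network = network, components = components,
                 experiments = as.list(experiments), layouts = layouts),
            class = "spml_project")
}

#' @export
print.spml_project <- function(x, ...) {
  cat(sprintf("<project \"%s\": %d component(s), %d experiment(s), %d layout(s)>\n",
              x$name, length(x$components), length(x$experiments),
              length(x$layouts)))
  print(x$network)
  invisible(x)
}

#' Write a project to a directory
#'
#' Emits one XML file per component and experiment, one network file, and a
#' project description file listing them all (plus the layout definitions).
#'
#' @param proj An `spml_project`.
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_project <- function(proj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  doc <- xml2::xml_new_root("Project", name = proj$name)
  net_file <- paste0(proj$network$name, ".xml")
  writeLines(write_network_xml(proj$network), file.path(dir, net_file))
  xml2::xml_add_child(doc, "File", type = "network", path = net_file)
  for (comp in proj$components) {
    f <- paste0(comp$name, ".xml")
    writeLines(write_component_xml(comp), file.path(dir, f))
    xml2::xml_add_child(doc, "File", type = "component", path = f)
  }
  for (exp in proj$experiments) {
    f <- paste0("experiment_", exp$name, ".xml")
    writeLines(write_experiment_xml(exp), file.path(dir, f))
    xml2::xml_add_child(doc, "File", type = "experiment", path = f)
  }
  for (rule in proj$layouts) write_layout_xml(doc, rule)
  xml2::write_xml(doc, file.path(dir, "project.xml"))
  invisible(dir)
}

#' Read a project from a directory
#'
#' @param dir Directory containing `project.xml` (or a path to the project
#'   file itself).  Every file listed must exist.
#' @return An `spml_project`.
#' @export
read_project <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "project.xml") else dir
  base <- dirname(path)
  doc <- xml2::xml_root(xml2::read_xml(path))
  if (xml2::xml_name(doc) != "Project")
    spml_error("spml_parse_error",
               sprintf("expected <Project>, found <%s>", xml2::xml_name(doc)))
  net <- NULL; comps <- list(); exps <- list(); layouts <- list()
  for (node in xml2::xml_children(doc)) {
    tag <- xml2::xml_name(node)
    if (tag == "File") {
      f <- file.path(base, chr_attr(node, "path"))
      if (!file.exists(f))
        spml_error("spml_validation_error",
                   sprintf("project lists missing file \"%s\"",
                           chr_attr(node, "path")))
      type <- chr_attr(node, "type")
      if (type == "network") net <- read_network_xml(f)
      else if (type == "component") {
        comp <- suppressWarnings(read_component_xml(f))
        comps[[comp$name]] <- comp
      } else if (type == "experiment")
        exps[[length(exps) + 1L]] <- read_experiment_xml(f)
      else spml_error("spml_parse_error",
                      sprintf("unknown project file type \"%s\"", type))
    } else if (tag == "Layout") {
      rule <- read_layout_xml(node)
      layouts[[rule$name]] <- rule
    } else {
      spml_error("spml_parse_error",
                 sprintf("unknown tag <%s> inside <Project>", tag))
    }
  }
  if (is.null(net))
    spml_error("spml_validation_error", "project lists no network file")
  project(chr_attr(doc, "name"), net, components = comps, experiments = exps,
          layouts = layouts)
}

#' Validate a whole project
#' @param proj An `spml_project`.
#' @return List of violation records (network-level plus per-component).
#' @export
validate_project <- function(proj) {
  v <- validate_network(proj$network, proj$components)
  for (comp in proj$components)
    v <- c(v, suppressWarnings(validate_component(comp)))
  for (exp in proj$experiments)
    v <- c(v, validate_experiment(exp, proj$network, proj$components))
  v
}
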