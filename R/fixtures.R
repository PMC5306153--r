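# Model fixtures: the channel-based basal-ganglia action-selection network of
# rate-coded leaky integrators, its conversion to a spiking version, and a
# striatal-like random-cube microcircuit.

#' Default weight/gain/threshold table for the selection network
#'
#' Defaults follow the standard published parameterisation of the
#' channel-based selection model family (Gurney, Prescott & Redgrave 2001):
#' unit-magnitude focused weights, 0.9 diffuse subthalamic weights, slope-1
#' outputs with striatal threshold 0.2, subthalamic offset -0.25, pallidal
#' offsets -0.2, and tonic dopamine 0.2.  They are shipped as a starting
#' point, not a certified reproduction: users reproducing published results
#' should supply the table from the published model files.
#'
#' @return Named list: projection weights (`w_*`), per-population slope `m`,
#'   output thresholds (`eps_*`), time constant `tau` (ms) and dopamine
#'   level `da`.
#' @export
selection_weight_defaults <- function() {
  list(w_cortex_sd1 = 1, w_cortex_sd2 = 1, w_cortex_stn = 1,
       w_sd1_snr = -1, w_sd2_gpe = -1, w_stn_snr = 0.9, w_stn_gpe = 0.9,
       w_gpe_stn = -1,
       m = 1, eps_sd1 = 0.2, eps_sd2 = 0.2, eps_stn = -0.25,
       eps_gpe = -0.2, eps_snr = -0.2, tau = 25, da = 0.2)
}

selection_roster <- function() {
  # source, destination, weight key, diffuse?
  list(list("Cortex", "SD1", "w_cortex_sd1", FALSE),
       list("Cortex", "SD2", "w_cortex_sd2", FALSE),
       list("Cortex", "STN", "w_cortex_stn", FALSE),
       list("SD1", "SNr", "w_sd1_snr", FALSE),
       list("SD2", "GPe", "w_sd2_gpe", FALSE),
       list("STN", "SNr", "w_stn_snr", TRUE),
       list("STN", "GPe", "w_stn_gpe", TRUE),
       list("GPe", "STN", "w_gpe_stn", FALSE))
}

#' Build the rate-coded selection network fixture
#'
#' A channel-based action-selection architecture: cortical input feeds two
#' striatal populations (D1- and D2-dopamine-modulated) and the subthalamic
#' nucleus; the D1 striatum inhibits the output nucleus (SNr), the D2
#' striatum inhibits the globus pallidus, and the subthalamic nucleus
#' diffusely excites both, closing a loop with pallidal feedback.  Selection
#' of a channel shows as disinhibition: its SNr output drops below
#' threshold.  All populations are rate-coded leaky integrators sized
#' `n_channels`; channel-wise pathways are one-to-one, diffuse subthalamic
#' pathways all-to-all with fan-in-normalised weights.
#'
#' @param n_channels Number of competing channels (default 6).
#' @param weights Weight/gain/threshold table; see
#'   [selection_weight_defaults()].  Missing entries are a config error.
#' @return An `spml_project` with one experiment ("baseline") exposing the
#'   cortical input ports and logging the SNr output.
#' @export
build_selection_network <- function(n_channels = 6L,
                                    weights = selection_weight_defaults()) {
  need <- names(selection_weight_defaults())
  missing <- setdiff(need, names(weights))
  if (length(missing) > 0L)
    spml_error("spml_config_error",
               sprintf("missing weight table entries: %s",
                       paste(missing, collapse = ", ")))
  comps <- list(analog_relay_component(),
                leaky_integrator_component("LeakyIntegrator"),
                leaky_integrator_component("LeakyIntegratorD1", "d1"),
                leaky_integrator_component("LeakyIntegratorD2", "d2"),
                linear_weight_component(),
                summing_postsynapse_component())
  names(comps) <- vapply(comps, `[[`, "", "name")

  lin_props <- function(eps, da = NULL) {
    p <- list(tau = fixed_value(weights$tau), m = fixed_value(weights$m),
              eps = fixed_value(eps), I_offset = fixed_value(0),
              a = fixed_value(0))
    if (!is.null(da)) p$da <- fixed_value(da)
    p
  }
  pops <- list(
    population("Cortex", n_channels, "AnalogRelay"),
    population("SD1", n_channels, "LeakyIntegratorD1",
               lin_props(weights$eps_sd1, weights$da)),
    population("SD2", n_channels, "LeakyIntegratorD2",
               lin_props(weights$eps_sd2, weights$da)),
    population("STN", n_channels, "LeakyIntegrator",
               lin_props(weights$eps_stn)),
    population("SNr", n_channels, "LeakyIntegrator",
               lin_props(weights$eps_snr)),
    population("GPe", n_channels, "LeakyIntegrator",
               lin_props(weights$eps_gpe)))

  projs <- lapply(selection_roster(), function(r) {
    w <- weights[[r[[3L]]]]
    conn <- if (r[[4L]]) all_to_all() else one_to_one()
    if (r[[4L]]) w <- w / n_channels  # diffuse: normalise by fan-in
    projection(r[[1L]], r[[2L]], list(
      synapse(conn,
              component_binding("LinearWeight", list(w = fixed_value(w))),
              component_binding("SummingPostsynapse"))))
  })

  net <- network("selection_network", populations = pops, projections = projs)
  exp <- experiment("baseline", "selection_network", duration = 1, dt = 1,
                    inputs = list(constant_input("Cortex", "in_a", 0)),
                    loggers = list(logger("SNr", "y", "analog"),
                                   logger("Cortex", "y", "analog")))
  project("selection", net, components = comps, experiments = list(exp))
}

#' Conversion configuration: rate model to spiking model
#'
#' Captures the recipe that turns each rate-coded unit into a group of
#' spiking neurons: `neurons_per_unit` leaky integrate-and-fire neurons per
#' unit (default 7, the lower bound for a robust group response);
#' channel-wise one-to-one pathways widen to all-to-all within the channel,
#' so every weight is divided by `weight_divisor` (default 7, the new
#' per-channel fan-in); current-valued properties (dimension pA/nA) are
#' multiplied by `current_scale` (default 10) to bridge rate-model input
#' levels and spiking currents, exempting the (population, property) paths
#' in `current_scale_exempt` (default the subthalamic intrinsic current);
#' membrane time constants are drawn per neuron from
#' `tau_m_range` = c(20, 30) ms so units do not spike in lockstep; synapses
#' become exponentially decaying currents with `synapse_tau` = 4 ms; the
#' analog cortical drive becomes a regular spike train at
#' `input_rate_scale` (default 100) Hz per unit of analog input; and the
#' dopamine influence on D2 receptors is scaled by `d2_dopamine_factor`
#' (< 1, default 0.9 — the exact reduction is not a published constant).
#'
#' @param neurons_per_unit,weight_divisor,current_scale,current_scale_exempt
#'   See description.
#' @param tau_m_range,synapse_tau,input_rate_scale,d2_dopamine_factor
#'   See description.
#' @export
snn_conversion_config <- function(neurons_per_unit = 7L,
                                  weight_divisor = neurons_per_unit,
                                  current_scale = 10,
                                  current_scale_exempt = list(c("STN", "I_offset")),
                                  tau_m_range = c(20, 30),
                                  synapse_tau = 4,
                                  input_rate_scale = 100,
                                  d2_dopamine_factor = 0.9) {
  stopifnot(neurons_per_unit >= 1L, d2_dopamine_factor > 0,
            d2_dopamine_factor <= 1)
  structure(list(neurons_per_unit = as.integer(neurons_per_unit),
                 weight_divisor = as.numeric(weight_divisor),
                 current_scale = as.numeric(current_scale),
                 current_scale_exempt = current_scale_exempt,
                 tau_m_range = as.numeric(tau_m_range),
                 synapse_tau = as.numeric(synapse_tau),
                 input_rate_scale = as.numeric(input_rate_scale),
                 d2_dopamine_factor = as.numeric(d2_dopamine_factor)),
            class = "spml_snn_config")
}

scale_current_properties <- function(pop_name, props, comp, cfg) {
  cur_dims <- c("pA", "nA")
  for (p in comp$parameters) {
    if (!(p$dimension %in% cur_dims)) next
    nm <- p$name
    if (is.null(props[[nm]])) next
    exempt <- any(vapply(cfg$current_scale_exempt, function(e)
      identical(e[[1L]], pop_name) && identical(e[[2L]], nm), logical(1L)))
    if (exempt) next
    v <- props[[nm]]
    if (v$variant == "fixed") props[[nm]] <- fixed_value(v$value * cfg$current_scale)
    else if (v$variant == "uniform")
      props[[nm]] <- uniform_value(v$min * cfg$current_scale,
                                   v$max * cfg$current_scale, v$seed)
    else if (v$variant == "normal")
      props[[nm]] <- normal_value(v$mean * cfg$current_scale,
                                  v$variance * cfg$current_scale^2, v$seed)
    else props[[nm]] <- value_list(v$indices, v$values * cfg$current_scale)
  }
  props
}

#' Convert the rate-coded selection network into a spiking version
#'
#' Applies the conversion recipe of [snn_conversion_config()] to a project
#' built by [build_selection_network()] (or one isomorphic to it).  Each
#' rate unit becomes `neurons_per_unit` LIF neurons; one-to-one channel
#' pathways become within-channel all-to-all connection lists; all weights
#' are divided by `weight_divisor`; current-valued properties are scaled by
#' `current_scale` (with exemptions); membrane time constants are sampled
#' uniformly from `tau_m_range` (seeded); synapses become exponential
#' current synapses with `synapse_tau`; constant analog cortical inputs
#' become regular spike trains at `input_rate_scale` Hz per unit of input;
#' and the D2 dopamine property is scaled by `d2_dopamine_factor`.
#'
#' @param proj Source `spml_project` (rate model).
#' @param cfg An [snn_conversion_config()].
#' @param seed Integer seed for the time-constant draws.
#' @return The converted `spml_project`.
#' @export
convert_rate_to_snn <- function(proj, cfg = snn_conversion_config(),
                                seed = 1L) {
  net <- proj$network
  comps <- proj$components
  k <- cfg$neurons_per_unit
  relay_names <- names(Filter(function(c)
    length(c$state_variables) == 0L && c$kind == "neuron_body" &&
      any(vapply(c$ports, function(p)
        p$direction == "receive" && p$kind == "analog", logical(1L))),
    comps))
  lin_names <- names(Filter(function(c)
    c$kind == "neuron_body" && !(c$name %in% relay_names), comps))
  if (length(lin_names) == 0L)
    spml_error("spml_structure_error",
               "source project has no rate-coded neuron populations to convert")
  for (p in net$populations)
    if (!(p$component_ref %in% c(relay_names, lin_names)))
      spml_error("spml_structure_error",
                 sprintf("population \"%s\" uses unexpected component \"%s\"",
                         p$name, p$component_ref))

  new_comps <- list(lif = lif_component(), relay = spike_relay_component(),
                    wu = static_impulse_weight_component(),
                    ps = exp_current_synapse_component())
  names(new_comps) <- vapply(new_comps, `[[`, "", "name")

  d2_names <- names(Filter(function(c)
    any(grepl("1 - da", vapply(c$regimes, function(r)
      paste(unlist(r$time_derivatives), collapse = " "), ""), fixed = TRUE)),
    comps))

  new_pops <- lapply(net$populations, function(p) {
    n <- p$size * k
    if (p$component_ref %in% relay_names)
      return(population(p$name, n, "SpikeRelay"))
    props <- list(
      tau_m = uniform_value(cfg$tau_m_range[[1L]], cfg$tau_m_range[[2L]],
                            seed = derive_seed(seed, paste0("tau_m/", p$name))),
      R = fixed_value(1), theta = fixed_value(1), v_reset = fixed_value(0),
      t_ref = fixed_value(2),
      I_offset = p$properties$I_offset %||% fixed_value(0),
      v = fixed_value(0), t_r = fixed_value(0))
    props <- scale_current_properties(p$name, props, new_comps$LIF, cfg)
    population(p$name, n, "LIF", props)
  })

  new_projs <- lapply(net$projections, function(pr) {
    n_units <- find_population(net, pr$source)$size
    syns <- lapply(pr$synapses, function(sy) {
      wprop <- sy$weight_update$properties$w
      if (is.null(wprop) || wprop$variant != "fixed")
        spml_error("spml_structure_error",
                   sprintf("projection %s->%s has no fixed weight to convert",
                           pr$source, pr$destination))
      w_new <- wprop$value / cfg$weight_divisor
      conn <- if (sy$connectivity$variant == "one_to_one") {
        src <- integer(); dst <- integer()
        for (ch in seq_len(n_units) - 1L) {
          idx <- ch * k + (0:(k - 1L))
          src <- c(src, rep(idx, each = k))
          dst <- c(dst, rep(idx, times = k))
        }
        connection_list(src = src, dst = dst)
      } else if (sy$connectivity$variant == "all_to_all") {
        all_to_all()
      } else sy$connectivity
      synapse(conn,
              component_binding("StaticImpulseWeight",
                                list(w = fixed_value(w_new))),
              component_binding("ExpCurrentSynapse",
                                list(tau_s = fixed_value(cfg$synapse_tau),
                                     I_post = fixed_value(0))))
    })
    projection(pr$source, pr$destination, syns)
  })

  # D2 dopamine influence slightly reduced: the LIF fixture has no explicit
  # dopamine parameter, so the reduced level is carried as an attribute that
  # the cortical-drive computation (and tests) can read
  for (i in seq_along(net$populations)) {
    old <- net$populations[[i]]
    if (old$component_ref %in% d2_names && !is.null(old$properties$da) &&
        old$properties$da$variant == "fixed")
      attr(new_pops[[i]], "d2_dopamine") <-
        old$properties$da$value * cfg$d2_dopamine_factor
  }

  new_net <- network(paste0(net$name, "_snn"), populations = new_pops,
                     projections = new_projs,
                     generic_inputs = net$generic_inputs)

  new_exps <- lapply(proj$experiments, function(e) {
    inputs <- list()
    for (inp in e$inputs) {
      tgt_pop <- find_population(net, inp$target)
      spiking_target <- !is.null(tgt_pop) &&
        tgt_pop$component_ref %in% relay_names
      if (inp$variant == "constant" && spiking_target) {
        idx <- if (is.null(inp$indices)) seq_len(tgt_pop$size) - 1L else inp$indices
        expanded <- as.integer(outer(0:(k - 1L), idx * k, `+`))
        inputs[[length(inputs) + 1L]] <-
          regular_spike_input(inp$target, "spike_in",
                              rate = inp$value * cfg$input_rate_scale,
                              start = 0, stop = e$duration,
                              indices = sort(expanded))
      } else if (spiking_target) {
        warning(sprintf("dropping non-constant analog input on \"%s\" during conversion",
                        inp$target), call. = FALSE)
      } else inputs[[length(inputs) + 1L]] <- inp
    }
    loggers <- lapply(e$loggers, function(lg)
      logger(lg$target, "spike", "event", name = lg$name))
    experiment(e$name, new_net$name, e$duration, e$dt, inputs = inputs,
               loggers = loggers, property_changes = list(),
               description = e$description)
  })
  project(paste0(proj$name, "_snn"), new_net, components = new_comps,
          experiments = new_exps)
}

#' Build the striatal-like random-cube microcircuit fixture
#'
#' A synthetic stand-in for an anatomically detailed striatal microcircuit:
#' two medium-spiny populations and a small fast-spiking interneuron
#' population placed uniformly at random in a `side`-um cube with a minimum
#' separation, connected by the `fixed_radius` builtin generator (connect
#' iff distance <= radius; delay = distance/velocity), with 2-variable
#' quadratic point neurons throughout.  Weights are inhibitory (GABAergic
#' collaterals and feed-forward interneuron inhibition).
#'
#' @param n_msn_d1,n_msn_d2,n_fsi Population sizes.
#' @param side Cube side in micrometres (default 300).
#' @param seed Master seed for layouts.
#' @param radius Connection radius in micrometres.
#' @param min_distance Minimum neuron separation in micrometres.
#' @return An `spml_project` with layouts, generated connection lists (each
#'   carrying its recipe) and a short "spontaneous" experiment.
#' @export
build_striatal_like_fixture <- function(n_msn_d1 = 84L, n_msn_d2 = 84L,
                                        n_fsi = 4L, side = 300, seed = 1L,
                                        radius = 100, min_distance = 10) {
  stopifnot(n_msn_d1 >= 1L, n_msn_d2 >= 1L, n_fsi >= 1L)
  izhi <- izhikevich_component()
  comps <- list(izhi, static_impulse_weight_component(),
                exp_current_synapse_component())
  names(comps) <- vapply(comps, `[[`, "", "name")

  sizes <- c(MSN_D1 = n_msn_d1, MSN_D2 = n_msn_d2, FSI = n_fsi)
  layouts <- list(); coords <- list()
  for (nm in names(sizes)) {
    rule <- layout_rule(paste0("box_", nm), equations = list(
      x = sprintf("rand() * %s", xnum(side)),
      y = sprintf("rand() * %s", xnum(side)),
      z = sprintf("rand() * %s", xnum(side))),
      seed = derive_seed(seed, paste0("layout/", nm)),
      min_distance = min_distance)
    layouts[[rule$name]] <- rule
    coords[[nm]] <- generate_layout(rule, sizes[[nm]])
  }

  izhi_props <- function(a, b, c, d) list(
    a_p = fixed_value(a), b_p = fixed_value(b), c_p = fixed_value(c),
    d_p = fixed_value(d), I_offset = fixed_value(0),
    v = fixed_value(-65), u = fixed_value(b * -65))
  pops <- list(
    population("MSN_D1", n_msn_d1, "Izhikevich2D",
               izhi_props(0.02, 0.2, -65, 8), layout_ref = "box_MSN_D1",
               colour = "#1f77b4"),
    population("MSN_D2", n_msn_d2, "Izhikevich2D",
               izhi_props(0.02, 0.2, -65, 8), layout_ref = "box_MSN_D2",
               colour = "#ff7f0e"),
    population("FSI", n_fsi, "Izhikevich2D",
               izhi_props(0.1, 0.2, -65, 2), layout_ref = "box_FSI",
               colour = "#d62728"))

  gen <- read_generator_script(builtin_generator_path("fixed_radius"))
  # population-major order (projections serialize nested under their source)
  roster <- list(c("MSN_D1", "MSN_D2"), c("MSN_D2", "MSN_D1"),
                 c("FSI", "MSN_D1"), c("FSI", "MSN_D2"))
  projs <- lapply(roster, function(r) {
    cl <- run_generator(gen, coords[[r[[1L]]]], coords[[r[[2L]]]],
                        values = c(radius, 1, 0))
    projection(r[[1L]], r[[2L]], list(
      synapse(cl,
              component_binding("StaticImpulseWeight",
                                list(w = fixed_value(-0.5))),
              component_binding("ExpCurrentSynapse",
                                list(tau_s = fixed_value(4),
                                     I_post = fixed_value(0))))))
  })
  net <- network("striatal_like", populations = pops, projections = projs)
  exp <- experiment("spontaneous", "striatal_like", duration = 0.2, dt = 0.1,
                    inputs = list(constant_input("MSN_D1", "I_syn", 5),
                                  constant_input("MSN_D2", "I_syn", 5),
                                  constant_input("FSI", "I_syn", 5)),
                    loggers = list(logger("MSN_D1", "spike", "event"),
                                   logger("FSI", "spike", "event")))
  project("striatal_like", net, components = comps,
          experiments = list(exp), layouts = layouts)
}
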