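# Shipped component fixtures: rate-coded leaky integrators, leaky
# integrate-and-fire neurons, static impulse weights, exponentially decaying
# current synapses, relays and a 2-variable quadratic (Izhikevich-style)
# point neuron.
#
# Conventions: time-constant parameters are in ms, so derivative expressions
# carry an explicit *1000 factor (derivatives are per second); analog and
# impulse send ports are named after the symbol they expose.

#' Rate-coded leaky integrator neuron (LIN)
#'
#' First-order low-pass dynamics `tau a' = -a + input` with piecewise-linear
#' output `y = clip(m (a - eps), 0, 1)`.  The `dopamine` argument adds the
#' channel-modulation variants used by the striatal populations of the
#' selection network: `"d1"` scales the input by `(1 + da)`, `"d2"` by
#' `(1 - da)`.
#'
#' @param name Component name.
#' @param dopamine `"none"`, `"d1"` or `"d2"`.
#' @export
leaky_integrator_component <- function(name = "LeakyIntegrator",
                                       dopamine = c("none", "d1", "d2")) {
  dopamine <- match.arg(dopamine)
  drive <- switch(dopamine,
    none = "(I_in + I_offset)",
    d1 = "((I_in + I_offset) * (1 + da))",
    d2 = "((I_in + I_offset) * (1 - da))")
  params <- list(parameter("tau", "ms"), parameter("m"), parameter("eps"),
                 parameter("I_offset", "pA"))
  if (dopamine != "none") params <- c(params, list(parameter("da")))
  component(name, kind = "neuron_body",
            parameters = params,
            state_variables = list(state_variable("a")),
            aliases = list(alias("y", "min(max(m * (a - eps), 0), 1)")),
            ports = list(port("I_in", "receive", "analog", reduce_rule = "sum"),
                         port("y", "send", "analog")),
            regimes = list(regime("integrating", time_derivatives = list(
              a = sprintf("1000 * (%s - a) / tau", drive)))))
}

#' Leaky integrate-and-fire neuron (LIF)
#'
#' `tau_m v' = -v + R (I_syn + I_offset)`; when v crosses `theta` the neuron
#' emits a spike, resets to `v_reset` and holds in a refractory regime for
#' `t_ref` ms.  The threshold/reset/refractory defaults (theta = 1,
#' v_reset = 0, t_ref = 2 ms) are this package's fixture choices, supplied
#' as ordinary properties.
#'
#' @param name Component name.
#' @export
lif_component <- function(name = "LIF") {
  component(name, kind = "neuron_body",
    parameters = list(parameter("tau_m", "ms"), parameter("R"),
                      parameter("theta", "mV"), parameter("v_reset", "mV"),
                      parameter("t_ref", "ms"), parameter("I_offset", "pA")),
    state_variables = list(state_variable("v", "mV"), state_variable("t_r", "s")),
    ports = list(port("I_syn", "receive", "analog", "pA", reduce_rule = "sum"),
                 port("spike", "send", "event")),
    regimes = list(
      regime("integrating",
             time_derivatives = list(
               v = "1000 * (R * (I_syn + I_offset) - v) / tau_m"),
             on_conditions = list(
               transition("v > theta",
                          assignments = list(v = "v_reset", t_r = "0"),
                          emits = "spike", target_regime = "refractory"))),
      regime("refractory",
             time_derivatives = list(t_r = "1"),
             on_conditions = list(
               transition("1000 * t_r >= t_ref",
                          assignments = list(t_r = "0"),
                          target_regime = "integrating")))),
    initial_regime = "integrating")
}

#' Static weight for analog (rate) projections: out = w * in
#' @param name Component name.
#' @export
linear_weight_component <- function(name = "LinearWeight") {
  suppressWarnings(component(name, kind = "weight_update",
    parameters = list(parameter("w")),
    aliases = list(alias("out", "w * in_a")),
    ports = list(port("in_a", "receive", "analog"),
                 port("out", "send", "analog")),
    regimes = list(regime("on"))))
}

#' Summing postsynapse for rate projections (pass-through of the reduced sum)
#' @param name Component name.
#' @export
summing_postsynapse_component <- function(name = "SummingPostsynapse") {
  suppressWarnings(component(name, kind = "postsynapse",
    aliases = list(alias("out", "in_a")),
    ports = list(port("in_a", "receive", "analog", reduce_rule = "sum"),
                 port("out", "send", "analog")),
    regimes = list(regime("on"))))
}

#' Static impulse weight for spiking projections
#'
#' On each presynaptic spike, emits an impulse whose payload is the weight
#' parameter `w`.
#' @param name Component name.
#' @export
static_impulse_weight_component <- function(name = "StaticImpulseWeight") {
  suppressWarnings(component(name, kind = "weight_update",
    parameters = list(parameter("w")),
    ports = list(port("spike_in", "receive", "event"),
                 port("w", "send", "impulse")),
    regimes = list(regime("on", on_events = list(
      transition("spike_in", emits = "w", target_regime = "on"))))))
}

#' Exponentially decaying current synapse
#'
#' `tau_s I' = -I`; each arriving impulse adds its payload to the current.
#' The conversion default is `tau_s = 4` ms, supplied as a property.
#' @param name Component name.
#' @export
exp_current_synapse_component <- function(name = "ExpCurrentSynapse") {
  component(name, kind = "postsynapse",
    parameters = list(parameter("tau_s", "ms")),
    state_variables = list(state_variable("I_post", "pA")),
    ports = list(port("w_in", "receive", "impulse"),
                 port("I_post", "send", "analog", "pA")),
    regimes = list(regime("decay",
      time_derivatives = list(I_post = "-1000 * I_post / tau_s"),
      on_impulses = list(transition("w_in",
                                    assignments = list(I_post = "I_post + w_in"),
                                    target_regime = "decay")))))
}

#' Analog relay (zero-state pass-through), used as the cortical input stage
#' @param name Component name.
#' @export
analog_relay_component <- function(name = "AnalogRelay") {
  suppressWarnings(component(name, kind = "neuron_body",
    aliases = list(alias("y", "in_a")),
    ports = list(port("in_a", "receive", "analog", reduce_rule = "sum"),
                 port("y", "send", "analog")),
    regimes = list(regime("on"))))
}

#' Spike relay: forwards every incoming event, used as the spiking cortical
#' input stage after conversion
#' @param name Component name.
#' @export
spike_relay_component <- function(name = "SpikeRelay") {
  suppressWarnings(component(name, kind = "neuron_body",
    ports = list(port("spike_in", "receive", "event"),
                 port("spike", "send", "event")),
    regimes = list(regime("on", on_events = list(
      transition("spike_in", emits = "spike", target_regime = "on"))))))
}

#' 2-variable quadratic point neuron (Izhikevich-style)
#'
#' `v' = 0.04 v^2 + 5 v + 140 - u + I`, `u' = a (b v - u)` (per ms, hence the
#' *1000 factors); on `v >= 30`: `v <- c_reset`, `u <- u + d`, spike.
#' @param name Component name.
#' @export
izhikevich_component <- function(name = "Izhikevich2D") {
  component(name, kind = "neuron_body",
    parameters = list(parameter("a_p"), parameter("b_p"), parameter("c_p"),
                      parameter("d_p"), parameter("I_offset", "pA")),
    state_variables = list(state_variable("v", "mV"), state_variable("u")),
    ports = list(port("I_syn", "receive", "analog", "pA", reduce_rule = "sum"),
                 port("spike", "send", "event")),
    regimes = list(regime("spiking",
      time_derivatives = list(
        v = "1000 * (0.04 * v * v + 5 * v + 140 - u + I_syn + I_offset)",
        u = "1000 * (a_p * (b_p * v - u))"),
      on_conditions = list(
        transition("v >= 30",
                   assignments = list(v = "c_p", u = "u + d_p"),
                   emits = "spike", target_regime = "spiking")))))
}
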