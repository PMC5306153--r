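# Shared in-code fixtures for the test suite.

# Minimal valid component: one regime, no ports.
minimal_component <- function(name = "Minimal") {
  component(name, "generic",
            state_variables = list(state_variable("s")),
            regimes = list(regime("only", time_derivatives = list(s = "-s"))))
}

# A single-LIF project with constant current drive and no threshold crossing
# (theta pushed out of reach), for closed-form charging-curve checks.
lif_charging_project <- function(tau_m = 25, R = 1, I = 2, theta = 1e9) {
  net <- network("one", populations = list(population("N", 1L, "LIF", list(
    tau_m = fixed_value(tau_m), R = fixed_value(R), theta = fixed_value(theta),
    v_reset = fixed_value(0), t_ref = fixed_value(2),
    I_offset = fixed_value(0), v = fixed_value(0), t_r = fixed_value(0)))))
  proj <- project("lif_charge", net, components = list(LIF = lif_component()))
  proj$drive <- I
  proj
}

run_lif_charging <- function(proj, duration = 0.1, dt = 0.01, seed = 1L) {
  exp <- experiment("charge", "one", duration = duration, dt = dt,
                    inputs = list(constant_input("N", "I_syn", proj$drive)),
                    loggers = list(logger("N", "v", "analog")))
  proj$experiments <- list(exp)
  run_experiment(proj, "charge", seed)
}

# Single exponential current synapse kicked by one presynaptic spike at
# `spike_t` seconds; returns the log set with the target's I_syn trace.
exp_synapse_kick_project <- function(tau_s = 4, w = 1) {
  comps <- list(SpikeRelay = spike_relay_component(), LIF = lif_component(),
                StaticImpulseWeight = static_impulse_weight_component(),
                ExpCurrentSynapse = exp_current_synapse_component())
  net <- network("syn", populations = list(
    population("Src", 1L, "SpikeRelay"),
    population("Tgt", 1L, "LIF", list(
      tau_m = fixed_value(25), R = fixed_value(1), theta = fixed_value(1e9),
      v_reset = fixed_value(0), t_ref = fixed_value(2),
      I_offset = fixed_value(0), v = fixed_value(0), t_r = fixed_value(0)))),
    projections = list(projection("Src", "Tgt", list(synapse(one_to_one(),
      component_binding("StaticImpulseWeight", list(w = fixed_value(w))),
      component_binding("ExpCurrentSynapse",
                        list(tau_s = fixed_value(tau_s),
                             I_post = fixed_value(0))))))))
  project("syn_kick", net, components = comps)
}

run_synapse_kick <- function(proj, spike_t = 0.01, duration = 0.03,
                             dt = 0.01, seed = 1L) {
  exp <- experiment("kick", "syn", duration = duration, dt = dt,
                    inputs = list(regular_spike_input(
                      "Src", "spike_in", rate = 100, start = spike_t,
                      stop = spike_t + 0.001)),
                    loggers = list(logger("Tgt", "I_syn", "analog")))
  proj$experiments <- list(exp)
  run_experiment(proj, "kick", seed)
}

# Fit the decay constant (ms) of a positive exponentially decaying trace.
fit_decay_tau_ms <- function(time_s, values, from_s, to_s) {
  sel <- time_s >= from_s & time_s <= to_s & values > 0
  fit <- stats::lm(log(values[sel]) ~ time_s[sel])
  -1 / stats::coef(fit)[[2L]] * 1000
}

# Sign-consistent random weight table for the selection network fixture:
# each projection weight keeps the roster's sign (striatal and pallidal
# projections inhibitory; cortical and subthalamic excitatory) and its
# magnitude is perturbed uniformly within +/-40% of the default table.
# Perturbations around the operating point — rather than unconstrained
# magnitudes — are what "a weight table satisfying the sign pattern" means
# for a selection circuit: with arbitrary magnitudes the diffuse subthalamic
# excitation can dominate the focused striatal inhibition and the
# architecture stops being a selection device at all (see the methods
# vignette for the analysis).
random_selection_weights <- function(seed) {
  w <- selection_weight_defaults()
  keys <- c("w_cortex_sd1", "w_cortex_sd2", "w_cortex_stn", "w_sd1_snr",
            "w_sd2_gpe", "w_stn_snr", "w_stn_gpe", "w_gpe_stn")
  fac <- spineml:::with_seed(seed, stats::runif(length(keys), 0.6, 1.4))
  for (i in seq_along(keys)) w[[keys[[i]]]] <- w[[keys[[i]]]] * fac[[i]]
  w
}

# Steady-state SNr output of the selection fixture under a given cortical
# input vector (one value per channel).
snr_steady_state <- function(weights, input = rep(0, 6), duration = 1.2,
                             dt = 5, seed = 1L) {
  proj <- build_selection_network(length(input), weights)
  inputs <- lapply(which(input != 0), function(ch)
    constant_input("Cortex", "in_a", input[[ch]], indices = ch - 1L))
  exp <- experiment("probe", "selection_network", duration = duration,
                    dt = dt, inputs = inputs,
                    loggers = list(logger("SNr", "y", "analog")))
  proj$experiments <- list(exp)
  logs <- run_experiment(proj, "probe", seed)
  y <- logs$analog[[1L]]$data
  y[nrow(y), ]
}
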