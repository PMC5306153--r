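test_that("fixture components validate cleanly and violations name offenders", {
  expect_length(validate_component(lif_component()), 0)
  expect_length(validate_component(izhikevich_component()), 0)
  expect_length(validate_component(minimal_component()), 0)

  bad_deriv <- component("Bad", "generic",
    state_variables = list(state_variable("s")),
    regimes = list(regime("r", time_derivatives = list(s = "-s + q"))))
  v <- validate_component(bad_deriv)
  expect_length(v, 1)
  expect_match(v[[1]]$message, "\"q\"")

  bad_init <- component("Bad2", "generic",
    state_variables = list(state_variable("s")),
    regimes = list(regime("r", time_derivatives = list(s = "-s"))),
    initial_regime = "missing")
  v <- validate_component(bad_init)
  expect_length(v, 1)
  expect_match(v[[1]]$message, "missing")

  dup <- component("Dup", "generic",
    parameters = list(parameter("s")),
    state_variables = list(state_variable("s")),
    regimes = list(regime("r")))
  expect_true(any(vapply(validate_component(dup), `[[`, "", "rule") ==
                    "unique_symbols"))

  cyc <- component("Cyc", "generic",
    state_variables = list(state_variable("s")),
    aliases = list(alias("u1", "u2 + 1"), alias("u2", "u1 + 1")),
    regimes = list(regime("r")))
  expect_true(any(vapply(validate_component(cyc), `[[`, "", "rule") ==
                    "alias_cycle"))

  # pure relays are valid but flagged with a warning
  expect_warning(validate_component(spike_relay_component()), "relay")
})

test_that("port compatibility requires equal kind and dimension", {
  s_mv <- port("v", "send", "analog", "mV")
  r_mv <- port("vin", "receive", "analog", "mV")
  r_pa <- port("iin", "receive", "analog", "pA")
  r_ev <- port("sp", "receive", "event")
  s_ev <- port("spo", "send", "event")
  expect_true(check_port_compatibility(s_mv, r_mv))
  expect_false(check_port_compatibility(s_mv, r_pa))
  expect_false(check_port_compatibility(s_mv, r_ev))
  expect_true(check_port_compatibility(s_ev, r_ev))
  expect_error(check_port_compatibility(r_mv, s_mv),
               class = "spml_contract_error")
  # event ports cannot carry a dimension; reduce only on analog receive
  bad <- component("P", "generic", ports = list(port("e", "send", "event", "mV")),
                   regimes = list(regime("r")))
  expect_true(any(vapply(suppressWarnings(validate_component(bad)),
                         `[[`, "", "rule") == "event_port_dimensionless"))
})

test_that("duplicate_component deep-copies under a new name", {
  src <- izhikevich_component()
  copy <- duplicate_component(src, "MSN_D1")
  expect_identical(copy$name, "MSN_D1")
  expect_identical(copy[-1], src[-1])
  expect_identical(validate_component(copy), validate_component(src))
  # mutating the copy leaves the source untouched
  copy$parameters[[1]]$name <- "mutated"
  expect_identical(src$parameters[[1]]$name, "a_p")
  expect_error(duplicate_component(src, src$name),
               class = "spml_contract_error")
  expect_error(duplicate_component(src, "Taken", existing = "Taken"),
               class = "spml_contract_error")
})

test_that("component XML round-trips exactly and rejects bad input", {
  for (comp in list(lif_component(), izhikevich_component(),
                    exp_current_synapse_component(),
                    static_impulse_weight_component(),
                    leaky_integrator_component("LinD1", "d1"),
                    minimal_component())) {
    back <- suppressWarnings(read_component_xml(write_component_xml(comp)))
    expect_identical(back, comp, label = comp$name)
  }
  expect_error(read_component_xml("<ComponentClass name='X' type='generic'>
    <Bogus/><Regime name='r'/></ComponentClass>"),
    class = "spml_parse_error")
  err <- tryCatch(read_component_xml("<ComponentClass name='X' type='generic'>
    <Bogus/><Regime name='r'/></ComponentClass>"), error = function(e) e)
  expect_match(conditionMessage(err), "Bogus")
  # event port carrying a dimension is rejected on load
  expect_error(read_component_xml("<ComponentClass name='X' type='generic'
    initial_regime='r'><EventSendPort name='sp' dimension='mV'/>
    <Regime name='r'/></ComponentClass>"),
    class = "spml_validation_error")
})
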