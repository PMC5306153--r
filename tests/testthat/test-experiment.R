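test_that("input specifications evaluate as piecewise-constant/spike trains", {
  tv <- time_varying_input("A", "p", data.frame(t = 1, v = 0.4))
  expect_equal(input_value(tv, 0.5), 0)
  expect_equal(input_value(tv, 2), 0.4)
  tv2 <- time_varying_input("A", "p", data.frame(t = c(1, 2), v = c(0.4, 0.1)))
  expect_equal(input_value(tv2, c(0, 1, 1.5, 2, 3)), c(0, 0.4, 0.4, 0.1, 0.1))
  expect_error(time_varying_input("A", "p", data.frame(t = c(2, 1),
                                                       v = c(1, 2))),
               class = "spml_validation_error")

  rs <- regular_spike_input("A", "p", rate = 10, start = 0, stop = 1)
  expect_equal(spike_times(rs), seq(0, 0.9, by = 0.1))
  expect_length(spike_times(regular_spike_input("A", "p", 0, 0, 1)), 0)
  expect_equal(input_value(constant_input("A", "p", 3), 0.7), 3)
})

test_that("property changes resolve to a copy, leaving the model untouched", {
  proj <- build_selection_network(3)
  net <- proj$network
  sd1 <- which(vapply(net$populations, `[[`, "", "name") == "SD1")
  net$populations[[sd1]]$properties$da <- fixed_value(0.2)

  exp <- experiment("override", "selection_network", duration = 1,
                    property_changes = list(
                      property_change("SD1", "da", fixed_value(0.5))))
  resolved <- apply_property_changes(net, exp)
  expect_equal(resolved$populations[[sd1]]$properties$da$value, 0.5)
  expect_equal(net$populations[[sd1]]$properties$da$value, 0.2)

  # empty change list is the identity
  expect_identical(apply_property_changes(net, experiment("noop",
    "selection_network", duration = 1)), net)

  # randomised override samples within its bounds
  exp2 <- experiment("rand", "selection_network", duration = 1,
                     property_changes = list(
                       property_change("SD1", "da",
                                       uniform_value(0, 0.3, seed = 6))))
  resolved2 <- apply_property_changes(net, exp2)
  vals <- sample_property(resolved2$populations[[sd1]]$properties$da, 1000)
  expect_true(all(vals >= 0 & vals < 0.3))

  # resolution purity: same experiment twice gives identical networks
  expect_identical(apply_property_changes(net, exp2),
                   apply_property_changes(net, exp2))

  expect_error(apply_property_changes(net, experiment("bad",
    "selection_network", duration = 1, property_changes = list(
      property_change("Nope", "da", fixed_value(1))))),
    class = "spml_contract_error")
})

test_that("experiments validate against their network", {
  proj <- build_selection_network(3)
  ok <- experiment("ok", "selection_network", duration = 1,
                   inputs = list(constant_input("Cortex", "in_a", 1)),
                   loggers = list(logger("SNr", "y", "analog")),
                   property_changes = list(
                     property_change("SD1", "da", fixed_value(0.1))))
  expect_length(validate_experiment(ok, proj$network, proj$components), 0)
  bad <- experiment("bad", "selection_network", duration = 1,
                    inputs = list(constant_input("Cortex", "nope", 1)),
                    loggers = list(logger("SNr", "spike", "event")),
                    property_changes = list(
                      property_change("SD1", "nope", fixed_value(1))))
  v <- validate_experiment(bad, proj$network, proj$components)
  expect_length(v, 3)
})

test_that("experiment XML round-trips and log metadata states the quantity", {
  e <- experiment("rich", "selection_network", duration = 2, dt = 0.5,
                  inputs = list(
                    constant_input("Cortex", "in_a", 0.3),
                    time_varying_input("Cortex", "in_a",
                                       data.frame(t = c(1, 2), v = c(0.4, 0.1)),
                                       indices = 0:1),
                    regular_spike_input("Cortex", "in_a", 10, 0, 1)),
                  loggers = list(logger("SD1", "a", "analog", indices = 0:1),
                                 logger("SD1", "spike", "event")),
                  property_changes = list(
                    property_change("SD1", "da", uniform_value(0, 0.3, 5))),
                  description = "kitchen sink")
  expect_identical(read_experiment_xml(write_experiment_xml(e)), e)

  md <- write_log_metadata(logger("SD1", "a", "analog", indices = 0:1),
                           record_count = 1000, dt = 0.1)
  doc <- xml2::xml_find_first(xml2::read_xml(md), "Log")
  expect_identical(xml2::xml_attr(doc, "records"), "1000")
  expect_identical(xml2::xml_attr(doc, "columns"), "2")
  expect_identical(xml2::xml_attr(doc, "kind"), "analog")
  md2 <- write_log_metadata(logger("SD1", "spike", "event"), 17, 0.1)
  expect_identical(
    xml2::xml_attr(xml2::xml_find_first(xml2::read_xml(md2), "Log"), "kind"),
    "event")
})

test_that("every logger yields exactly one data and one metadata file", {
  proj <- lif_charging_project()
  exp <- experiment("charge", "one", duration = 0.01, dt = 0.1,
                    inputs = list(constant_input("N", "I_syn", 2)),
                    loggers = list(logger("N", "v", "analog")))
  proj$experiments <- list(exp)
  logs <- run_experiment(proj, "charge", 1)
  dir <- withr::local_tempdir()
  files <- write_logset(logs, dir)
  expect_setequal(basename(files), c("N_v.bin", "N_v.csv", "N_v.xml"))
  # binary trace has floor(duration/dt) + 1 records of 8 bytes per column
  expect_equal(file.info(file.path(dir, "N_v.bin"))$size, 101 * 8)
})
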