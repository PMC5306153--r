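test_that("the selection network has the expected roster and sizes", {
  proj <- build_selection_network(3)
  net <- proj$network
  expect_length(validate_project(proj), 0)
  expect_true(all(vapply(net$populations, `[[`, 0L, "size") == 3L))
  expect_length(net$projections, 8)
  edges <- vapply(net$projections, function(p)
    paste(p$source, p$destination, sep = "->"), "")
  expect_setequal(edges, c("Cortex->SD1", "Cortex->SD2", "Cortex->STN",
                           "SD1->SNr", "SD2->GPe", "STN->SNr", "STN->GPe",
                           "GPe->STN"))
  expect_error(build_selection_network(3, weights = list(w_cortex_sd1 = 1)),
               class = "spml_config_error")
})

test_that("rate-to-spiking conversion applies the documented factors", {
  proj <- build_selection_network(2)
  # give the exempt and a non-exempt population explicit intrinsic currents
  for (i in seq_along(proj$network$populations)) {
    p <- proj$network$populations[[i]]
    if (p$name %in% c("STN", "SNr"))
      proj$network$populations[[i]]$properties$I_offset <- fixed_value(1.5)
  }
  conv <- convert_rate_to_snn(proj, seed = 5)
  expect_length(validate_project(conv), 0)
  net <- conv$network

  # each unit becomes 7 LIF neurons
  expect_true(all(vapply(net$populations, `[[`, 0L, "size") == 14L))
  lif_pops <- Filter(function(p) p$component_ref == "LIF", net$populations)
  expect_length(lif_pops, 5)

  # one-to-one channels widen to within-channel all-to-all, 49 per channel
  pr <- net$projections[[1]]
  cl <- pr$synapses[[1]]$connectivity
  expect_s3_class(cl, "spml_connection_list")
  expect_length(cl$src, 2 * 49)
  for (ch in 0:1) {
    in_ch <- cl$src >= ch * 7 & cl$src < (ch + 1) * 7
    expect_equal(sum(in_ch), 49)
    expect_true(all(cl$dst[in_ch] >= ch * 7 & cl$dst[in_ch] < (ch + 1) * 7))
  }

  # weights reduced sevenfold
  w_old <- proj$network$projections[[1]]$synapses[[1]]$weight_update$properties$w$value
  w_new <- pr$synapses[[1]]$weight_update$properties$w$value
  expect_equal(w_old / w_new, 7)

  # currents scaled tenfold, except the subthalamic intrinsic current
  stn <- Find(function(p) p$name == "STN", net$populations)
  snr <- Find(function(p) p$name == "SNr", net$populations)
  expect_equal(stn$properties$I_offset$value, 1.5)
  expect_equal(snr$properties$I_offset$value, 15)

  # membrane time constants drawn from the stated uniform range, seeded
  tm <- sample_property(snr$properties$tau_m, 14)
  expect_true(all(tm >= 20 & tm < 30))
  conv2 <- convert_rate_to_snn(proj, seed = 5)
  expect_identical(
    sample_property(Find(function(p) p$name == "SNr",
                         conv2$network$populations)$properties$tau_m, 14), tm)

  # synapses become 4 ms exponential current synapses
  expect_identical(pr$synapses[[1]]$postsynapse$component_ref,
                   "ExpCurrentSynapse")
  expect_equal(pr$synapses[[1]]$postsynapse$properties$tau_s$value, 4)

  # the cortical analog drive becomes a regular spike train at 100 Hz/unit
  src <- build_selection_network(2)
  src$experiments[[1]]$inputs <- list(constant_input("Cortex", "in_a", 0.4))
  conv3 <- convert_rate_to_snn(src, seed = 5)
  inp <- conv3$experiments[[1]]$inputs[[1]]
  expect_identical(inp$variant, "regular_spikes")
  expect_equal(inp$rate, 40)

  # D2 dopamine influence is slightly reduced
  sd2_old <- Find(function(p) p$name == "SD2", proj$network$populations)
  sd2_new <- Find(function(p) p$name == "SD2", net$populations)
  expect_equal(attr(sd2_new, "d2_dopamine"),
               sd2_old$properties$da$value * 0.9)

  expect_error(convert_rate_to_snn(project("x", network("empty"),
                                           components = list())),
               class = "spml_structure_error")
})

test_that("single-unit toy conversion reproduces the worked factors", {
  w <- selection_weight_defaults()
  proj <- build_selection_network(1, w)
  proj$network$populations[[4]]$properties$I_offset <- fixed_value(1.5) # STN
  proj$network$populations[[5]]$properties$I_offset <- fixed_value(1.5) # SNr
  conv <- convert_rate_to_snn(proj, seed = 2)
  pops <- conv$network$populations
  expect_equal(Find(function(p) p$name == "SD1", pops)$size, 7L)
  pr <- Find(function(p) p$source == "Cortex" && p$destination == "SD1",
             conv$network$projections)
  expect_equal(pr$synapses[[1]]$weight_update$properties$w$value,
               w$w_cortex_sd1 / 7)
  expect_equal(Find(function(p) p$name == "SNr", pops)$properties$I_offset$value,
               15)
  expect_equal(Find(function(p) p$name == "STN", pops)$properties$I_offset$value,
               1.5)
})

test_that("raising one channel's cortical drive disinhibits that channel", {
  # behavioural fixture property: for sign-consistent weight tables, a
  # cortical drive on exactly one channel strictly lowers that channel's SNr
  # output at steady state
  for (seed in 1:5) {
    w <- random_selection_weights(seed)
    base <- snr_steady_state(w, rep(0, 6))
    driven <- snr_steady_state(w, c(0.6, 0, 0, 0, 0, 0))
    expect_lt(driven[[1]], base[[1]])
  }
})

test_that("the striatal-like fixture respects its geometric contracts", {
  proj <- build_striatal_like_fixture(20, 20, 3, side = 300, seed = 9,
                                      radius = 120, min_distance = 10)
  expect_length(validate_project(proj), 0)
  coords <- lapply(c(MSN_D1 = "box_MSN_D1", MSN_D2 = "box_MSN_D2",
                     FSI = "box_FSI"),
                   function(l) generate_layout(proj$layouts[[l]],
                     Find(function(p) p$layout_ref == l,
                          proj$network$populations)$size))
  for (cs in coords) expect_true(all(cs >= 0 & cs < 300))

  # FSI -> MSN_D1 connections never exceed the radius (brute-force check)
  pr <- Find(function(p) p$source == "FSI" && p$destination == "MSN_D1",
             proj$network$projections)
  cl <- pr$synapses[[1]]$connectivity
  expect_gt(length(cl$src), 0)
  for (k in seq_along(cl$src)) {
    d <- sqrt(sum((coords$FSI[cl$src[[k]] + 1, ] -
                     coords$MSN_D1[cl$dst[[k]] + 1, ])^2))
    expect_lte(d, 120)
    expect_equal(cl$delay[[k]], d, tolerance = 1e-9)  # velocity 1 um/ms
  }
  # connection lists carry their regeneration recipe
  expect_false(is.null(cl$recipe))
})
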