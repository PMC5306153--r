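test_that("connectivity schemes expand as defined", {
  oto <- instantiate_connectivity(one_to_one(), 3, 3)
  expect_identical(oto$src, 0:2)
  expect_identical(oto$dst, 0:2)
  expect_error(instantiate_connectivity(one_to_one(), 3, 4),
               class = "spml_contract_error")

  # all_to_all count against a nested-loop oracle, in src-major order
  for (n in c(1, 4, 7, 20)) {
    ata <- instantiate_connectivity(all_to_all(), n, n)
    oracle_src <- integer(); oracle_dst <- integer()
    for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
      oracle_src <- c(oracle_src, i); oracle_dst <- c(oracle_dst, j)
    }
    expect_identical(ata$src, oracle_src)
    expect_identical(ata$dst, oracle_dst)
  }

  expect_length(instantiate_connectivity(fixed_probability(0), 5, 5, 1)$src, 0)
  full <- instantiate_connectivity(fixed_probability(1), 4, 5, 1)
  expect_length(full$src, 20)
})

test_that("fixed_probability is seeded, self-pair aware, and unbiased", {
  a <- instantiate_connectivity(fixed_probability(0.3, seed = 9), 30, 30)
  b <- instantiate_connectivity(fixed_probability(0.3, seed = 9), 30, 30)
  expect_identical(a, b)
  c <- instantiate_connectivity(fixed_probability(0.3, seed = 10), 30, 30)
  expect_false(identical(a, c))

  noself <- instantiate_connectivity(fixed_probability(1, allow_self = FALSE),
                                     10, 10, recurrent = TRUE)
  expect_false(any(noself$src == noself$dst))
  expect_length(noself$src, 90)

  # mean count over 200 seeded draws within 3 standard errors of p * n^2
  counts <- vapply(1:200, function(s)
    length(instantiate_connectivity(fixed_probability(0.2, seed = s),
                                    50, 50)$src), 0L)
  se <- sqrt(500 * 0.8) / sqrt(200)
  expect_lt(abs(mean(counts) - 500), 3 * se)
})

test_that("sample_property covers all variants deterministically", {
  expect_identical(sample_property(fixed_value(25), 7), rep(25, 7))
  expect_identical(sample_property(normal_value(0, 0), 3, seed = 4), rep(0, 3))
  u <- sample_property(uniform_value(20, 30, seed = 11), 10000)
  expect_true(all(u >= 20 & u < 30))
  expect_identical(u, sample_property(uniform_value(20, 30, seed = 11), 10000))
  vl <- value_list(c(2, 0, 1), c(30, 10, 20))
  expect_identical(sample_property(vl, 3), c(10, 20, 30))
  expect_error(sample_property(vl, 4), class = "spml_coverage_error")
  expect_error(value_list(c(0, 0), c(1, 2)), class = "spml_validation_error")
  expect_error(uniform_value(3, 2), class = "spml_validation_error")
})

test_that("copy_properties copies exactly the shared names and reports the rest", {
  comps <- list(A = lif_component("A"), B = izhikevich_component("B"))
  src <- population("P1", 3, "A",
                    list(tau_m = fixed_value(20), I_offset = fixed_value(2),
                         theta = fixed_value(1)))
  dst <- population("P2", 3, "B", list(a_p = fixed_value(0.02)))
  # shared property names between LIF and the quadratic neuron: I_offset, v
  out <- copy_properties(src, dst, comps)
  expect_identical(sort(out$copied), "I_offset")
  expect_identical(sort(out$skipped), c("tau_m", "theta"))
  expect_identical(out$population$properties$I_offset, fixed_value(2))
  expect_identical(out$population$properties$a_p, fixed_value(0.02))
  # identical components: everything copies
  dst2 <- population("P3", 3, "A")
  out2 <- copy_properties(src, dst2, comps)
  expect_identical(out2$population$properties, src$properties)
  expect_length(out2$skipped, 0)
})

test_that("validate_network catches dangling references and port mismatches", {
  proj <- build_selection_network(3)
  expect_length(validate_network(proj$network, proj$components), 0)

  broken <- proj$network
  broken$projections[[4]]$destination <- "GPi2"
  v <- validate_network(broken, proj$components)
  expect_length(v, 1)
  expect_match(v[[1]]$message, "GPi2")

  # generic input with incompatible ports names both ends
  net2 <- proj$network
  net2$generic_inputs <- list(generic_input("SNr", "y", "Cortex", "in_a"),
                              generic_input("SNr", "y", "SD1", "I_in"))
  comps2 <- proj$components
  v2 <- validate_network(net2, comps2)
  expect_length(v2, 0)   # y (dimensionless analog) matches both receive ports
  ei <- list(generic_input("Cortex", "y", "SD1", "missing_port"))
  net2$generic_inputs <- ei
  v3 <- validate_network(net2, comps2)
  expect_length(v3, 1)
  expect_match(v3[[1]]$element, "missing_port")
})

test_that("network and project files round-trip with annotations intact", {
  proj <- build_selection_network(4)
  net2 <- read_network_xml(write_network_xml(proj$network))
  expect_identical(net2, proj$network)

  # population annotations (colour, layout_ref) survive
  strio <- build_striatal_like_fixture(8, 8, 2, seed = 5)
  back <- read_network_xml(write_network_xml(strio$network))
  expect_identical(back, strio$network)
  expect_identical(back$populations[[1]]$colour, "#1f77b4")
  expect_identical(back$populations[[1]]$layout_ref, "box_MSN_D1")

  dir <- withr::local_tempdir()
  write_project(strio, dir)
  back_proj <- read_project(dir)
  expect_identical(back_proj$network, strio$network)
  expect_identical(back_proj$components[names(strio$components)],
                   strio$components)
  expect_identical(unname(back_proj$experiments), strio$experiments)
  expect_identical(back_proj$layouts, strio$layouts)

  # a project listing a missing file is rejected
  unlink(file.path(dir, "Izhikevich2D.xml"))
  expect_error(read_project(dir), class = "spml_validation_error")
})
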