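test_that("previous-iteration semantics: variables read last iteration's value", {
  rule <- layout_rule("walk", equations = list(x = "x + 1"))
  cs <- generate_layout(rule, 4)
  expect_equal(cs[, "x"], c(0, 1, 2, 3))
  expect_equal(cs[, "y"], rep(0, 4))

  # an equation reading a variable assigned EARLIER this frame sees the new
  # value; reading one assigned later sees the previous frame's value
  r1 <- layout_rule("fwd", equations = list(x = "x + 1", y = "x"))
  expect_equal(generate_layout(r1, 3)[, "y"], c(0, 1, 2))
  r2 <- layout_rule("bwd", equations = list(y = "x", x = "x + 1"))
  expect_equal(generate_layout(r2, 3)[, "y"], c(0, 0, 1))

  # permuting equations that do not read each other leaves output unchanged
  ra <- layout_rule("a", equations = list(x = "p * 2", y = "p + 10"))
  rb <- layout_rule("b", equations = list(y = "p + 10", x = "p * 2"))
  expect_equal(unclass(generate_layout(ra, 5))[, c("x", "y", "z")],
               unclass(generate_layout(rb, 5))[, c("x", "y", "z")])

  # undeclared symbols are rejected at rule construction
  expect_error(layout_rule("bad", equations = list(x = "q + 1")),
               class = "spml_validation_error")
})

test_that("seeded layouts are deterministic and respect min_distance", {
  a <- random_box_layout(100, 300, seed = 7, min_distance = 5)
  b <- random_box_layout(100, 300, seed = 7, min_distance = 5)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a),
                         unclass(random_box_layout(100, 300, seed = 8,
                                                   min_distance = 5))))
  expect_true(all(a >= 0 & a < 300))

  # exhaustive O(n^2) pairwise check
  d <- as.matrix(stats::dist(a)); diag(d) <- Inf
  expect_gte(min(d), 5)

  big <- random_box_layout(1000, 300, seed = 3, min_distance = 5)
  d <- as.matrix(stats::dist(big)); diag(d) <- Inf
  expect_gte(min(d), 5)

  c50 <- random_box_layout(50, 300, seed = 1, min_distance = 20)
  d <- as.matrix(stats::dist(c50)); diag(d) <- Inf
  expect_gte(min(d), 20)

  # impossible packing raises, deterministic violation raises immediately
  expect_error(random_box_layout(100, 10, seed = 1, min_distance = 50),
               class = "spml_packing_error")
  det <- layout_rule("flat", equations = list(x = "0"), min_distance = 1)
  expect_error(generate_layout(det, 2), class = "spml_constraint_error")
})

test_that("grid layout fills rows of the requested length", {
  g9 <- grid_layout(9, 3)
  expect_equal(g9[, "x"], rep(0:2, 3))
  expect_equal(g9[, "y"], rep(0:2, each = 3))
  expect_equal(g9[, "z"], rep(0, 9))
  g7 <- grid_layout(7, 3)
  expect_equal(sum(g7[, "y"] == 2), 1)  # last row has one point
  # six channels of seven neurons each
  g42 <- grid_layout(42, 7)
  expect_equal(nrow(g42), 42)
  expect_equal(max(g42[, "x"]), 6)
  expect_equal(max(g42[, "y"]), 5)
  expect_equal(as.vector(table(g42[, "y"])), rep(7L, 6))
})

test_that("layout rules round-trip through project XML and CSV", {
  rule <- layout_rule("rnd", equations = list(x = "rand() * 300",
                                              y = "rand() * 300",
                                              z = "rand() * 300"),
                      seed = 12, min_distance = 2)
  doc <- xml2::xml_new_root("Root")
  spineml:::write_layout_xml(doc, rule)
  back <- spineml:::read_layout_xml(xml2::xml_child(doc))
  expect_identical(back, rule)

  cs <- generate_layout(rule, 20)
  f <- withr::local_tempfile(fileext = ".csv")
  write_coords_csv(cs, f)
  back_cs <- read_coords_csv(f)
  expect_equal(unclass(back_cs), unclass(cs)[, ], tolerance = 1e-12)
})
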