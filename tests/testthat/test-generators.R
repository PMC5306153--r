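test_that("generator metadata parses labels, grid cells and flags", {
  g <- read_generator_script(builtin_generator_path("fixed_radius"))
  expect_identical(g$entry_name, "connect")
  expect_identical(g$params$label, c("radius", "velocity", "base delay"))
  expect_identical(g$params$grid_row, c(1L, 2L, 3L))
  expect_false(g$has_weight)
  expect_true(g$has_delay)

  g2 <- read_generator_script(builtin_generator_path("gaussian_field"))
  expect_true(g2$has_weight)
  expect_false(g2$has_delay)
  expect_equal(nrow(g2$params), 3)

  bare <- parse_generator_metadata(
    "connect <- function(srclocs, dstlocs) list(src = 0, dst = 0)")
  expect_equal(nrow(bare$params), 0)
  expect_false(bare$has_weight || bare$has_delay)

  expect_error(parse_generator_metadata(paste(
    "#PARNAME: a", "#LOC: 1,1", "#PARNAME: b", "#LOC: 1,2", "#PARNAME: c",
    "#LOC: 1,3",
    "connect <- function(srclocs, dstlocs, a) list(src = 0, dst = 0)",
    sep = "\n")), class = "spml_arity_error")
  expect_error(parse_generator_metadata(paste(
    "#PARNAME: a", "#LOC: 1,1", "#PARNAME: b", "#LOC: 1,1",
    "connect <- function(srclocs, dstlocs, a, b) list(src = 0, dst = 0)",
    sep = "\n")), class = "spml_layout_error")
  expect_error(parse_generator_metadata("f <- function(x, y) x + y"),
               class = "spml_validation_error")
})

test_that("fixed_radius connects by distance and matches a brute-force oracle", {
  g <- read_generator_script(builtin_generator_path("fixed_radius"))
  two <- structure(matrix(c(0, 0, 0, 0, 0, 0), 2, 3, byrow = TRUE),
                   class = "spml_coords")
  cl <- run_generator(g, two[1, , drop = FALSE], two[2, , drop = FALSE],
                      c(1, 1, 0))
  expect_identical(cl$src, 0L)
  expect_identical(cl$dst, 0L)

  apart <- structure(matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE),
                     class = "spml_coords")
  cl2 <- run_generator(g, apart[1, , drop = FALSE], apart[2, , drop = FALSE],
                       c(3, 1, 0))
  expect_length(cl2$src, 0)

  src <- random_box_layout(150, 100, seed = 21)
  dst <- random_box_layout(200, 100, seed = 22)
  cl3 <- run_generator(g, src, dst, c(40, 2, 0.5))
  # oracle: direct O(n^2) pair loop
  o_src <- integer(); o_dst <- integer(); o_delay <- numeric()
  for (i in seq_len(nrow(src))) for (j in seq_len(nrow(dst))) {
    d <- sqrt(sum((src[i, ] - dst[j, ])^2))
    if (d <= 40) {
      o_src <- c(o_src, i - 1L); o_dst <- c(o_dst, j - 1L)
      o_delay <- c(o_delay, d / 2 + 0.5)
    }
  }
  expect_identical(cl3$src, o_src)
  expect_identical(cl3$dst, o_dst)
  expect_equal(cl3$delay, o_delay, tolerance = 1e-12)

  # symmetric on equal coordinate sets: (i,j) present iff (j,i) present
  fwd <- run_generator(g, src, src, c(40, 1, 0))
  expect_setequal(paste(fwd$src, fwd$dst), paste(fwd$dst, fwd$src))
})

test_that("gaussian_field matches a seeded brute-force oracle pair by pair", {
  g <- read_generator_script(builtin_generator_path("gaussian_field"))
  src <- grid_layout(100, 10)
  dst <- grid_layout(100, 10)
  cl <- run_generator(g, src, dst, c(2, 1.5, 77), weight_target = "w")
  # oracle: same draw order (src-major, one uniform per destination), direct
  # per-pair probability computation
  suppressWarnings(set.seed(77, kind = "Mersenne-Twister",
                            normal.kind = "Inversion", sample.kind = "Rejection"))
  o_src <- integer(); o_dst <- integer(); o_w <- numeric()
  for (i in seq_len(nrow(src))) {
    u <- stats::runif(nrow(dst))
    for (j in seq_len(nrow(dst))) {
      pr <- exp(-sum((src[i, ] - dst[j, ])^2) / (2 * 2^2))
      if (u[[j]] < pr) {
        o_src <- c(o_src, i - 1L); o_dst <- c(o_dst, j - 1L)
        o_w <- c(o_w, 1.5 * pr)
      }
    }
  }
  expect_identical(cl$src, o_src)
  expect_identical(cl$dst, o_dst)
  expect_equal(cl$weights, o_w, tolerance = 1e-12)
  expect_gt(length(cl$src), 0)
})

test_that("regeneration triggers exactly on script/values/size changes", {
  g <- read_generator_script(builtin_generator_path("fixed_radius"))
  src <- random_box_layout(20, 100, seed = 31)
  cl <- run_generator(g, src, src, c(30, 1, 0))
  rc <- cl$recipe
  expect_false(needs_regeneration(rc, rc$source_text, rc$values, 20, 20))
  expect_true(needs_regeneration(rc, rc$source_text, c(30, 1, 0.5), 20, 20))
  expect_true(needs_regeneration(rc, rc$source_text, rc$values, 21, 20))
  expect_true(needs_regeneration(rc, paste0(rc$source_text, " "),
                                 rc$values, 20, 20))  # whitespace-only edit

  # regeneration from the recipe is bit-exact
  again <- regenerate_from_recipe(rc, src, src)
  expect_identical(again, cl)
})

test_that("persisted connection lists stay valid plain connectivity", {
  cl <- instantiate_connectivity(all_to_all(), 7, 7)
  rc <- generation_recipe("dummy <- function(srclocs, dstlocs) 0",
                          numeric(), 7, 7)
  frag <- persist_with_recipe(cl, rc)
  expect_equal(length(xml2::xml_find_all(xml2::read_xml(frag), "Connection")),
               49)
  back <- read_connection_fragment(frag)
  expect_identical(back$src, cl$src)
  expect_identical(back$recipe$source_text, rc$source_text)

  # stripped of annotations it still loads as a plain connection list
  doc <- xml2::read_xml(frag)
  xml2::xml_remove(xml2::xml_find_all(doc, "Annotations"))
  naked <- read_connection_fragment(as.character(doc))
  expect_identical(naked$src, cl$src)
  expect_null(naked$recipe)

  # load -> save is stable
  frag2 <- persist_with_recipe(back)
  expect_identical(read_connection_fragment(frag2), back)
})

test_that("the sandbox blocks scripts from reaching the file system", {
  evil <- paste("connect <- function(srclocs, dstlocs) {",
                "  readLines('/etc/passwd')",
                "  list(src = 0, dst = 0)", "}", sep = "\n")
  one <- structure(matrix(0, 1, 3), class = "spml_coords")
  expect_error(run_generator(evil, one, one),
               class = "spml_execution_error")
  oor <- "connect <- function(srclocs, dstlocs) list(src = 5, dst = 0)"
  expect_error(run_generator(oor, one, one), class = "spml_validation_error")
})
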