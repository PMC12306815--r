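test_that("direction classification follows the slope threshold rules", {
  expect_equal(classify_direction(10, 1, 0.2), "l-r")
  expect_equal(classify_direction(-10, 1, 0.2), "r-l")
  expect_equal(classify_direction(1, 10, 0.2), "t-b")
  expect_equal(classify_direction(1, -10, 0.2), "b-t")
  expect_equal(classify_direction(10, 10, 0.2), "tl-br")
  expect_equal(classify_direction(-10, -10, 0.2), "br-tl")
  expect_equal(classify_direction(-10, 10, 0.2), "tr-bl")
  expect_equal(classify_direction(10, -10, 0.2), "bl-tr")
  expect_error(classify_direction(0, 0), "zero-length")
})

test_that("classification is total, deterministic and mutually exclusive on a grid sweep", {
  labels <- c("l-r", "r-l", "t-b", "b-t", "tl-br", "br-tl", "tr-bl", "bl-tr")
  eps <- 0.2
  for (dx in -10:10) for (dy in -10:10) {
    if (dx == 0 && dy == 0) next
    lab <- classify_direction(dx, dy, eps)
    expect_true(lab %in% labels)
    expect_identical(lab, classify_direction(dx, dy, eps))
    horiz <- dx != 0 && abs(dy / dx) < eps
    vert <- dy != 0 && abs(dx / dy) < eps
    expect_false(horiz && vert)  # product of the two ratios is 1
  }
})

make_mapping <- function(nodes, segs, parent, kind = "path") {
  out <- tibble::tibble(node = nodes, seg = segs,
                        rank = unlist(lapply(split(nodes, segs), seq_along),
                                      use.names = FALSE))
  structure(out, parent = parent, kind = kind,
            counts = as.integer(table(factor(segs, levels = seq_len(max(segs))))),
            class = c("node_line_mapping", class(out)))
}

test_that("left-right segments emit left/right relatives plus one alignment", {
  mp <- make_mapping(c("a", "b", "c"), c(1, 1, 1),
                     c(a = NA, b = "a", c = "b"))
  cs <- generate_constraints(mp, "l-r")
  expect_equal(nrow(cs$relatives), 2)
  expect_identical(cs$relatives$axis, c("horizontal", "horizontal"))
  expect_identical(cs$relatives$first, c("a", "b"))   # {left: q, right: v}
  expect_identical(cs$relatives$second, c("b", "c"))
  expect_equal(nrow(cs$alignments), 1)
  expect_identical(cs$alignments$axis, "horizontal")
  expect_identical(cs$alignments$members[[1]], c("a", "b", "c"))
})

test_that("diagonal segments emit constraints on both axes and no alignment", {
  mp <- make_mapping("x", 1, c(x = "w"))
  cs <- generate_constraints(mp, "tl-br")
  expect_equal(nrow(cs$relatives), 2)
  expect_identical(cs$relatives$axis, c("horizontal", "vertical"))
  expect_identical(cs$relatives$first, c("w", "w"))
  expect_identical(cs$relatives$second, c("x", "x"))
  expect_equal(nrow(cs$alignments), 0)
})

test_that("a lone parent-less node yields an empty constraint set", {
  mp <- make_mapping("a", 1, c(a = NA))
  cs <- generate_constraints(mp, "t-b")
  expect_equal(nrow(cs$relatives), 0)
  expect_equal(nrow(cs$alignments), 0)
})

test_that("constraint counts scale with mapped nodes by label class", {
  n <- 12
  nodes <- paste0("v", seq_len(n))
  parent <- stats::setNames(c(NA, nodes[-n]), nodes)
  segs <- rep(1:3, each = 4)
  mp <- make_mapping(nodes, segs, parent)
  ax <- generate_constraints(mp, c("l-r", "t-b", "l-r"))
  expect_equal(nrow(ax$relatives), n - 1)
  expect_equal(nrow(ax$alignments), 3)
  di <- generate_constraints(mp, c("tl-br", "bl-tr", "br-tl"))
  expect_equal(nrow(di$relatives), 2 * (n - 1))
  expect_equal(nrow(di$alignments), 0)
})

test_that("contradictory relatives are dropped first-come-first-served", {
  # a 3-cycle folded onto one l-r segment: the wrap-around parent map makes
  # the third left-of constraint close a directed cycle c -> a -> b -> c
  mp <- make_mapping(c("a", "b", "c"), c(1, 1, 1),
                     c(a = "c", b = "a", c = "b"), kind = "cycle")
  expect_warning(cs <- generate_constraints(mp, "l-r"), "contradictory")
  expect_equal(nrow(cs$relatives), 2)
  expect_identical(cs$relatives$first, c("c", "a"))
  expect_identical(cs$relatives$second, c("a", "b"))
})

test_that("constraint sets survive a JSON round trip", {
  mp <- make_mapping(c("a", "b", "c", "d"), c(1, 1, 2, 2),
                     c(a = NA, b = "a", c = "b", d = "c"))
  cs <- generate_constraints(mp, c("l-r", "t-b"))
  json <- constraints_to_json(cs)
  expect_match(json, "relativePlacementConstraint")
  back <- constraints_from_json(json)
  expect_identical(back$relatives, cs$relatives)
  expect_identical(back$alignments$axis, cs$alignments$axis)
  expect_identical(back$alignments$members, cs$alignments$members)

  path <- withr::local_tempfile(fileext = ".json")
  constraints_to_json(cs, path)
  expect_identical(constraints_from_json(path)$relatives, cs$relatives)
})
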