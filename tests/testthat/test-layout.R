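two_node_constraints <- function() {
  structure(list(
    relatives = tibble::tibble(axis = "horizontal", first = "a", second = "b"),
    alignments = tibble::tibble(axis = character(0), members = list())
  ), class = "constraint_set")
}

square_fixture <- function(n = 12) {
  chain <- sketchlayout:::new_chain(
    cbind(c(0, 120, 120, 0, 0), c(0, 0, 120, 120, 0)), closed = TRUE)
  g <- make_graph("cycle", n)
  seq_ <- node_sequence(paste0("n", seq_len(n)), kind = "cycle")
  mapping <- distribute_nodes(chain, seq_)
  anchors <- target_positions(chain, mapping)
  constraints <- generate_constraints(mapping, classify_chain(chain))
  list(g = g, anchors = anchors, constraints = constraints,
       mapping = mapping)
}

cyclic_order_matches <- function(positions, nodes) {
  # angular order around the centroid equals the cycle order (up to
  # rotation and orientation)
  p <- positions[match(nodes, positions$node), ]
  ang <- atan2(p$y - mean(p$y), p$x - mean(p$x))
  r <- unname(rank(ang))
  shift <- which(r == 1)
  fwd <- c(r[shift:length(r)], r[seq_len(shift - 1)])
  bwd <- rev(r)
  shift2 <- which(bwd == 1)
  bwd <- c(bwd[shift2:length(bwd)], bwd[seq_len(shift2 - 1)])
  all(fwd == seq_along(r)) || all(bwd == seq_along(r))
}

test_that("a single relative constraint separates the pair by the gap", {
  g <- igraph::make_graph(~ a - b)
  anchors <- tibble::tibble(node = c("a", "b"), x = c(0, 30), y = c(0, 0))
  res <- constrained_layout(g, two_node_constraints(), anchors,
                            layout_params(iterations = 50, seed = 2))
  x <- stats::setNames(res$positions$x, res$positions$node)
  expect_lte(x["a"], x["b"] - 10 + 1e-6)
  expect_true(all(res$report$satisfied))
})

test_that("alignment groups share a coordinate after the constrained phase", {
  g <- igraph::make_graph(~ a - b, b - c)
  cs <- structure(list(
    relatives = tibble::tibble(axis = character(0), first = character(0),
                               second = character(0)),
    alignments = tibble::tibble(axis = "horizontal",
                                members = list(c("a", "b", "c")))
  ), class = "constraint_set")
  anchors <- tibble::tibble(node = c("a", "b", "c"),
                            x = c(0, 50, 100), y = c(0, 8, -4))
  res <- constrained_layout(g, cs, anchors,
                            layout_params(iterations = 40, seed = 3))
  ys <- res$positions$y
  expect_lte(diff(range(ys)), 1e-6)
})

test_that("a ring on a closed square chain satisfies all constraints in cycle order", {
  fx <- square_fixture(12)
  res <- constrained_layout(fx$g, fx$constraints, fx$anchors,
                            layout_params(seed = 5))
  expect_true(all(res$report$satisfied))
  expect_true(cyclic_order_matches(res$positions, fx$mapping$node))

  ref <- refine_layout(res)
  expect_true(cyclic_order_matches(ref$positions, fx$mapping$node))
})

test_that("layouts are deterministic for a fixed seed", {
  fx <- square_fixture(10)
  r1 <- constrained_layout(fx$g, fx$constraints, fx$anchors,
                           layout_params(iterations = 80, seed = 11))
  r2 <- constrained_layout(fx$g, fx$constraints, fx$anchors,
                           layout_params(iterations = 80, seed = 11))
  expect_identical(r1$positions, r2$positions)
  expect_identical(refine_layout(r1)$positions, refine_layout(r2)$positions)
})

test_that("refinement is capped and the zero-iteration case is the identity", {
  fx <- square_fixture(12)
  res <- constrained_layout(fx$g, fx$constraints, fx$anchors,
                            layout_params(iterations = 100, seed = 5))
  p0 <- layout_params(iterations = 100, seed = 5, refine_iterations = 0)
  same <- refine_layout(res, p0)
  expect_identical(same$positions, res$positions)

  ref <- refine_layout(res)
  d <- sqrt((ref$positions$x - res$positions$x)^2 +
              (ref$positions$y - res$positions$y)^2)
  expect_lte(max(d), res$params$refine_cap + 1e-9)
})

test_that("fidelity is 1 for similarity transforms and lower for scatter", {
  anchors <- tibble::tibble(node = paste0("n", 1:8),
                            x = c(0, 1, 2, 2, 2, 1, 0, 0),
                            y = c(0, 0, 0, 1, 2, 2, 2, 1))
  expect_equal(shape_fidelity(anchors, anchors), 1)

  th <- 0.7
  rot <- anchors
  rot$x <- 3 + 2 * (cos(th) * anchors$x - sin(th) * anchors$y)
  rot$y <- -5 + 2 * (sin(th) * anchors$x + cos(th) * anchors$y)
  expect_equal(shape_fidelity(rot, anchors), 1, tolerance = 1e-9)

  set.seed(1)
  scatter <- tibble::tibble(node = anchors$node,
                            x = runif(8, 0, 2), y = runif(8, 0, 2))
  expect_lt(shape_fidelity(scatter, anchors), 1)

  expect_error(shape_fidelity(anchors[1, ], anchors), "at least 2")
})

test_that("fidelity agrees with symmetric Procrustes from vegan", {
  skip_if_not_installed("vegan")
  set.seed(8)
  A <- tibble::tibble(node = paste0("p", 1:15),
                      x = rnorm(15), y = rnorm(15))
  B <- tibble::tibble(node = A$node,
                      x = A$x + rnorm(15, sd = 0.3),
                      y = A$y + rnorm(15, sd = 0.3))
  ours <- shape_fidelity(B, A)
  ss <- vegan::procrustes(cbind(A$x, A$y), cbind(B$x, B$y),
                          symmetric = TRUE)$ss
  expect_equal(ours, 1 - ss, tolerance = 1e-8)
})

test_that("constraints naming unknown nodes are rejected", {
  g <- igraph::make_graph(~ a - b)
  cs <- structure(list(
    relatives = tibble::tibble(axis = "horizontal", first = "a", second = "zz"),
    alignments = tibble::tibble(axis = character(0), members = list())
  ), class = "constraint_set")
  anchors <- tibble::tibble(node = c("a", "b"), x = c(0, 1), y = c(0, 0))
  expect_error(constrained_layout(g, cs, anchors), "unknown node")
})
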