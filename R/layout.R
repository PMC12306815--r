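#' Layout parameters
#'
#' @param ideal_edge_length Desired edge length in pixels (spring rest
#'   length and repulsion scale).
#' @param iterations Number of constrained force-directed iterations.
#' @param gap Minimum separation, in pixels, enforced by each relative
#'   placement constraint.
#' @param refine_iterations Iterations of the unconstrained refinement.
#' @param refine_cap Maximum total per-node displacement during refinement;
#'   defaults to `ideal_edge_length / 2`.
#' @param seed Integer seed for all layout randomness.
#' @return A `layout_params` list.
#' @export
layout_params <- function(ideal_edge_length = 50, iterations = 500, gap = 10,
                          refine_iterations = 30,
                          refine_cap = ideal_edge_length / 2, seed = 1L) {
  stopifnot(ideal_edge_length > 0, iterations > 0, gap > 0,
            refine_iterations >= 0, refine_cap > 0)
  structure(list(ideal_edge_length = ideal_edge_length,
                 iterations = as.integer(iterations), gap = gap,
                 refine_iterations = as.integer(refine_iterations),
                 refine_cap = refine_cap, seed = as.integer(seed)),
            class = "layout_params")
}

#' Constrained force-directed layout
#'
#' A spring-repulsion embedder (attraction `d^2/k` along edges, repulsion
#' `k^2/d` between node pairs, `k` the ideal edge length) with a constraint
#' projection step after every iteration: alignment groups are snapped to
#' their mean coordinate, then violated relative constraints are repaired
#' symmetrically to exact `gap` separation, for up to 10 sweeps. Constrained
#' nodes start at their sketch anchors, degree-one nodes at a small random
#' offset from a neighbour, remaining nodes at seeded random positions.
#' Temperature (the per-iteration displacement cap) decays linearly from
#' `k/2` to 1 px. After the force phase the projection is iterated to
#' convergence so every constraint is satisfied to residual `<= 1e-6`.
#' Repulsion is exact for up to 1500 nodes and grid-approximated above.
#'
#' @param graph igraph object (named vertices).
#' @param constraints A `constraint_set` (possibly empty).
#' @param anchors Tibble `node`, `x`, `y`: sketch-derived target positions
#'   for the constrained nodes.
#' @param params A [layout_params()] list.
#' @return A `sketch_layout`: list with `positions` (tibble `node`, `x`,
#'   `y`), `report` (per-constraint residuals), `fidelity`, and `params`.
#' @export
constrained_layout <- function(graph, constraints, anchors,
                               params = layout_params()) {
  g <- as_undirected_named(graph)
  nms <- igraph::V(g)$name
  n <- length(nms)
  idx <- stats::setNames(seq_len(n), nms)

  bad <- setdiff(c(constraints$relatives$first, constraints$relatives$second,
                   unlist(constraints$alignments$members)), nms)
  if (length(bad)) {
    stop("constraints reference unknown node(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }

  pos <- init_positions(g, anchors, params)
  k <- params$ideal_edge_length
  em <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(em) <- "integer"
  em <- em - 1L

  proj <- compile_projection(constraints, idx, n)
  apply_projection <- function(pos) {
    for (sys in proj) {
      project_exact(pos, sys$coord, sys$members, sys$topo,
                    sys$edge_first, sys$edge_second, params$gap)
    }
    pos
  }
  for (it in seq_len(params$iterations)) {
    temp <- k / 2 + (1 - k / 2) * (it - 1) / max(1, params$iterations - 1)
    f <- attraction_edges(pos, em, k) + repulse(pos, k, n)
    pos <- pos + cap_displacement(f, temp)
    pos <- apply_projection(pos)
  }
  pos <- apply_projection(pos)
  if (!all(is.finite(pos))) {
    stop("layout diverged to non-finite coordinates", call. = FALSE)
  }

  build_result(g, pos, nms, constraints, anchors, params, refined = FALSE)
}

# Seeded initial positions: anchors, then neighbours+offset for degree-1
# nodes, seeded random box positions for the rest.
init_positions <- function(g, anchors, params) {
  nms <- igraph::V(g)$name
  n <- length(nms)
  k <- params$ideal_edge_length
  if (nrow(anchors) > 0) {
    lo <- c(min(anchors$x), min(anchors$y))
    hi <- c(max(anchors$x), max(anchors$y))
    if (any(hi - lo < k)) hi <- lo + pmax(hi - lo, k)
  } else {
    lo <- c(0, 0)
    hi <- c(10 * k, 10 * k)
  }
  pos <- with_seed(params$seed, cbind(stats::runif(n, lo[1], hi[1]),
                                      stats::runif(n, lo[2], hi[2])))
  rownames(pos) <- nms
  deg <- igraph::degree(g)
  sat <- which(deg == 1)
  if (length(sat)) {
    offs <- with_seed(params$seed + 1L,
                      matrix(stats::runif(2 * length(sat), -k / 2, k / 2),
                             ncol = 2))
    nb <- vapply(sat, function(v) {
      as.integer(igraph::adjacent_vertices(g, v)[[1]][1])
    }, integer(1))
    pos[sat, ] <- pos[nb, , drop = FALSE] + offs
  }
  if (nrow(anchors) > 0) {
    pos[anchors$node, ] <- cbind(anchors$x, anchors$y)
  }
  pos
}

# Per-coordinate projection systems for the C++ kernel. On x (coord 0) the
# "horizontal" relative constraints order nodes and "vertical" alignment
# groups share the coordinate; on y (coord 1) it is the reverse. Alignment
# groups are merged into super-nodes by union-find; relative constraints
# become gap edges between super-nodes, and any constraint that is
# infeasible at the merged level (endpoints in one super-node, or closing
# a directed cycle) is dropped, first come first served, with a warning.
compile_projection <- function(constraints, idx, n) {
  lapply(c(0L, 1L), function(coord) {
    rel_axis <- if (coord == 0L) "horizontal" else "vertical"
    al_axis <- if (coord == 0L) "vertical" else "horizontal"
    rel <- constraints$relatives[constraints$relatives$axis == rel_axis, ]
    groups <- constraints$alignments$members[
      constraints$alignments$axis == al_axis]

    uf <- seq_len(n)
    find <- function(i) {
      while (uf[i] != i) {
        uf[i] <<- uf[uf[i]]
        i <- uf[i]
      }
      i
    }
    for (g in groups) {
      gi <- as.integer(idx[g])
      r <- find(gi[1])
      for (j in gi[-1]) {
        uf[find(j)] <- r
      }
    }

    constrained <- sort(unique(c(
      unlist(lapply(groups, function(g) as.integer(idx[g]))),
      as.integer(idx[rel$first]), as.integer(idx[rel$second])
    )))
    if (length(constrained) == 0L) {
      return(list(coord = coord, members = list(), topo = integer(0),
                  edge_first = integer(0), edge_second = integer(0)))
    }
    roots <- vapply(constrained, find, integer(1))
    super <- match(roots, unique(roots))          # 1-based super id
    super_of <- stats::setNames(super, constrained)
    ns <- max(super)
    members <- split(constrained - 1L, super)     # 0-based node indices

    # gap edges between super-nodes, dropping infeasible ones
    adj <- vector("list", ns)
    ef <- integer(0)
    es <- integer(0)
    reaches <- function(from, to) {
      stack <- from
      seen <- logical(ns)
      while (length(stack)) {
        v <- stack[length(stack)]
        stack <- stack[-length(stack)]
        if (v == to) return(TRUE)
        if (seen[v]) next
        seen[v] <- TRUE
        stack <- c(stack, adj[[v]])
      }
      FALSE
    }
    for (i in seq_len(nrow(rel))) {
      s1 <- super_of[[as.character(idx[[rel$first[i]]])]]
      s2 <- super_of[[as.character(idx[[rel$second[i]]])]]
      if (s1 == s2 || reaches(s2, s1)) {
        warning("dropping ", rel_axis, " constraint ", rel$first[i], " -> ",
                rel$second[i], ": infeasible with alignment groups",
                call. = FALSE)
        next
      }
      adj[[s1]] <- c(adj[[s1]], s2)
      ef <- c(ef, s1)
      es <- c(es, s2)
    }

    # Kahn topological order of the super-node DAG
    indeg <- tabulate(es, nbins = ns)
    queue <- which(indeg == 0L)
    topo <- integer(0)
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      topo <- c(topo, v)
      for (u in adj[[v]]) {
        indeg[u] <- indeg[u] - 1L
        if (indeg[u] == 0L) queue <- c(queue, u)
      }
    }

    list(coord = coord, members = unname(members),
         topo = as.integer(topo - 1L),
         edge_first = as.integer(ef - 1L), edge_second = as.integer(es - 1L))
  })
}

repulse <- function(pos, k, n) {
  if (n <= 1500) repulsion_exact(pos, k) else repulsion_grid(pos, k, 4 * k)
}

cap_displacement <- function(f, temp) {
  len <- sqrt(rowSums(f^2))
  scale <- ifelse(len > temp, temp / len, 1)
  f * scale
}

build_result <- function(g, pos, nms, constraints, anchors, params, refined) {
  positions <- tibble::tibble(node = nms,
                              x = unname(pos[, 1]), y = unname(pos[, 2]))
  report <- constraint_report(positions, constraints, params$gap)
  fid <- if (nrow(anchors) >= 2) {
    shape_fidelity(positions, anchors)
  } else {
    NA_real_
  }
  structure(list(positions = positions, report = report, fidelity = fid,
                 anchors = anchors, constraints = constraints,
                 params = params, graph = g, refined = refined),
            class = "sketch_layout")
}

#' Per-constraint satisfaction report
#'
#' Residual of each constraint under the given positions: for a relative
#' constraint, `max(0, first - (second - gap))` on its axis; for an
#' alignment group, the coordinate spread of its members. A constraint is
#' satisfied when its residual is at most 1e-6.
#'
#' @param positions Tibble `node`, `x`, `y`.
#' @param constraints A `constraint_set`.
#' @param gap Relative-constraint separation in pixels.
#' @return Tibble with columns `type`, `axis`, `residual`, `satisfied`.
#' @export
constraint_report <- function(positions, constraints, gap = 10) {
  px <- stats::setNames(positions$x, positions$node)
  py <- stats::setNames(positions$y, positions$node)
  rel <- constraints$relatives
  rres <- if (nrow(rel)) {
    a <- ifelse(rel$axis == "horizontal", px[rel$first], py[rel$first])
    b <- ifelse(rel$axis == "horizontal", px[rel$second], py[rel$second])
    pmax(0, a - (b - gap))
  } else {
    numeric(0)
  }
  al <- constraints$alignments
  ares <- if (nrow(al)) {
    vapply(seq_len(nrow(al)), function(i) {
      v <- if (al$axis[i] == "horizontal") py[al$members[[i]]] else px[al$members[[i]]]
      max(v) - min(v)
    }, numeric(1))
  } else {
    numeric(0)
  }
  out <- tibble::tibble(
    type = c(rep("relative", length(rres)), rep("alignment", length(ares))),
    axis = c(rel$axis, al$axis),
    residual = c(rres, ares)
  )
  out$satisfied <- out$residual <= 1e-6
  out
}

#' Unconstrained refinement
#'
#' A short low-temperature unconstrained force-directed pass that relaxes
#' the constrained result for a more natural look. Each node's total
#' displacement from its constrained position is capped at
#' `params$refine_cap`, so the sketched structure cannot drift far;
#' constraints may be slightly violated afterwards (the report and fidelity
#' are recomputed).
#'
#' @param result A `sketch_layout` from [constrained_layout()].
#' @param params A [layout_params()] list (uses `refine_iterations` and
#'   `refine_cap`).
#' @return A refined `sketch_layout`.
#' @export
refine_layout <- function(result, params = result$params) {
  stopifnot(inherits(result, "sketch_layout"))
  g <- result$graph
  nms <- result$positions$node
  pos0 <- cbind(result$positions$x, result$positions$y)
  pos <- pos0
  k <- params$ideal_edge_length
  if (params$refine_iterations > 0) {
    em <- igraph::as_edgelist(g, names = FALSE)
    storage.mode(em) <- "integer"
    em <- em - 1L
    n <- nrow(pos)
    for (it in seq_len(params$refine_iterations)) {
      temp <- max(1, (k / 8) * (1 - (it - 1) / params$refine_iterations))
      f <- attraction_edges(pos, em, k) + repulse(pos, k, n)
      pos <- pos + cap_displacement(f, temp)
      # cap the cumulative displacement from the constrained result
      dvec <- pos - pos0
      dl <- sqrt(rowSums(dvec^2))
      over <- dl > params$refine_cap
      if (any(over)) {
        pos[over, ] <- pos0[over, , drop = FALSE] +
          dvec[over, , drop = FALSE] * (params$refine_cap / dl[over])
      }
    }
  }
  out <- build_result(g, pos, nms, result$constraints, result$anchors,
                      params, refined = TRUE)
  out
}

#' Shape fidelity score
#'
#' Similarity-invariant agreement between achieved positions and their
#' sketch anchors: both point sets are centred and unit-normalised, the
#' optimal rotation-plus-scale (Procrustes, reflections excluded) is
#' applied, and the score is one minus the residual sum of squares —
#' equivalently the squared sum of the (sign-corrected) singular values of
#' the cross-covariance. 1 means the layout is an exact similarity
#' transform of the anchors; 0 means no agreement.
#'
#' @param positions Tibble `node`, `x`, `y`.
#' @param anchors Tibble `node`, `x`, `y`; at least 2 nodes must be shared.
#' @return A score in `[0, 1]`.
#' @export
shape_fidelity <- function(positions, anchors) {
  shared <- intersect(positions$node, anchors$node)
  if (length(shared) < 2) {
    stop("fidelity needs at least 2 shared nodes", call. = FALSE)
  }
  X <- as.matrix(anchors[match(shared, anchors$node), c("x", "y")])
  Y <- as.matrix(positions[match(shared, positions$node), c("x", "y")])
  X <- scale(X, scale = FALSE)
  Y <- scale(Y, scale = FALSE)
  nx <- sqrt(sum(X^2))
  ny <- sqrt(sum(Y^2))
  if (nx == 0 || ny == 0) return(0)
  M <- crossprod(X / nx, Y / ny)
  sv <- svd(M)
  s <- sv$d
  if (det(M) < 0) s[2] <- -s[2]  # rotation only, no reflection
  tr <- sum(s)
  max(0, min(1, tr^2))
}

#' @export
print.sketch_layout <- function(x, ...) {
  sat <- if (nrow(x$report)) mean(x$report$satisfied) else NA
  cat(sprintf(
    "<sketch_layout> %d node(s)%s; constraints satisfied: %s; fidelity: %s\n",
    nrow(x$positions), if (x$refined) " (refined)" else "",
    if (is.na(sat)) "n/a" else sprintf("%.1f%%", 100 * sat),
    if (is.na(x$fidelity)) "n/a" else sprintf("%.3f", x$fidelity)
  ))
  invisible(x)
}
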