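#' Prune degree-one nodes
#'
#' Drops every node whose degree in the original graph is 1, together with
#' its incident edges, in a single pass over the original degrees (no
#' iterative peeling by default: repeated peeling would empty path-like
#' graphs entirely). Self-loops are removed first with a warning, and the
#' graph is treated as undirected.
#'
#' @param graph An igraph object (named vertices).
#' @param iterative If `TRUE`, peel repeatedly to the 2-core instead.
#' @param keep_all If `TRUE`, skip pruning entirely (fallback for graphs
#'   whose pruned core would be empty, e.g. a single edge).
#' @return The pruned igraph. Errors with "graph has no multi-degree core"
#'   if no node survives and `keep_all` is `FALSE`.
#' @export
prune_graph <- function(graph, iterative = FALSE, keep_all = FALSE) {
  stopifnot(igraph::vcount(graph) > 0)
  g <- as_undirected_named(graph)
  if (keep_all) return(g)
  if (iterative) {
    core <- igraph::coreness(g)
    keep <- igraph::V(g)[core >= 2]
  } else {
    keep <- igraph::V(g)[igraph::degree(g) > 1]
  }
  if (length(keep) == 0L) {
    stop("graph has no multi-degree core", call. = FALSE)
  }
  igraph::induced_subgraph(g, keep)
}

# Undirected simple named copy of a graph; warns when self-loops dropped.
as_undirected_named <- function(graph) {
  g <- graph
  if (igraph::is_directed(g)) {
    g <- igraph::as_undirected(g, mode = "collapse")
  }
  if (any(igraph::which_loop(g))) {
    warning("self-loops dropped before mapping", call. = FALSE)
    g <- igraph::simplify(g, remove.multiple = FALSE, remove.loops = TRUE)
  }
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  g
}

#' Long-cycle heuristic
#'
#' Depth-first search from each not-yet-visited node (iteration order is a
#' seeded shuffle, then fixed), tracking the longest simple cycle closed by
#' a back edge to the current DFS stack. DFS from already-visited nodes is
#' skipped, and total neighbour examinations are capped at
#' `work_factor * (|V| + |E|)` to keep the search near-linear. The cycle is
#' returned only when its length reaches `tau`.
#'
#' @param pruned Pruned igraph.
#' @param tau Minimum acceptable cycle length (>= 3).
#' @param seed Integer seed for the node iteration order.
#' @param work_factor Cap multiplier on neighbour examinations.
#' @return A node sequence (see [node_sequence()]) of kind `"cycle"`, or
#'   `NULL` when no sufficiently long cycle is found.
#' @export
find_long_cycle <- function(pruned, tau, seed = 1L, work_factor = 50) {
  stopifnot(tau >= 3)
  n <- igraph::vcount(pruned)
  if (n == 0L) return(NULL)
  nms <- igraph::V(pruned)$name
  adj <- lapply(igraph::adjacent_vertices(pruned, igraph::V(pruned)),
                function(v) sort(as.integer(v)))
  order_ <- with_seed(seed, sample.int(n))
  budget <- work_factor * (n + igraph::ecount(pruned))

  visited <- rep(FALSE, n)
  depth <- rep(0L, n)        # 1-based depth while on stack, 0 otherwise
  best <- integer(0)
  work <- 0L

  for (s in order_) {
    if (visited[s]) next
    # iterative DFS with explicit stack; next-neighbour cursor per level
    stack <- s
    cursor <- 1L
    depth[s] <- 1L
    visited[s] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]
      nb <- adj[[v]]
      advanced <- FALSE
      while (cursor[length(cursor)] <= length(nb)) {
        u <- nb[cursor[length(cursor)]]
        cursor[length(cursor)] <- cursor[length(cursor)] + 1L
        work <- work + 1L
        if (depth[u] > 0L) {
          len <- depth[v] - depth[u] + 1L
          if (len >= 3L && len > length(best)) {
            best <- stack[depth[u]:depth[v]]
          }
        } else if (!visited[u]) {
          visited[u] <- TRUE
          depth[u] <- depth[v] + 1L
          stack <- c(stack, u)
          cursor <- c(cursor, 1L)
          advanced <- TRUE
          break
        }
      }
      if (!advanced && cursor[length(cursor)] > length(nb)) {
        depth[v] <- 0L
        stack <- stack[-length(stack)]
        cursor <- cursor[-length(cursor)]
      }
      if (work > budget) break
    }
    if (work > budget) break
  }

  if (length(best) < tau) return(NULL)
  nodes <- nms[best]
  stopifnot(is_simple_cycle(pruned, nodes))
  node_sequence(nodes, kind = "cycle")
}

# Validate that `nodes` traces a simple cycle in g.
is_simple_cycle <- function(g, nodes) {
  if (anyDuplicated(nodes)) return(FALSE)
  m <- length(nodes)
  if (m < 3L) return(FALSE)
  pairs <- cbind(nodes, nodes[c(2:m, 1)])
  all(apply(pairs, 1, function(p) {
    igraph::are_adjacent(g, p[1], p[2])
  }))
}

#' BFS double sweep
#'
#' First BFS from a seeded-random node of the largest connected component
#' finds a farthest node (maximum hop distance, ties broken by smallest
#' node id); a second BFS from that node yields the visit order and its
#' BFS-tree parents. Neighbours are explored in sorted-id order so the
#' sweep is deterministic given the seed. Nodes outside the largest
#' component are excluded and reported via the `"excluded"` attribute.
#'
#' @param pruned Pruned igraph (non-empty).
#' @param seed Integer seed for the start-node draw.
#' @return A node sequence of kind `"path"`.
#' @export
bfs_double_sweep <- function(pruned, seed = 1L) {
  n <- igraph::vcount(pruned)
  stopifnot(n > 0)
  nms <- igraph::V(pruned)$name
  comp <- igraph::components(pruned)
  big <- which.max(comp$csize)
  members <- which(comp$membership == big)
  excluded <- nms[comp$membership != big]
  if (length(excluded)) {
    warning(length(excluded), " node(s) outside the largest component are ",
            "not mapped", call. = FALSE)
  }
  adj <- lapply(igraph::adjacent_vertices(pruned, igraph::V(pruned)),
                function(v) {
      iv <- as.integer(v)
      iv[order(nms[iv])]
  })

  start <- members[with_seed(seed, sample.int(length(members), 1L))]
  d1 <- bfs_orders(adj, start)$dist
  far_cand <- members[d1[members] == max(d1[members])]
  v_far <- far_cand[order(nms[far_cand])][1]
  sweep2 <- bfs_orders(adj, v_far)
  ord <- sweep2$order
  parent <- sweep2$parent

  pmap <- stats::setNames(rep(NA_character_, length(ord)), nms[ord])
  has_par <- parent[ord] > 0L
  pmap[nms[ord[has_par]]] <- nms[parent[ord[has_par]]]
  seq_ <- node_sequence(nms[ord], kind = "path", parent = pmap)
  attr(seq_, "excluded") <- excluded
  seq_
}

# Queue BFS over adjacency lists from `start`; returns visit order,
# distances (Inf if unreached) and parents (0 for none).
bfs_orders <- function(adj, start) {
  n <- length(adj)
  dist <- rep(Inf, n)
  parent <- rep(0L, n)
  order_ <- integer(0)
  dist[start] <- 0
  queue <- start
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    order_ <- c(order_, v)
    for (u in adj[[v]]) {
      if (is.infinite(dist[u])) {
        dist[u] <- dist[v] + 1
        parent[u] <- v
        queue <- c(queue, u)
      }
    }
  }
  list(order = order_, dist = dist, parent = parent)
}

#' Construct a node sequence
#'
#' An ordered list of distinct node ids with a traversal parent map. For a
#' cycle the parent of each node is its cycle predecessor (the first node's
#' parent is the last node); for a path the default parent is the previous
#' node in the order, unless an explicit BFS-tree parent map is supplied.
#'
#' @param nodes Character vector of distinct node ids.
#' @param kind `"cycle"` or `"path"`.
#' @param parent Optional named character vector: parent of each node
#'   (`NA` for none).
#' @return A `node_sequence` list with elements `nodes`, `kind`, `parent`.
#' @export
node_sequence <- function(nodes, kind = c("path", "cycle"), parent = NULL) {
  kind <- match.arg(kind)
  nodes <- as.character(nodes)
  stopifnot(!anyDuplicated(nodes), length(nodes) >= 1)
  if (is.null(parent)) {
    if (kind == "cycle") {
      parent <- stats::setNames(nodes[c(length(nodes), seq_len(length(nodes) - 1L))],
                                nodes)
    } else {
      parent <- stats::setNames(c(NA_character_, nodes[-length(nodes)]), nodes)
    }
  }
  stopifnot(setequal(names(parent), nodes))
  structure(list(nodes = nodes, kind = kind, parent = parent[nodes]),
            class = "node_sequence")
}

#' @export
print.node_sequence <- function(x, ...) {
  cat(sprintf("<node_sequence> kind=%s, %d node(s)\n", x$kind, length(x$nodes)))
  invisible(x)
}

#' Choose the node sequence for a chain
#'
#' Closed-loop mapping (the cycle heuristic) is used only when the chain is
#' closed AND a cycle of length at least `ceiling(tau_factor * sqrt(|V'|))`
#' is found; every other combination falls back to the BFS double sweep.
#'
#' @param pruned Pruned igraph.
#' @param chain A `sketch_chain`.
#' @param tau_factor Multiplier on `sqrt(|V'|)` for the cycle-acceptance
#'   threshold (default 2).
#' @param seed Integer seed.
#' @return A `node_sequence`.
#' @export
choose_sequence <- function(pruned, chain, tau_factor = 2, seed = 1L) {
  if (chain_closed(chain)) {
    tau <- max(3L, ceiling(tau_factor * sqrt(igraph::vcount(pruned))))
    cyc <- find_long_cycle(pruned, tau = tau, seed = seed)
    if (!is.null(cyc)) return(cyc)
  }
  bfs_double_sweep(pruned, seed = seed)
}

#' Distribute a node sequence over chain segments
#'
#' Each segment receives a real-valued quota `d_i * |seq| / D` of nodes
#' (`d_i` the segment length, `D` the chain's total length); integer counts
#' come from the largest-remainder method with ties broken by lower segment
#' index, so counts always sum to `|seq|`. Nodes are dealt to segments in
#' traversal order, preserving their relative positions.
#'
#' @param chain A `sketch_chain`.
#' @param seq A `node_sequence`.
#' @return A `node_line_mapping`: tibble with columns `node`, `seg`, `rank`
#'   (position within the segment), carrying the parent map and sequence
#'   kind as attributes.
#' @export
distribute_nodes <- function(chain, seq) {
  stopifnot(inherits(chain, "sketch_chain"), inherits(seq, "node_sequence"))
  k <- largest_remainder(chain$length, length(seq$nodes))
  segi <- rep(chain$seg, k)
  rank <- unlist(lapply(k, seq_len), use.names = FALSE)
  out <- tibble::tibble(node = seq$nodes, seg = segi, rank = rank)
  structure(out,
            parent = seq$parent,
            kind = seq$kind,
            counts = k,
            class = c("node_line_mapping", class(out)))
}

#' Largest-remainder apportionment
#'
#' Allocates `total` integer units proportionally to `weights`: floors of
#' the real quotas, then one extra unit to the largest fractional
#' remainders (ties to the lower index) until the total is reached.
#'
#' @param weights Non-negative numeric weights (not all zero).
#' @param total Non-negative integer to allocate.
#' @return Integer vector summing exactly to `total`.
#' @export
largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), sum(weights) > 0, total >= 0)
  quota <- weights * total / sum(weights)
  k <- floor(quota)
  rem <- total - sum(k)
  if (rem > 0) {
    frac <- quota - k
    extra <- order(-frac, seq_along(frac))[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  as.integer(k)
}

#' Anchor positions along the chain
#'
#' Places the nodes of each segment at evenly spaced interior fractions
#' `j / (k_i + 1)` along the segment, scaled by `canvas_scale`. These
#' anchors initialize the constrained layout and define the reference shape
#' for the fidelity score.
#'
#' @param chain A `sketch_chain`.
#' @param mapping A `node_line_mapping` from [distribute_nodes()].
#' @param canvas_scale Scale factor applied to image coordinates.
#' @return Tibble with columns `node`, `x`, `y`.
#' @export
target_positions <- function(chain, mapping, canvas_scale = 1) {
  counts <- attr(mapping, "counts")
  seg <- chain[mapping$seg, ]
  t <- mapping$rank / (counts[mapping$seg] + 1)
  tibble::tibble(
    node = mapping$node,
    x = (seg$x0 + t * (seg$x1 - seg$x0)) * canvas_scale,
    y = (seg$y0 + t * (seg$y1 - seg$y0)) * canvas_scale
  )
}
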