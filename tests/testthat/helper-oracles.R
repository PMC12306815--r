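# Independent oracles used across the suite. These deliberately avoid the
# package's own internals: component counting is a plain flood fill and the
# longest-cycle oracle is exhaustive DFS enumeration.

# 8-connected component count by queue flood fill.
oracle_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      r <- (p - 1L) %% nrow(mask) + 1L
      c <- (p - 1L) %/% nrow(mask) + 1L
      for (k in seq_len(nrow(offs))) {
        r2 <- r + offs$dr[k]
        c2 <- c + offs$dc[k]
        if (r2 < 1 || r2 > nrow(mask) || c2 < 1 || c2 > ncol(mask)) next
        q <- (c2 - 1L) * nrow(mask) + r2
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  nxt
}

# Exhaustive longest simple cycle length (0 if acyclic). Only for tiny graphs.
oracle_longest_cycle <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  best <- 0L
  path <- integer(0)
  onpath <- rep(FALSE, n)
  dfs <- function(v, start, depth) {
    onpath[v] <<- TRUE
    path[depth] <<- v
    for (u in adj[[v]]) {
      if (u == start && depth >= 3L) {
        best <<- max(best, depth)
      } else if (!onpath[u] && u > start) {
        # only extend with ids above start: each cycle counted from its
        # minimum vertex, avoiding duplicates
        dfs(u, start, depth + 1L)
      }
    }
    onpath[v] <<- FALSE
  }
  for (s in seq_len(n)) dfs(s, s, 1L)
  best
}

# Random blob mask: union of seeded discs and bars on a small grid.
random_blob <- function(seed, size = 48) {
  set.seed(seed)
  m <- matrix(FALSE, size, size)
  xs <- matrix(rep(seq_len(size), each = size), size, size)
  ys <- matrix(rep(seq_len(size), size), size, size)
  for (i in seq_len(sample(2:4, 1))) {
    cx <- runif(1, 8, size - 8)
    cy <- runif(1, 8, size - 8)
    r <- runif(1, 3, 7)
    m <- m | ((xs - cx)^2 + (ys - cy)^2 <= r^2)
  }
  for (i in seq_len(sample(1:3, 1))) {
    r0 <- sample(5:(size - 10), 1)
    c0 <- sample(5:(size - 15), 1)
    m[r0:(r0 + sample(1:4, 1)), c0:(c0 + sample(5:12, 1))] <- TRUE
  }
  m
}

# Random jagged polyline for simplification property tests.
random_polyline <- function(seed, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(10:80, 1)
  ang <- cumsum(runif(n, -0.6, 0.6))
  step <- runif(n, 1, 6)
  tibble::tibble(x = cumsum(step * cos(ang)), y = cumsum(step * sin(ang)))
}

# Small connected random graph for the cycle-heuristic oracle suite.
random_connected_graph <- function(seed, n) {
  set.seed(seed)
  repeat {
    m <- sample(n:(n + 4), 1)
    from <- sample.int(n, m, replace = TRUE)
    to <- sample.int(n, m, replace = TRUE)
    keep <- from != to
    el <- unique(cbind(pmin(from[keep], to[keep]), pmax(from[keep], to[keep])))
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(el))
    igraph::V(g)$name <- paste0("v", seq_len(n))
    if (igraph::is_connected(g)) return(g)
  }
}
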