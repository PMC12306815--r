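#' Render a synthetic sketch
#'
#' Draws one of five canonical stroke shapes (dark on white) onto an
#' intensity matrix, emulating a freehand sketch. Freehand wobble is
#' emulated by per-vertex Gaussian displacement (`sigma = jitter`) applied
#' to the shape's control points before rasterization. The exact (jittered)
#' ground-truth polyline is attached as the `"ground_truth"` attribute and
#' the intended closedness as `"closed"`, so downstream stages can be
#' checked against known truth.
#'
#' @param shape One of `"line"`, `"L"`, `"rectangle"`, `"circle"`,
#'   `"zigzag"`.
#' @param stroke_width Stroke width in pixels (>= 1).
#' @param jitter Standard deviation of per-vertex displacement, pixels.
#' @param resolution Integer `c(width, height)` in pixels.
#' @param seed Integer seed (jitter is deterministic per seed).
#' @return Intensity matrix in `[0, 255]` (rows = y, columns = x), with
#'   attributes `ground_truth` (tibble `x`, `y`) and `closed`.
#' @export
render_sketch <- function(shape = c("line", "L", "rectangle", "circle", "zigzag"),
                          stroke_width = 3, jitter = 0,
                          resolution = c(512, 512), seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(stroke_width >= 1, jitter >= 0, all(resolution >= 32))
  w <- resolution[1]
  h <- resolution[2]
  pts <- switch(shape,
    line = cbind(c(0.1, 0.9) * w, c(0.5, 0.5) * h),
    L = cbind(c(0.25, 0.25, 0.8) * w, c(0.2, 0.75, 0.75) * h),
    rectangle = cbind(c(0.15, 0.85, 0.85, 0.15, 0.15) * w,
                      c(0.15, 0.15, 0.85, 0.85, 0.15) * h),
    circle = {
      th <- seq(0, 2 * pi, length.out = 73)
      cbind(0.5 * w + 0.35 * min(w, h) * cos(th),
            0.5 * h + 0.35 * min(w, h) * sin(th))
    },
    zigzag = cbind(seq(0.1, 0.9, length.out = 5) * w,
                   c(0.25, 0.75, 0.25, 0.75, 0.25) * h)
  )
  closed <- shape %in% c("rectangle", "circle")
  if (jitter > 0) {
    nfree <- nrow(pts) - if (closed) 1L else 0L
    noise <- with_seed(seed, matrix(stats::rnorm(2 * nfree, sd = jitter),
                                    ncol = 2))
    pts[seq_len(nfree), ] <- pts[seq_len(nfree), ] + noise
    if (closed) pts[nrow(pts), ] <- pts[1, ]
  }
  img <- matrix(255, nrow = h, ncol = w)
  mask <- rasterize_stroke(pts, w, h, stroke_width)
  img[mask] <- 0
  structure(img,
            ground_truth = tibble::tibble(x = pts[, 1], y = pts[, 2]),
            closed = closed)
}

# Rasterize a polyline with a given stroke width onto an h x w canvas.
rasterize_stroke <- function(pts, w, h, width) {
  r <- width / 2
  # disc of pixel offsets covering the stroke radius
  rad <- ceiling(r)
  og <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  og <- og[sqrt(og$dr^2 + og$dc^2) <= max(r - 0.5, 0) + 0.5, , drop = FALSE]
  mask <- matrix(FALSE, nrow = h, ncol = w)
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]
    b <- pts[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    ns <- max(2L, ceiling(len / 0.3))
    t <- seq(0, 1, length.out = ns)
    sx <- round(a[1] + t * (b[1] - a[1]))
    sy <- round(a[2] + t * (b[2] - a[2]))
    cols <- as.integer(outer(sx, og$dc, `+`))
    rows <- as.integer(outer(sy, og$dr, `+`))
    ok <- rows >= 1L & rows <= h & cols >= 1L & cols <= w
    mask[cbind(rows[ok], cols[ok])] <- TRUE
  }
  mask
}

#' Generate a synthetic graph
#'
#' Deterministic per seed. `cycle` and `path` are the standard ring and
#' path graphs; `tree` is a random-attachment tree (node i joins a uniform
#' earlier node); `sparse_random` is such a tree plus `extra_edges`
#' additional distinct non-tree edges, hence always connected.
#'
#' @param kind One of `"cycle"`, `"path"`, `"tree"`, `"sparse_random"`.
#' @param n Number of nodes (>= 2).
#' @param extra_edges Extra edges for `sparse_random`.
#' @param seed Integer seed.
#' @return An undirected igraph with vertex names `"n1" ... "nN"`.
#' @export
make_graph <- function(kind = c("cycle", "path", "tree", "sparse_random"),
                       n, extra_edges = 0, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n >= 2)
  nms <- paste0("n", seq_len(n))
  edges <- switch(kind,
    cycle = cbind(seq_len(n), c(seq_len(n - 1) + 1L, 1L)),
    path = cbind(seq_len(n - 1), seq_len(n - 1) + 1L),
    tree = random_tree_edges(n, seed),
    sparse_random = {
      te <- random_tree_edges(n, seed)
      existing <- paste(pmin(te[, 1], te[, 2]), pmax(te[, 1], te[, 2]))
      extra <- matrix(0L, 0, 2)
      if (extra_edges > 0) {
        extra <- with_seed(seed + 1L, {
          out <- matrix(0L, extra_edges, 2)
          got <- 0L
          while (got < extra_edges) {
            u <- sample.int(n, 1L)
            v <- sample.int(n, 1L)
            if (u == v) next
            key <- paste(min(u, v), max(u, v))
            if (key %in% existing) next
            existing <- c(existing, key)
            got <- got + 1L
            out[got, ] <- c(u, v)
          }
          out
        })
      }
      rbind(te, extra)
    }
  )
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  igraph::V(g)$name <- nms
  g
}

random_tree_edges <- function(n, seed) {
  with_seed(seed, {
    parents <- vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
    cbind(parents, 2:n)
  })
}
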