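#' Assemble simplified polylines into an ordered segment chain
#'
#' Greedily concatenates polylines: starting from the first, the polyline
#' with the nearest free endpoint (within `offset_threshold`) is attached to
#' a free chain end, reversed if needed. Attached endpoints are snapped to
#' their midpoint and made bit-identical, so consecutive segments share
#' endpoints exactly. The chain is closed when the two remaining free ends
#' fall within `offset_threshold` of each other (they are snapped too).
#' Zero-length segments produced by snapping are dropped.
#'
#' @param polys List of polylines (tibbles with columns `x`, `y`).
#' @param offset_threshold Maximum endpoint gap, in pixels, that is still
#'   considered a drawing misalignment rather than a genuine break.
#' @return A `sketch_chain`: a tibble with one row per segment (columns
#'   `seg`, `x0`, `y0`, `x1`, `y1`, `length`) and attributes `closed` and
#'   `total_length`.
#' @export
build_chain <- function(polys, offset_threshold = 5) {
  stopifnot(length(polys) >= 1, offset_threshold >= 0)
  pls <- lapply(polys, function(p) as.matrix(p[, c("x", "y")]))
  chain <- pls[[1]]
  remaining <- pls[-1]

  while (length(remaining)) {
    ends <- rbind(chain[1, ], chain[nrow(chain), ])  # start, end
    best <- NULL
    for (k in seq_along(remaining)) {
      p <- remaining[[k]]
      pe <- rbind(p[1, ], p[nrow(p), ])
      for (ce in 1:2) for (pp in 1:2) {
        d <- sqrt(sum((ends[ce, ] - pe[pp, ])^2))
        if (is.null(best) || d < best$d) best <- list(d = d, k = k, ce = ce, pp = pp)
      }
    }
    if (best$d > offset_threshold) {
      stop("branching or disconnected sketch", call. = FALSE)
    }
    p <- remaining[[best$k]]
    if (best$pp == 2L) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    # p now attaches by its first point
    if (best$ce == 2L) {
      mid <- (chain[nrow(chain), ] + p[1, ]) / 2
      chain[nrow(chain), ] <- mid
      p[1, ] <- mid
      chain <- rbind(chain, p[-1, , drop = FALSE])
    } else {
      mid <- (chain[1, ] + p[1, ]) / 2
      chain[1, ] <- mid
      p[1, ] <- mid
      chain <- rbind(p[rev(seq_len(nrow(p))), , drop = FALSE][-nrow(p), , drop = FALSE],
                     chain)
    }
    remaining <- remaining[-best$k]
  }

  closed <- FALSE
  n <- nrow(chain)
  if (n >= 3L) {
    gap <- sqrt(sum((chain[1, ] - chain[n, ])^2))
    if (gap <= offset_threshold) {
      mid <- (chain[1, ] + chain[n, ]) / 2
      chain[1, ] <- mid
      chain[n, ] <- mid
      closed <- TRUE
    }
  }

  new_chain(chain, closed)
}

# Construct a sketch_chain from ordered vertex points (m x 2 matrix).
new_chain <- function(pts, closed) {
  dimnames(pts) <- NULL
  keep <- c(TRUE, rowSums((pts[-1, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2) > 0)
  pts <- pts[keep, , drop = FALSE]
  n <- nrow(pts)
  if (n < 2L) stop("chain has no segments", call. = FALSE)
  seg <- tibble::tibble(
    seg = seq_len(n - 1L),
    x0 = pts[-n, 1], y0 = pts[-n, 2],
    x1 = pts[-1, 1], y1 = pts[-1, 2]
  )
  seg$length <- sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2)
  structure(
    seg,
    closed = closed,
    total_length = sum(seg$length),
    class = c("sketch_chain", class(seg))
  )
}

#' Is the chain a closed loop?
#' @param chain A `sketch_chain`.
#' @return Logical scalar.
#' @export
chain_closed <- function(chain) isTRUE(attr(chain, "closed"))

#' Total length of a chain in pixels
#' @param chain A `sketch_chain`.
#' @return Numeric scalar.
#' @export
chain_length <- function(chain) attr(chain, "total_length")

#' @export
print.sketch_chain <- function(x, ...) {
  cat(sprintf(
    "<sketch_chain> %d segment(s), %s, total length %.1f px\n",
    nrow(x), if (chain_closed(x)) "closed" else "open", chain_length(x)
  ))
  NextMethod()
}
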