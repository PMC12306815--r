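#' Simplify a polyline
#'
#' Two passes: a radial-distance pass drops points close to the previously
#' kept point (a cheap dedup of dense pixel chains), then
#' Ramer-Douglas-Peucker removes points whose distance to the local chord
#' stays small. The two deviations can compound, so the budget is split —
#' one third to the radial pass, two thirds to RDP — which guarantees that
#' every input point ends up within `tolerance` (perpendicular distance) of
#' the simplified polyline. First and last points are always preserved.
#'
#' @param poly A tibble/data frame with columns `x`, `y` and at least 2 rows.
#' @param tolerance Positive distance in pixels.
#' @return A tibble with columns `x`, `y`, at most as many rows as `poly`.
#' @export
simplify_polyline <- function(poly, tolerance) {
  stopifnot(tolerance > 0)
  pts <- as.matrix(poly[, c("x", "y")])
  n <- nrow(pts)
  stopifnot(n >= 2)
  pts <- pts[radial_keep(pts, tolerance / 3), , drop = FALSE]
  keep <- rdp_keep(pts, 2 * tolerance / 3)
  out <- pts[keep, , drop = FALSE]
  tibble::tibble(x = out[, 1], y = out[, 2])
}

# Radial distance pass: indices of points kept.
radial_keep <- function(pts, tol) {
  n <- nrow(pts)
  keep <- c(TRUE, rep(FALSE, n - 1L))
  last <- 1L
  tol2 <- tol^2
  for (i in seq_len(n)[-1]) {
    if (sum((pts[i, ] - pts[last, ])^2) > tol2) {
      keep[i] <- TRUE
      last <- i
    }
  }
  keep[n] <- TRUE
  keep
}

# Ramer-Douglas-Peucker on a point matrix; returns logical keep vector.
rdp_keep <- function(pts, tol) {
  n <- nrow(pts)
  keep <- rep(FALSE, n)
  keep[c(1L, n)] <- TRUE
  if (n <= 2L) return(keep)
  tol2 <- tol^2
  stack <- list(c(1L, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rng[1]
    j <- rng[2]
    if (j - i < 2L) next
    mid <- (i + 1L):(j - 1L)
    d2 <- point_segment_dist2(pts[mid, , drop = FALSE], pts[i, ], pts[j, ])
    k <- mid[which.max(d2)]
    if (max(d2) > tol2) {
      keep[k] <- TRUE
      stack <- c(stack, list(c(i, k)), list(c(k, j)))
    }
  }
  keep
}

# Squared distance from points (matrix) to segment a-b.
point_segment_dist2 <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(rowSums(sweep(p, 2, a)^2))
  t <- pmin(pmax((sweep(p, 2, a) %*% ab) / len2, 0), 1)
  proj <- cbind(a[1] + t * ab[1], a[2] + t * ab[2])
  rowSums((p - proj)^2)
}

#' Distance from points to a polyline (exhaustive)
#'
#' Maximum-deviation oracle: the distance from each point to the nearest
#' segment of `poly`, checking every segment.
#'
#' @param points Tibble/matrix with columns `x`, `y`.
#' @param poly Tibble with columns `x`, `y` (at least 2 points).
#' @return Numeric vector of distances, one per point.
#' @export
points_to_polyline_dist <- function(points, poly) {
  p <- as.matrix(points[, c("x", "y")])
  q <- as.matrix(poly[, c("x", "y")])
  best <- rep(Inf, nrow(p))
  for (i in seq_len(nrow(q) - 1L)) {
    best <- pmin(best, point_segment_dist2(p, q[i, ], q[i + 1L, ]))
  }
  sqrt(best)
}
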