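#' Trace a skeleton into polylines
#'
#' Walks 8-connected paths of a one-pixel-wide skeleton. Walks are seeded at
#' endpoint pixels (exactly one 8-neighbour); pixels left over afterwards
#' (pure cycles, or branches cut off at junctions) seed further walks. At a
#' true junction the walk continues along the branch that best preserves the
#' current heading; the remaining branches are traced as separate polylines
#' later. Thinning represents diagonals partly as 4-connected staircases, so
#' a diagonal neighbour that touches an orthogonal candidate is deferred
#' (the walk reaches it through the orthogonal pixel) and branching is
#' detected by the crossing number (three or more 0-to-1 transitions around
#' the neighbour ring), not by raw degree. Branching sketches are only
#' best-effort supported and trigger a warning.
#'
#' @param skeleton Logical matrix as produced by [thin()].
#' @return A list of polylines, each a tibble with columns `x`, `y`
#'   (pixel coordinates, origin top-left, y downward). A skeleton consisting
#'   only of isolated pixels yields an empty list with a warning.
#' @export
extract_polylines <- function(skeleton) {
  stopifnot(is.matrix(skeleton), is.logical(skeleton))
  if (!any(skeleton)) stop("cannot trace an empty skeleton", call. = FALSE)
  nr <- nrow(skeleton)
  idx <- which(skeleton)
  np <- length(idx)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  pos <- matrix(0L, nr, ncol(skeleton))
  pos[idx] <- seq_len(np)

  # Neighbour lists, orthogonal neighbours listed before diagonal ones.
  offs <- rbind(
    c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
    c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)
  )
  nbrs <- vector("list", np)
  for (p in seq_len(np)) {
    r2 <- row[p] + offs[, 1]
    c2 <- col[p] + offs[, 2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(skeleton)
    ok[ok] <- skeleton[cbind(r2[ok], c2[ok])]
    nbrs[[p]] <- pos[cbind(r2[ok], c2[ok])]
  }
  deg <- lengths(nbrs)
  if (any(crossing_number(skeleton)[idx] >= 3L)) {
    warning("skeleton has branch points; branching sketches are only ",
            "best-effort supported", call. = FALSE)
  }

  visited <- rep(FALSE, np)
  polys <- list()

  is_adjacent <- function(a, b) {
    max(abs(row[a] - row[b]), abs(col[a] - col[b])) == 1L
  }

  choose_next <- function(cur, path, cand) {
    ortho <- abs(row[cand] - row[cur]) + abs(col[cand] - col[cur]) == 1L
    if (any(ortho) && any(!ortho)) {
      # defer diagonal candidates reachable through an orthogonal one
      drop <- vapply(cand, function(d) {
        !ortho[match(d, cand)] &&
          any(vapply(cand[ortho], function(o) is_adjacent(d, o), logical(1)))
      }, logical(1))
      cand <- cand[!drop]
      ortho <- ortho[!drop]
    }
    score <- rep(0, length(cand))
    if (length(path) >= 2L) {
      prev <- path[length(path) - 1L]
      h <- c(col[cur] - col[prev], row[cur] - row[prev])
      h <- h / sqrt(sum(h^2))
      dvec <- cbind(col[cand] - col[cur], row[cand] - row[cur])
      dn <- dvec / sqrt(rowSums(dvec^2))
      score <- as.numeric(dn %*% h)
    }
    ord <- order(-round(score, 10), !ortho, cand)
    cand[ord[1]]
  }

  walk <- function(start) {
    path <- integer(0)
    cur <- start
    repeat {
      visited[cur] <<- TRUE
      path <- c(path, cur)
      cand <- nbrs[[cur]]
      cand <- cand[!visited[cand]]
      if (length(cand) == 0L) break
      cur <- if (length(cand) == 1L) cand else choose_next(cur, path, cand)
    }
    path
  }

  emit <- function(path) {
    if (length(path) < 2L) return()
    pts <- tibble::tibble(x = as.numeric(col[path]), y = as.numeric(row[path]))
    # close the loop when the walk returns next to its own start
    if (length(path) >= 3L && path[1] %in% nbrs[[path[length(path)]]]) {
      pts <- dplyr::bind_rows(pts, pts[1, ])
    }
    polys[[length(polys) + 1L]] <<- pts
  }

  # endpoint-seeded walks first
  for (s in which(deg == 1L)) {
    if (!visited[s]) emit(walk(s))
  }
  # leftovers: branches cut at junctions, then pure cycles
  repeat {
    un <- which(!visited)
    if (length(un) == 0L) break
    udeg <- vapply(un, function(p) sum(!visited[nbrs[[p]]]), integer(1))
    s <- if (any(udeg <= 1L)) un[which(udeg <= 1L)[1]] else un[1]
    if (deg[s] == 0L) {
      visited[s] <- TRUE  # isolated pixel: degenerate, no polyline
      next
    }
    emit(walk(s))
  }

  if (length(polys) == 0L) {
    warning("skeleton contains only isolated pixels; nothing to trace",
            call. = FALSE)
  }
  polys
}

# Crossing number per pixel: 0-to-1 transitions around the cyclic
# 8-neighbour ring. 1 = endpoint, 2 = path interior, >= 3 = branch point.
crossing_number <- function(m) {
  ring <- list(
    shift_mask(m, -1L, 0L), shift_mask(m, -1L, 1L), shift_mask(m, 0L, 1L),
    shift_mask(m, 1L, 1L), shift_mask(m, 1L, 0L), shift_mask(m, 1L, -1L),
    shift_mask(m, 0L, -1L), shift_mask(m, -1L, -1L)
  )
  a <- matrix(0L, nrow(m), ncol(m))
  for (i in 1:8) {
    a <- a + (!ring[[i]] & ring[[c(2:8, 1)[i]]])
  }
  a
}
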