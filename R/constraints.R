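#' Classify a segment's direction
#'
#' Eight compass-style labels. With `dx = x1 - x0`, `dy = y1 - y0` (y grows
#' downward): the segment is horizontal when `|dy/dx| < epsilon` (`l-r` for
#' `dx > 0`, else `r-l`), vertical when `|dx/dy| < epsilon` (`t-b` for
#' `dy > 0`, else `b-t`), and diagonal otherwise, with the label decided by
#' the sign pair (`tl-br`, `br-tl`, `tr-bl`, `bl-tr`). The slope threshold
#' absorbs hand-drawing wobble; for `epsilon < 1` the horizontal and
#' vertical tests are mutually exclusive.
#'
#' @param dx,dy Segment deltas in pixels (not both zero).
#' @param epsilon Slope threshold in (0, 1); default 0.2.
#' @return One of `"l-r"`, `"r-l"`, `"t-b"`, `"b-t"`, `"tl-br"`, `"br-tl"`,
#'   `"tr-bl"`, `"bl-tr"`.
#' @export
classify_direction <- function(dx, dy, epsilon = 0.2) {
  stopifnot(epsilon > 0, epsilon < 1)
  if (dx == 0 && dy == 0) stop("zero-length segment", call. = FALSE)
  if (dx != 0 && abs(dy / dx) < epsilon) {
    return(if (dx > 0) "l-r" else "r-l")
  }
  if (dy != 0 && abs(dx / dy) < epsilon) {
    return(if (dy > 0) "t-b" else "b-t")
  }
  if (dx > 0 && dy > 0) "tl-br"
  else if (dx < 0 && dy < 0) "br-tl"
  else if (dx < 0 && dy > 0) "tr-bl"
  else "bl-tr"
}

#' Classify every segment of a chain
#'
#' @param chain A `sketch_chain`.
#' @param epsilon Slope threshold, see [classify_direction()].
#' @return Character vector of labels, one per segment.
#' @export
classify_chain <- function(chain, epsilon = 0.2) {
  mapply(classify_direction,
         dx = chain$x1 - chain$x0, dy = chain$y1 - chain$y0,
         MoreArgs = list(epsilon = epsilon), USE.NAMES = FALSE)
}

# label -> does it have a horizontal (x) component, and which node is left?
# first element: q relative to v ("q_first" means constraint {left q, right v})
label_rules <- list(
  "l-r"   = list(h = "qv", v = NULL),
  "r-l"   = list(h = "vq", v = NULL),
  "t-b"   = list(h = NULL, v = "qv"),
  "b-t"   = list(h = NULL, v = "vq"),
  "tl-br" = list(h = "qv", v = "qv"),
  "br-tl" = list(h = "vq", v = "vq"),
  "tr-bl" = list(h = "vq", v = "qv"),
  "bl-tr" = list(h = "qv", v = "vq")
)

#' Generate placement constraints from a node-line mapping
#'
#' For each mapped node `v` with traversal predecessor `q = P(v)`, the
#' direction label of `v`'s segment decides the relative-placement
#' constraints: one horizontal or vertical constraint for axis-aligned
#' labels (e.g. `l-r` gives left `q`, right `v`), and one of each for
#' diagonal labels (e.g. `tl-br` gives left/right plus top/bottom).
#' Each horizontally labelled segment carrying at least two nodes also
#' emits one horizontal alignment over its node sequence, and vertical
#' segments likewise. A relative constraint that duplicates an earlier one
#' is skipped; one that would contradict earlier constraints (close a
#' directed cycle on its axis, possible when a closed chain's labels fold
#' back) is dropped with a warning — first come, first served.
#'
#' @param mapping A `node_line_mapping` from [distribute_nodes()].
#' @param labels Character vector of direction labels, one per chain
#'   segment (from [classify_chain()]).
#' @return A `constraint_set`: list with `relatives` (tibble `axis`,
#'   `first`, `second`; `first` is the left/top node) and `alignments`
#'   (tibble `axis`, `members` list-column).
#' @export
generate_constraints <- function(mapping, labels) {
  stopifnot(inherits(mapping, "node_line_mapping"))
  stopifnot(max(mapping$seg) <= length(labels))
  parent <- attr(mapping, "parent")

  acc <- constraint_accumulator()
  for (i in seq_len(nrow(mapping))) {
    v <- mapping$node[i]
    q <- parent[[v]]
    if (is.na(q) || q == v) next
    rule <- label_rules[[labels[mapping$seg[i]]]]
    if (!is.null(rule$h)) {
      if (rule$h == "qv") acc$add("horizontal", q, v) else acc$add("horizontal", v, q)
    }
    if (!is.null(rule$v)) {
      if (rule$v == "qv") acc$add("vertical", q, v) else acc$add("vertical", v, q)
    }
  }

  seg_nodes <- split(mapping$node, mapping$seg)
  align <- list()
  for (s in names(seg_nodes)) {
    nodes <- seg_nodes[[s]]
    if (length(nodes) < 2L) next
    lab <- labels[as.integer(s)]
    if (lab %in% c("l-r", "r-l")) {
      align[[length(align) + 1L]] <- list(axis = "horizontal", members = nodes)
    } else if (lab %in% c("t-b", "b-t")) {
      align[[length(align) + 1L]] <- list(axis = "vertical", members = nodes)
    }
  }
  alignments <- tibble::tibble(
    axis = vapply(align, `[[`, "", "axis"),
    members = lapply(align, `[[`, "members")
  )

  structure(list(relatives = acc$result(), alignments = alignments),
            class = "constraint_set")
}

# Accumulates relative constraints, rejecting duplicates silently and
# cycle-closing (contradictory) constraints with a warning.
constraint_accumulator <- function() {
  rows <- list()
  adj <- list(horizontal = new.env(parent = emptyenv()),
              vertical = new.env(parent = emptyenv()))
  reaches <- function(env, from, to) {
    # DFS: is `to` reachable from `from` along recorded edges?
    stack <- from
    seen <- character(0)
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (v == to) return(TRUE)
      if (v %in% seen) next
      seen <- c(seen, v)
      nxt <- if (exists(v, envir = env)) get(v, envir = env) else character(0)
      stack <- c(stack, nxt)
    }
    FALSE
  }
  list(
    add = function(axis, first, second) {
      env <- adj[[axis]]
      cur <- if (exists(first, envir = env)) get(first, envir = env) else character(0)
      if (second %in% cur) return(invisible())  # duplicate
      if (reaches(env, second, first)) {
        warning("dropping contradictory ", axis, " constraint ", first,
                " -> ", second, call. = FALSE)
        return(invisible())
      }
      assign(first, c(cur, second), envir = env)
      rows[[length(rows) + 1L]] <<- list(axis = axis, first = first, second = second)
      invisible()
    },
    result = function() {
      tibble::tibble(
        axis = vapply(rows, `[[`, "", "axis"),
        first = vapply(rows, `[[`, "", "first"),
        second = vapply(rows, `[[`, "", "second")
      )
    }
  )
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf("<constraint_set> %d relative constraint(s), %d alignment group(s)\n",
              nrow(x$relatives), nrow(x$alignments)))
  invisible(x)
}

#' Export a constraint set as fCoSE-style JSON
#'
#' Produces a JSON document with keys `relativePlacementConstraint` (a list
#' of `{left, right}` / `{top, bottom}` objects) and `alignmentConstraint`
#' (`{horizontal: [[...]], vertical: [[...]]}`), the option schema used by
#' constrained force-directed layout engines in the Cytoscape.js ecosystem.
#'
#' @param constraints A `constraint_set`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
constraints_to_json <- function(constraints, path = NULL) {
  rel <- lapply(seq_len(nrow(constraints$relatives)), function(i) {
    r <- constraints$relatives[i, ]
    if (r$axis == "horizontal") list(left = r$first, right = r$second)
    else list(top = r$first, bottom = r$second)
  })
  al <- constraints$alignments
  doc <- list(
    relativePlacementConstraint = rel,
    alignmentConstraint = list(
      horizontal = al$members[al$axis == "horizontal"],
      vertical = al$members[al$axis == "vertical"]
    )
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(as.character(json))
}

#' Parse a constraint-set JSON document
#'
#' Inverse of [constraints_to_json()].
#'
#' @param json A JSON string or path to a JSON file.
#' @return A `constraint_set`.
#' @export
constraints_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  rel <- doc$relativePlacementConstraint
  relatives <- tibble::tibble(
    axis = vapply(rel, function(r) if (!is.null(r$left)) "horizontal" else "vertical", ""),
    first = vapply(rel, function(r) if (!is.null(r$left)) r$left else r$top, ""),
    second = vapply(rel, function(r) if (!is.null(r$left)) r$right else r$bottom, "")
  )
  ah <- doc$alignmentConstraint$horizontal
  av <- doc$alignmentConstraint$vertical
  alignments <- tibble::tibble(
    axis = c(rep("horizontal", length(ah)), rep("vertical", length(av))),
    members = c(lapply(ah, unlist), lapply(av, unlist))
  )
  structure(list(relatives = relatives, alignments = alignments),
            class = "constraint_set")
}
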