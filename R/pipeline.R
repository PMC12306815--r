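#' Pipeline configuration
#'
#' Collects every tunable of the four-stage pipeline. Defaults: binarization
#' threshold 128, slope threshold `epsilon = 0.2`, cycle-acceptance factor
#' `tau_factor = 2` (applied to `sqrt(|V'|)`), simplification tolerance 5 px
#' at 512x512 (scaled proportionally with the image diagonal when `NULL`),
#' endpoint offset threshold 5 px.
#'
#' @param threshold Binarization cutoff in `[0, 255]`, or `"otsu"`.
#' @param epsilon Direction-classification slope threshold in (0, 1).
#' @param tau_factor Multiplier on `sqrt(|V'|)` for cycle acceptance.
#' @param simplify_tolerance Simplification tolerance in pixels, or `NULL`
#'   to scale 5 px with the image diagonal relative to 512x512.
#' @param offset_threshold Endpoint snapping threshold in pixels.
#' @param invert Treat bright pixels as strokes.
#' @param min_speck Minimum component size kept before thinning.
#' @param spur_length Maximum skeleton spur length pruned before tracing
#'   (see [prune_spurs()]).
#' @param canvas_scale Scale from image to layout coordinates.
#' @param keep_all_nodes Skip degree-one pruning (fallback for graphs with
#'   no multi-degree core).
#' @param layout A [layout_params()] list; its seed is overridden by `seed`.
#' @param seed Integer seed for every random choice in the pipeline.
#' @param verbose Emit per-stage messages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(threshold = 128, epsilon = 0.2, tau_factor = 2,
                            simplify_tolerance = NULL, offset_threshold = 5,
                            invert = FALSE, min_speck = 5, spur_length = 10,
                            canvas_scale = 1, keep_all_nodes = FALSE,
                            layout = layout_params(), seed = 1L,
                            verbose = FALSE) {
  layout$seed <- as.integer(seed)
  structure(list(threshold = threshold, epsilon = epsilon,
                 tau_factor = tau_factor,
                 simplify_tolerance = simplify_tolerance,
                 offset_threshold = offset_threshold, invert = invert,
                 min_speck = min_speck, spur_length = spur_length,
                 canvas_scale = canvas_scale,
                 keep_all_nodes = keep_all_nodes, layout = layout,
                 seed = as.integer(seed), verbose = verbose),
            class = "pipeline_config")
}

#' Extract the segment chain from a sketch image
#'
#' Stage one of the pipeline: binarize, thin to the skeleton, trace
#' polylines, simplify each, and assemble the ordered chain.
#'
#' @param image Intensity matrix (see [read_sketch()]).
#' @param config A [pipeline_config()].
#' @return A `sketch_chain`.
#' @export
extract_chain <- function(image, config = pipeline_config()) {
  mask <- binarize(image, threshold = config$threshold,
                   invert = config$invert, min_speck = config$min_speck)
  skel <- prune_spurs(thin(mask), iterations = config$spur_length)
  polys <- extract_polylines(skel)
  if (length(polys) == 0L) stop("blank sketch", call. = FALSE)
  tol <- config$simplify_tolerance
  if (is.null(tol)) {
    tol <- 5 * sqrt(nrow(image)^2 + ncol(image)^2) / sqrt(2 * 512^2)
  }
  simp <- lapply(polys, simplify_polyline, tolerance = tol)
  # residual tiny fragments (un-pruned spur remnants) cannot be part of one
  # coherent stroke; keep the substantial polylines
  if (length(simp) > 1L) {
    len <- vapply(simp, function(p) {
      sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
    }, numeric(1))
    keep <- len >= max(config$offset_threshold, tol) | len == max(len)
    if (!all(keep)) {
      warning(sum(!keep), " short fragment(s) discarded before chain ",
              "assembly", call. = FALSE)
      simp <- simp[keep]
    }
  }
  build_chain(simp, offset_threshold = config$offset_threshold)
}

#' Run the full sketch-guided layout pipeline
#'
#' Executes extraction, node-line mapping, constraint generation,
#' constrained layout and refinement. Inputs may be file paths (PNG sketch;
#' GraphML or edge-list graph) or in-memory objects.
#'
#' @param graph An igraph object or path to a GraphML / edge-list file.
#' @param sketch An intensity matrix or path to a PNG file.
#' @param config A [pipeline_config()].
#' @return A `sketch_pipeline` list: `layout` (refined `sketch_layout`),
#'   `constrained` (pre-refinement layout), `chain`, `mapping`,
#'   `constraints`, `labels`, and the effective `config`.
#' @export
run_pipeline <- function(graph, sketch, config = pipeline_config()) {
  if (is.character(graph)) graph <- read_graph_file(graph)
  if (is.character(sketch)) sketch <- read_sketch(sketch)
  say <- function(...) if (config$verbose) message(...)

  chain <- extract_chain(sketch, config)
  say(sprintf("chain: %d segment(s), %s, total length %.1f px", nrow(chain),
              if (chain_closed(chain)) "closed" else "open",
              chain_length(chain)))

  pruned <- prune_graph(graph, keep_all = config$keep_all_nodes)
  seq_ <- choose_sequence(pruned, chain, tau_factor = config$tau_factor,
                          seed = config$seed)
  say(sprintf("mapping: kind=%s over %d node(s)", seq_$kind,
              length(seq_$nodes)))
  mapping <- distribute_nodes(chain, seq_)
  anchors <- target_positions(chain, mapping, config$canvas_scale)

  labels <- classify_chain(chain, epsilon = config$epsilon)
  constraints <- generate_constraints(mapping, labels)
  say(sprintf("constraints: %d relative, %d alignment group(s)",
              nrow(constraints$relatives), nrow(constraints$alignments)))

  constrained <- constrained_layout(graph, constraints, anchors,
                                    params = config$layout)
  refined <- refine_layout(constrained)
  say(sprintf("layout: satisfied %.1f%% of constraints, fidelity %.3f",
              100 * mean(constrained$report$satisfied), refined$fidelity))

  structure(list(layout = refined, constrained = constrained, chain = chain,
                 mapping = mapping, constraints = constraints,
                 labels = labels, config = config),
            class = "sketch_pipeline")
}

#' @export
print.sketch_pipeline <- function(x, ...) {
  cat(sprintf("<sketch_pipeline> kind=%s | ", attr(x$mapping, "kind")))
  print(x$layout)
  invisible(x)
}

#' Read a graph from GraphML or edge-list file
#'
#' Files ending in `.graphml`/`.xml` are parsed as GraphML; anything else
#' as a whitespace/tab-delimited two-column edge list (lines starting with
#' `#` are skipped, node ids are opaque strings). Directedness is kept on
#' the object but the mapping stages treat the graph as undirected.
#'
#' @param path Path to the graph file.
#' @return An igraph object with named vertices.
#' @export
read_graph_file <- function(path) {
  if (!file.exists(path)) stop("graph file not found: ", path, call. = FALSE)
  if (grepl("\\.(graphml|xml)$", path, ignore.case = TRUE)) {
    g <- igraph::read_graph(path, format = "graphml")
    if (is.null(igraph::V(g)$name)) {
      id <- igraph::vertex_attr(g, "id")
      igraph::V(g)$name <- if (!is.null(id)) as.character(id) else
        as.character(seq_len(igraph::vcount(g)))
    }
    return(g)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  edges <- matrix(character(0), 0, 2)
  for (i in which(keep)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 2L) {
      stop("malformed edge-list record at line ", i, " of ", path,
           call. = FALSE)
    }
    edges <- rbind(edges, tok)
  }
  if (nrow(edges) == 0L) stop("no edges in ", path, call. = FALSE)
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

#' Write layout outputs
#'
#' Writes node positions as JSON (`{"id": {"x": ..., "y": ...}, ...}`,
#' full precision) and optionally GraphML with `x`/`y` vertex attributes
#' and a simple SVG rendering (image coordinates, y downward).
#'
#' @param result A `sketch_layout` or `sketch_pipeline`.
#' @param path Output path for the positions JSON.
#' @param graphml Optional path for GraphML with coordinates.
#' @param svg Optional path for an SVG rendering.
#' @return `invisible(NULL)`.
#' @export
write_layout <- function(result, path, graphml = NULL, svg = NULL) {
  if (inherits(result, "sketch_pipeline")) result <- result$layout
  stopifnot(inherits(result, "sketch_layout"))
  pos <- result$positions
  doc <- stats::setNames(
    lapply(seq_len(nrow(pos)), function(i) list(x = pos$x[i], y = pos$y[i])),
    pos$node
  )
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  if (!is.null(graphml)) {
    g <- result$graph
    igraph::V(g)$x <- pos$x[match(igraph::V(g)$name, pos$node)]
    igraph::V(g)$y <- pos$y[match(igraph::V(g)$name, pos$node)]
    igraph::write_graph(g, graphml, format = "graphml")
  }
  if (!is.null(svg)) write_layout_svg(result, svg)
  invisible(NULL)
}

#' Read a positions JSON written by [write_layout()]
#'
#' @param path Path to the JSON file.
#' @return Tibble with columns `node`, `x`, `y`.
#' @export
read_layout_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tibble::tibble(
    node = names(doc),
    x = vapply(doc, function(p) as.numeric(p$x), numeric(1), USE.NAMES = FALSE),
    y = vapply(doc, function(p) as.numeric(p$y), numeric(1), USE.NAMES = FALSE)
  )
}

# Minimal SVG rendering: edges as lines, nodes as circles, y downward.
write_layout_svg <- function(result, path, node_radius = 4) {
  pos <- result$positions
  pad <- 4 * node_radius
  x0 <- min(pos$x) - pad
  y0 <- min(pos$y) - pad
  w <- diff(range(pos$x)) + 2 * pad
  h <- diff(range(pos$y)) + 2 * pad
  em <- igraph::as_edgelist(result$graph)
  ix <- match(em[, 1], pos$node)
  jx <- match(em[, 2], pos$node)
  lines <- sprintf(
    '<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="#888" stroke-width="1"/>',
    pos$x[ix] - x0, pos$y[ix] - y0, pos$x[jx] - x0, pos$y[jx] - y0
  )
  circles <- sprintf(
    '<circle cx="%.2f" cy="%.2f" r="%g" fill="#2166ac"/>',
    pos$x - x0, pos$y - y0, node_radius
  )
  writeLines(c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f" viewBox="0 0 %.2f %.2f">',
            w, h, w, h),
    '<rect width="100%" height="100%" fill="white"/>',
    lines, circles, "</svg>"
  ), path)
  invisible(NULL)
}

#' Write an intensity matrix as a PNG
#'
#' @param image Intensity matrix in `[0, 255]`.
#' @param path Output PNG path.
#' @return `invisible(NULL)`.
#' @export
write_sketch_png <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(NULL)
}
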