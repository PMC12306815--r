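#' Read a sketch image from a PNG file
#'
#' Reads a grayscale or RGB PNG and returns an intensity matrix in
#' `[0, 255]`, rows indexing y (top to bottom) and columns indexing x.
#' RGB images are converted by the usual luminance weights
#' (0.299 R + 0.587 G + 0.114 B); an alpha channel, if present, is
#' composited over white.
#'
#' @param path Path to a PNG file.
#' @return A numeric matrix of intensities in `[0, 255]`.
#' @export
read_sketch <- function(path) {
  if (!file.exists(path)) {
    stop("sketch file not found: ", path, call. = FALSE)
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    gray <- img
  } else {
    nc <- dim(img)[3]
    if (nc >= 3L) {
      gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      gray <- img[, , 1]
    }
    if (nc %in% c(2L, 4L)) {
      alpha <- img[, , nc]
      gray <- gray * alpha + (1 - alpha)
    }
  }
  round(gray * 255)
}

#' Binarize an intensity image
#'
#' Dark strokes on a light background: a pixel is foreground when its
#' intensity is strictly below `threshold`. Set `invert = TRUE` for
#' light-on-dark sketches. With `threshold = "otsu"` the threshold is chosen
#' automatically by Otsu's between-class variance criterion.
#'
#' @param image Numeric intensity matrix in `[0, 255]`.
#' @param threshold Intensity cutoff in `[0, 255]`, or `"otsu"`.
#' @param invert If `TRUE`, treat bright pixels as foreground.
#' @param min_speck Connected foreground components (8-connectivity) with
#'   fewer pixels than this are discarded as noise. Set to 0 to keep all.
#' @return A logical matrix, `TRUE` = foreground.
#' @export
binarize <- function(image, threshold = 128, invert = FALSE, min_speck = 5) {
  stopifnot(is.matrix(image), nrow(image) >= 1, ncol(image) >= 1)
  if (invert) image <- 255 - image
  if (identical(threshold, "otsu")) threshold <- otsu_threshold(image)
  stopifnot(is.numeric(threshold), threshold >= 0, threshold <= 255)
  mask <- image < threshold
  if (min_speck > 0 && any(mask)) {
    lab <- label_components8(mask)
    sizes <- tabulate(lab[mask])
    keep <- which(sizes >= min_speck)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  if (!any(mask)) stop("blank sketch", call. = FALSE)
  mask
}

# Otsu's method on a 256-bin histogram of rounded intensities.
otsu_threshold <- function(image) {
  h <- tabulate(pmin(pmax(round(image), 0), 255) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) - 1L  # threshold t: foreground is intensity < t
}

#' Label 8-connected components of a logical mask
#'
#' @param mask Logical matrix.
#' @return Integer matrix of component labels (0 for background).
#' @noRd
label_components8 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  # Edges to E, S, SE, SW neighbours cover all 8-adjacencies once.
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  edges <- list()
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  pos <- matrix(0L, nr, nc)
  pos[idx] <- seq_along(idx)
  for (o in offs) {
    r2 <- row + o[1]
    c2 <- col + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    if (any(ok)) {
      edges[[length(edges) + 1L]] <-
        cbind(pos[idx[ok]], pos[cbind(r2[ok], c2[ok])])
    }
  }
  em <- if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(em)) g <- igraph::add_edges(g, t(em))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Count 8-connected components of a logical mask
#' @noRd
count_components8 <- function(mask) {
  if (!any(mask)) return(0L)
  max(label_components8(mask))
}

#' Foreground pixel coordinates of a mask
#'
#' @param mask Logical matrix.
#' @return A tibble with integer columns `x` (column) and `y` (row).
#' @export
foreground_pixels <- function(mask) {
  rc <- which(mask, arr.ind = TRUE)
  tibble::tibble(x = as.integer(rc[, 2]), y = as.integer(rc[, 1]))
}
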