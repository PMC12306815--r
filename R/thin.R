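#' Zhang-Suen thinning
#'
#' Reduces a binary image to a one-pixel-wide skeleton with the classic
#' two-subiteration Zhang-Suen scheme, iterated to a fixed point. A border
#' pixel is deleted when its 8-neighbourhood has between 2 and 6 foreground
#' pixels, exactly one 0-to-1 transition around the cyclic neighbour
#' sequence, and satisfies the subiteration's two deletion products
#' (first pass: north/east/south and east/south/west; second pass:
#' north/east/west and north/south/west). The result is idempotent and
#' preserves 8-connected component count.
#'
#' @param mask Logical matrix, `TRUE` = foreground; must be non-empty.
#' @return Logical matrix of the same shape, the thinning fixed point.
#' @export
thin <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("cannot thin an empty image", call. = FALSE)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      del <- zs_deletable(mask, pass)
      if (any(del)) {
        del <- protect_components(mask, del)
        mask[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  mask
}

# The textbook scheme deletes 2x2 blocks (and blobs that collapse to them)
# entirely, which would drop a connected component. Keep the first pixel of
# any component that a simultaneous deletion pass would erase completely.
protect_components <- function(mask, del) {
  lab <- label_components8(mask)
  gone <- setdiff(unique(lab[mask]), unique(lab[mask & !del]))
  for (k in gone) {
    del[which(lab == k)[1]] <- FALSE
  }
  del
}

#' Prune short skeleton spurs
#'
#' Morphological pruning: endpoint pixels (exactly one 8-neighbour) are
#' deleted simultaneously, `iterations` times. Burns away branch spurs up
#' to that length — an artefact of thinning wobbly strokes — while leaving
#' closed loops untouched; open strokes lose at most `iterations` pixels at
#' each genuine end.
#'
#' @param skeleton Logical matrix from [thin()].
#' @param iterations Maximum spur length removed, in pixels.
#' @return Logical matrix. If pruning would empty the image the last
#'   non-empty state is returned.
#' @export
prune_spurs <- function(skeleton, iterations = 10) {
  m <- skeleton
  for (i in seq_len(iterations)) {
    nb <- neighbor_count(m)
    ends <- m & nb == 1L
    if (!any(ends)) break
    nxt <- m & !ends
    if (!any(nxt)) break
    m <- nxt
  }
  m
}

# Number of foreground 8-neighbours per pixel.
neighbor_count <- function(m) {
  shift_mask(m, -1L, 0L) + shift_mask(m, -1L, 1L) + shift_mask(m, 0L, 1L) +
    shift_mask(m, 1L, 1L) + shift_mask(m, 1L, 0L) + shift_mask(m, 1L, -1L) +
    shift_mask(m, 0L, -1L) + shift_mask(m, -1L, -1L)
}

# Shift a logical matrix so out[r, c] = m[r + dr, c + dc] (FALSE outside).
shift_mask <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 - dr):min(nr, nr - dr)
  cs <- max(1, 1 - dc):min(nc, nc - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

# Deletable pixels for one Zhang-Suen subiteration, fully vectorized.
zs_deletable <- function(m, pass) {
  p2 <- shift_mask(m, -1L, 0L)   # N
  p3 <- shift_mask(m, -1L, 1L)   # NE
  p4 <- shift_mask(m, 0L, 1L)    # E
  p5 <- shift_mask(m, 1L, 1L)    # SE
  p6 <- shift_mask(m, 1L, 0L)    # S
  p7 <- shift_mask(m, 1L, -1L)   # SW
  p8 <- shift_mask(m, 0L, -1L)   # W
  p9 <- shift_mask(m, -1L, -1L)  # NW
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  seq_ <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  a <- matrix(0L, nrow(m), ncol(m))
  for (i in 1:8) a <- a + (!seq_[[i]] & seq_[[i + 1]])
  cond <- m & b >= 2 & b <= 6 & a == 1
  if (pass == 1L) {
    cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
  } else {
    cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
  }
}
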