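#' Gray-level statistics of a head crop
#'
#' `G` is the summed intensity over in-mask pixels, `n` the pixel count and
#' `P = 1 - G / (255 n)` the darkness fraction: 1 for an all-black head,
#' 0 for an all-white one.
#'
#' @param crop a `sperm_crop` (or `list(image, mask)`).
#' @return `list(G, n, P)` of class `gray_stats`.
#' @export
gray_stats <- function(crop) {
  if (!any(crop$mask)) stopf("empty mask")
  g <- as.numeric(crop$image[crop$mask])
  G <- sum(g)
  n <- length(g)
  structure(list(G = G, n = n, P = 1 - G / (n * 255)), class = "gray_stats")
}

#' @export
print.gray_stats <- function(x, ...) {
  cat(sprintf("<gray_stats> G=%g over n=%d px, darkness P=%.4f\n", x$G, x$n, x$P))
  invisible(x)
}

# Ordered square-spiral steps on the unbounded lattice, starting at (0, 0):
# run lengths 1,1,2,2,3,3,... with turn order +row, +col, -row, -col.
# Returns a (>= n)-row matrix of (drow, dcol) offsets, (0, 0) first.
spiral_offsets_unbounded <- function(n_steps) {
  dirs <- rbind(c(1L, 0L), c(0L, 1L), c(-1L, 0L), c(0L, -1L))
  offs <- matrix(0L, 1L, 2L)
  run <- 0L
  d <- 0L
  while (nrow(offs) < n_steps) {
    d <- d + 1L
    if (d %% 2L == 1L) run <- run + 1L
    dir <- dirs[((d - 1L) %% 4L) + 1L, ]
    last <- offs[nrow(offs), ]
    steps <- cbind(last[1] + dir[1] * seq_len(run),
                   last[2] + dir[2] * seq_len(run))
    offs <- rbind(offs, steps)
  }
  offs
}

#' Square-spiral extraction path over a grid
#'
#' The "roundabout" path along which gray values are read: it starts at the
#' grid centre, steps first toward larger row index, then turns toward
#' larger column index, with run lengths 1, 1, 2, 2, 3, 3, ... and turn
#' order +row, +col, -row, -col. Cells that fall outside the grid are
#' skipped without consuming an index, so every grid cell receives exactly
#' one path index.
#'
#' @param extent `c(height, width)` of the grid, both >= 1.
#' @return a `spiral_path`: `list(offsets, start, extent)` where `offsets`
#'   is an n x 2 matrix of (drow, dcol) relative to the start cell, in path
#'   order (row 1 is `c(0, 0)`), and `start = c(row, col)` is the 1-based
#'   centre cell.
#' @export
spiral_path <- function(extent) {
  h <- extent[1]; w <- extent[2]
  if (!is_count(h) || !is_count(w) || h < 1 || w < 1) {
    stopf("extent must be two positive integers")
  }
  start <- as.integer(c(ceiling(h / 2), ceiling(w / 2)))
  n_cells <- as.integer(h * w)
  # a spiral of side 2s+1 covers any start-anchored h x w grid once
  s <- max(h, w)
  offs <- spiral_offsets_unbounded((2L * s + 3L)^2)
  rows <- start[1] + offs[, 1]
  cols <- start[2] + offs[, 2]
  keep <- rows >= 1L & rows <= h & cols >= 1L & cols <= w
  offs <- offs[keep, , drop = FALSE][seq_len(n_cells), , drop = FALSE]
  structure(list(offsets = offs, start = start, extent = c(h, w)),
            class = "spiral_path")
}

#' Spiral index grid
#'
#' Renders a [spiral_path()] as the matrix of path indices: cell `(r, c)`
#' holds the position at which the spiral visits it. For an 8 x 8 grid this
#' reproduces the printed extraction-path map cell for cell.
#'
#' @param extent `c(height, width)`.
#' @return integer matrix of path indices `1 .. height * width`.
#' @export
spiral_index_grid <- function(extent) {
  sp <- spiral_path(extent)
  grid <- matrix(0L, extent[1], extent[2])
  rows <- sp$start[1] + sp$offsets[, 1]
  cols <- sp$start[2] + sp$offsets[, 2]
  grid[cbind(rows, cols)] <- seq_len(nrow(sp$offsets))
  grid
}

#' Gray values along the spiral until the path hits the contour
#'
#' Walks the square spiral outward from the head centre and collects gray
#' values of the visited pixels. Cells outside the crop grid are skipped
#' (the grid merely truncates the path); the walk terminates at the first
#' in-grid cell outside the mask — where the path "collides with the
#' contour".
#'
#' @param crop a `sperm_crop`.
#' @param start `"mask-centroid"` (default: the rounded centroid of the mask
#'   pixels, moved to the nearest in-mask pixel if the mask is non-convex)
#'   or an explicit in-mask `c(row, col)`.
#' @return numeric vector of gray values, length >= 1.
#' @export
spiral_gray_sequence <- function(crop, start = "mask-centroid") {
  h <- nrow(crop$image); w <- ncol(crop$image)
  if (identical(start, "mask-centroid")) {
    idx <- which(crop$mask, arr.ind = TRUE)
    ctr <- round(colMeans(idx))
    if (ctr[1] >= 1 && ctr[1] <= h && ctr[2] >= 1 && ctr[2] <= w &&
        crop$mask[ctr[1], ctr[2]]) {
      start <- ctr
    } else {
      d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
      start <- idx[which.min(d2), ]
    }
  } else {
    start <- as.integer(start)
    if (start[1] < 1 || start[1] > h || start[2] < 1 || start[2] > w ||
        !crop$mask[start[1], start[2]]) {
      stopf("spiral start (%d, %d) is outside the mask", start[1], start[2])
    }
  }
  s <- max(h, w)
  offs <- spiral_offsets_unbounded((2L * s + 3L)^2)
  rows <- start[1] + offs[, 1]
  cols <- start[2] + offs[, 2]
  in_grid <- rows >= 1L & rows <= h & cols >= 1L & cols <= w
  rows <- rows[in_grid]; cols <- cols[in_grid]
  lin <- cbind(rows, cols)
  in_mask <- crop$mask[lin]
  stop_at <- which(!in_mask)[1]
  take <- if (is.na(stop_at)) seq_along(rows) else seq_len(stop_at - 1L)
  as.numeric(crop$image[lin[take, , drop = FALSE]])
}
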