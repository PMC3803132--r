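#' Trace the closed boundary of a head mask
#'
#' Moore-neighbour boundary tracing with Jacob's stopping criterion,
#' starting at the top-most then left-most boundary pixel and walking
#' clockwise in image coordinates (row 1 at top). The result is an ordered,
#' closed list of boundary pixels of the single connected component.
#'
#' @param mask logical matrix: one 8-connected component with at least 8
#'   boundary pixels.
#' @return a `contour`: `list(points)` where `points` is an n x 2 integer
#'   matrix of (row, col) coordinates; the successor of the last point is
#'   the first.
#' @export
trace_contour <- function(mask) {
  if (sum(mask) < 4L) stopf("degenerate mask: too few pixels for a contour")
  labs <- label_components(mask)
  if (max(labs) != 1L) stopf("mask must contain exactly one component")

  h <- nrow(mask); w <- ncol(mask)
  inside <- function(r, c) r >= 1L && r <= h && c >= 1L && c <= w && mask[r, c]

  # clockwise Moore neighbourhood (image coords, row grows downward)
  moves <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                 c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  dir_of <- matrix(0L, 3L, 3L)   # dir_of[dr + 2, dc + 2] -> move index
  for (k in 1:8) dir_of[moves[k, 1] + 2L, moves[k, 2] + 2L] <- k

  idx <- which(mask, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  start <- idx[ord[1], ]                     # top-most, then left-most

  pts <- matrix(0L, 0L, 2L)
  cur <- start
  # came "from" the west neighbour, which is background by start choice
  from_dir <- 7L
  start_from <- from_dir
  repeat {
    pts <- rbind(pts, cur)
    found <- FALSE
    d <- from_dir
    for (step in seq_len(8L)) {
      d <- (d %% 8L) + 1L
      r <- cur[1] + moves[d, 1]; c <- cur[2] + moves[d, 2]
      if (inside(r, c)) {
        # backtrack = the (background) ring cell examined just before d;
        # recompute its direction as seen from the new current pixel
        prev <- ((d - 2L) %% 8L) + 1L
        rel <- moves[prev, ] - moves[d, ]
        nxt_from <- dir_of[rel[1] + 2L, rel[2] + 2L]
        nxt <- c(r, c)
        found <- TRUE
        break
      }
    }
    if (!found) break                         # isolated region smaller than trace
    # Jacob's criterion: closed when start is re-entered the same way
    if (nxt[1] == start[1] && nxt[2] == start[2] && nxt_from == start_from) break
    # fallback for spur-start masks whose initial entry state never recurs:
    # the walk is cyclic once the start -> second transition repeats
    if (nrow(pts) >= 2L && cur[1] == start[1] && cur[2] == start[2] &&
        nxt[1] == pts[2, 1] && nxt[2] == pts[2, 2]) {
      pts <- pts[-nrow(pts), , drop = FALSE]   # drop the duplicated start
      break
    }
    cur <- nxt
    from_dir <- nxt_from
    if (nrow(pts) > 8L * sum(mask)) stopf("contour trace failed to close")
  }
  if (nrow(pts) < 8L) stopf("degenerate mask: contour has fewer than 8 points")
  dimnames(pts) <- NULL
  structure(list(points = pts), class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %d points, start (%d, %d)\n",
              nrow(x$points), x$points[1, 1], x$points[1, 2]))
  invisible(x)
}

#' Geometric centre of a contour
#'
#' Arithmetic mean of the boundary point coordinates (edge points only;
#' interior pixels do not enter).
#'
#' @param contour a `contour`.
#' @return `c(row, col)` of the centroid (real-valued).
#' @export
contour_centroid <- function(contour) {
  colMeans(contour$points)
}

new_waveform <- function(values, source) {
  structure(list(values = as.numeric(values), source = source),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> source=%s, length %d, range [%.2f, %.2f]\n",
              x$source, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Centroid-to-edge distance waveform
#'
#' One value per contour point, in traversal order: the Euclidean distance
#' from the geometric centre to that boundary point. The sequence is
#' circular. This is the descriptor used for classification (it avoids the
#' starting-point sensitivity of the symmetry-pair method).
#'
#' @param contour a `contour`.
#' @param center optional centroid `c(row, col)`; defaults to
#'   [contour_centroid()].
#' @return a `waveform` with `source = "centroid-distance"`.
#' @export
distance_waveform <- function(contour, center = NULL) {
  if (is.null(center)) center <- contour_centroid(contour)
  d <- sqrt((contour$points[, 1] - center[1])^2 +
            (contour$points[, 2] - center[2])^2)
  new_waveform(d, "centroid-distance")
}

#' Bilateral symmetry score of every candidate axis anchor
#'
#' For each contour index `n`, compares the two arcs on either side of the
#' candidate axis through that point: the score is the absolute difference
#' between the summed squared distances from the anchor to the paired arc
#' samples `n + j` and `n - j`. A contour mirror-symmetric about the axis
#' through `n` scores 0; lower is more symmetric.
#'
#' @param contour a `contour` with at least 8 points.
#' @return numeric vector, one score per anchor index.
#' @export
symmetry_scores <- function(contour) {
  pts <- contour$points
  L <- nrow(pts)
  if (L < 8L) stopf("contour too short for symmetry scoring")
  half <- (L - 1L) %/% 2L
  scores <- numeric(L)
  d2 <- function(i, n) (pts[i, 1] - pts[n, 1])^2 + (pts[i, 2] - pts[n, 2])^2
  j <- seq_len(half)
  for (n in seq_len(L)) {
    fwd <- wrap_index(n + j, L)
    bwd <- wrap_index(n - j, L)
    scores[n] <- abs(sum(d2(fwd, n)) - sum(d2(bwd, n)))
  }
  scores
}

#' Symmetry percentage of a waveform about a pairing index
#'
#' `1 - sum(|A(i) - A(2k - i)|) / sum(2 * sqrt(A(i) * A(2k - i)))` with
#' indices taken modulo the sequence length (the sequence is circular).
#' Equals 1 exactly when the sequence is symmetric about `k`; always <= 1.
#'
#' @param A a `waveform` or positive numeric vector (circular).
#' @param k pairing index (1-based).
#' @return scalar symmetry percentage.
#' @export
percent_sym <- function(A, k) {
  v <- if (inherits(A, "waveform")) A$values else as.numeric(A)
  L <- length(v)
  if (L < 2L) stopf("waveform too short")
  i <- seq_len(L)
  p <- wrap_index(2L * k - i, L)
  prod_pairs <- v[i] * v[p]
  if (any(prod_pairs <= 0)) {
    stopf("percent_sym undefined: zero-valued pair encountered")
  }
  1 - sum(abs(v[i] - v[p])) / sum(2 * sqrt(prod_pairs))
}

#' Symmetric-pair distance waveform
#'
#' Finds the most symmetric axis anchor `k` (global minimum of
#' [symmetry_scores()], ties broken by the lowest index) and emits the
#' Euclidean distances between the paired contour points `k + j` and
#' `k - j` for `j = 0 .. floor(L/2)`. Unlike the centroid-distance
#' waveform, this descriptor depends on where the contour trace starts,
#' which is why classification uses the centroid method.
#'
#' @param contour a `contour`.
#' @param k optional anchor index; defaults to the best symmetry anchor.
#' @return a `waveform` with `source = "symmetry"`.
#' @export
symmetry_waveform <- function(contour, k = NULL) {
  pts <- contour$points
  L <- nrow(pts)
  if (is.null(k)) k <- which.min(symmetry_scores(contour))
  j <- 0:(L %/% 2L)
  a <- wrap_index(k + j, L)
  b <- wrap_index(k - j, L)
  d <- sqrt((pts[a, 1] - pts[b, 1])^2 + (pts[a, 2] - pts[b, 2])^2)
  new_waveform(d, "symmetry")
}

#' Serialize waveforms to CSV
#'
#' @param waveforms list of `waveform` objects.
#' @param path output CSV path.
#' @param ids optional sperm identifiers (default sequence).
#' @return the data frame written, invisibly.
#' @export
write_waveforms <- function(waveforms, path, ids = seq_along(waveforms)) {
  rows <- lapply(seq_along(waveforms), function(i) {
    w <- waveforms[[i]]
    data.frame(sperm_id = ids[i], index = seq_along(w$values) - 1L,
               value = w$values, source = w$source)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
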