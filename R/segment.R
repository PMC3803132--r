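#' Otsu's automatic threshold
#'
#' Maximizes between-class variance of the 256-bin intensity histogram.
#' Returns the threshold `t` such that pixels with intensity `< t` are
#' foreground under [threshold_segment()]'s darker-than rule.
#'
#' @param values integer intensities in `[0, 255]`.
#' @return scalar threshold in `[0, 255]`.
#' @export
otsu_threshold <- function(values) {
  counts <- tabulate(as.integer(values) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  omega <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t_star <- levels[which.max(sigma_b)]
  # histogram split keeps bin t_star in the dark class; "< t" rule needs +1
  t_star + 1
}

#' Background-mode automatic threshold
#'
#' Robust automatic threshold for micrographs whose background dominates
#' the histogram: the background level is the modal intensity, its noise
#' scale a MAD estimate over near-mode pixels, and the threshold sits
#' `6 * sigma` (at least 10 gray levels) below the mode. Unlike Otsu's
#' method this stays close to the background even when the foreground is a
#' small multi-modal fraction of the pixels, so pale heads are kept.
#'
#' @param values integer intensities in `[0, 255]`.
#' @return scalar threshold.
#' @export
background_threshold <- function(values) {
  v <- as.integer(values)
  counts <- tabulate(v + 1L, nbins = 256L)
  mode_val <- which.max(counts) - 1L
  near <- v[abs(v - mode_val) <= 20L]
  sigma <- 1.4826 * stats::median(abs(near - mode_val))
  max(1, mode_val - max(6 * sigma, 10))
}

#' Threshold segmentation of a micrograph
#'
#' Marks pixels strictly darker than the threshold as foreground, optionally
#' restricted to one or more rectangular regions of interest (the automated
#' stand-in for manually picking non-overlapping areas). Automatic
#' thresholds are computed from the intensity histogram of the ROI union:
#' `"auto"` (the default) uses [background_threshold()], which tolerates a
#' small multi-modal foreground; `"otsu"` uses [otsu_threshold()].
#'
#' @param image a `gray_image` or numeric matrix in `[0, 255]`.
#' @param roi `NULL` (whole image) or a list of boxes `c(r1, c1, r2, c2)`
#'   (1-based, inclusive).
#' @param threshold numeric cut in `[0, 255]`, `"auto"`, or `"otsu"`.
#' @return logical matrix; `TRUE` = foreground. Pixels outside every ROI are
#'   always background.
#' @export
threshold_segment <- function(image, roi = NULL, threshold = "auto") {
  image <- as_gray_image(image)
  roi_mask <- matrix(TRUE, nrow(image), ncol(image))
  if (!is.null(roi)) {
    if (length(roi) == 0L) stopf("roi list is empty")
    roi_mask[] <- FALSE
    for (b in roi) {
      if (length(b) != 4L || b[1] > b[3] || b[2] > b[4] ||
          b[1] < 1 || b[2] < 1 || b[3] > nrow(image) || b[4] > ncol(image)) {
        stopf("invalid ROI box [%s]", paste(b, collapse = ", "))
      }
      roi_mask[b[1]:b[3], b[2]:b[4]] <- TRUE
    }
  }
  if (identical(threshold, "auto")) {
    threshold <- background_threshold(image[roi_mask])
  } else if (identical(threshold, "otsu")) {
    threshold <- otsu_threshold(image[roi_mask])
  } else if (!is.numeric(threshold) || threshold < 0 || threshold > 255) {
    stopf("threshold must be in [0, 255], \"auto\" or \"otsu\"")
  }
  image < threshold & roi_mask
}

# 8-connected component labelling by vectorised BFS over foreground pixels.
# Returns an integer matrix (0 = background) with labels in first-pixel
# (column-major) discovery order.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  fg <- which(mask)
  if (!length(fg)) return(labels)
  nbr <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
  # row wrap guard: neighbour offsets that change the row by +-1
  drow <- c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L)
  n_px <- h * w
  next_label <- 0L
  for (s in fg) {
    if (labels[s] != 0L) next
    next_label <- next_label + 1L
    labels[s] <- next_label
    frontier <- s
    while (length(frontier)) {
      cand <- rep(frontier, each = 8L) + nbr
      rows <- ((rep(frontier, each = 8L) - 1L) %% h) + 1L + drow
      ok <- cand >= 1L & cand <= n_px & rows >= 1L & rows <= h
      cand <- unique(cand[ok])
      cand <- cand[mask[cand] & labels[cand] == 0L]
      labels[cand] <- next_label
      frontier <- cand
    }
  }
  labels
}

#' Extract connected components from a binary mask
#'
#' 8-connected components with at least `min_area` pixels, sorted by the
#' top-left corner of their bounding boxes in row-major order (row first,
#' then column).
#'
#' @param mask logical matrix.
#' @param min_area minimum component area in pixels (`>= 1`).
#' @return list of components, each `list(mask, bbox)` where `mask` is the
#'   bounding-box crop (logical, exactly one component) and
#'   `bbox = c(r1, c1, r2, c2)`.
#' @export
extract_components <- function(mask, min_area = 1) {
  if (!is_count(min_area) || min_area < 1) stopf("min_area must be >= 1")
  labels <- label_components(mask)
  n_lab <- max(labels)
  if (n_lab == 0L) return(list())
  comps <- list()
  for (l in seq_len(n_lab)) {
    idx <- which(labels == l, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    bbox <- c(min(idx[, 1]), min(idx[, 2]), max(idx[, 1]), max(idx[, 2]))
    sub <- labels[bbox[1]:bbox[3], bbox[2]:bbox[4], drop = FALSE] == l
    comps[[length(comps) + 1L]] <- list(mask = sub, bbox = bbox)
  }
  if (!length(comps)) return(list())
  ord <- order(vapply(comps, function(x) x$bbox[1], 0),
               vapply(comps, function(x) x$bbox[2], 0))
  comps[ord]
}

disc_offsets <- function(radius) {
  d <- -radius:radius
  g <- expand.grid(dr = d, dc = d)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

# Pad, then AND (erode) or OR (dilate) over all disc shifts.
erode_disc <- function(mask, radius) {
  offs <- disc_offsets(radius)
  out <- mask
  for (i in seq_len(nrow(offs))) {
    out <- out & shift_matrix(mask, -offs$dr[i], -offs$dc[i], fill = FALSE)
    if (!any(out)) break
  }
  out
}

dilate_disc <- function(mask, radius) {
  offs <- disc_offsets(radius)
  out <- mask
  for (i in seq_len(nrow(offs))) {
    out <- out | shift_matrix(mask, offs$dr[i], offs$dc[i], fill = FALSE)
  }
  out
}

#' Remove the tail from a segmented sperm component
#'
#' Thin appendages (local width below `width_threshold`) are erased by
#' morphological opening with a disc of that radius; the largest surviving
#' component (the head body) is kept and re-dilated inside the original
#' mask, so the head regains its boundary pixels while the tail stays gone.
#'
#' @param mask logical matrix, one connected component.
#' @param width_threshold disc radius in pixels (default 4): structures
#'   thinner than this are treated as tail.
#' @return logical matrix of the same size: the head mask.
#' @export
remove_tail <- function(mask, width_threshold = 4) {
  if (!any(mask)) stopf("empty component mask")
  pad <- width_threshold + 1L
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(FALSE, h + 2L * pad, w + 2L * pad)
  padded[pad + seq_len(h), pad + seq_len(w)] <- mask
  opened <- dilate_disc(erode_disc(padded, width_threshold), width_threshold)
  if (!any(opened)) {
    stopf("degenerate component: opening with radius %d erased everything",
          width_threshold)
  }
  labs <- label_components(opened)
  areas <- tabulate(labs[labs > 0L])
  largest <- labs == which.max(areas)
  head <- dilate_disc(largest, width_threshold) & padded
  head[pad + seq_len(h), pad + seq_len(w), drop = FALSE]
}

#' Crop a single sperm head from a micrograph
#'
#' Cuts the mask's bounding box plus a 2-pixel margin (clipped at the image
#' border) and records the crop origin so crops can be pasted back. Pixels
#' outside the mask are retained; mask-restricted statistics use the
#' aligned `mask` slot.
#'
#' @param image a `gray_image` or numeric matrix.
#' @param mask logical matrix aligned with `image`, non-empty, one
#'   connected component.
#' @param margin margin in pixels around the bounding box (default 2).
#' @param label optional class label carried along for evaluation.
#' @return a `sperm_crop`: `list(image, mask, origin, label)` where `origin`
#'   is the (row, col) of the crop's top-left pixel in the source image.
#' @export
crop_head <- function(image, mask, margin = 2, label = NULL) {
  image <- as_gray_image(image)
  if (!any(mask)) stopf("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  margin <- as.integer(margin)
  r1 <- max(1L, min(idx[, 1]) - margin); r2 <- min(nrow(image), max(idx[, 1]) + margin)
  c1 <- max(1L, min(idx[, 2]) - margin); c2 <- min(ncol(image), max(idx[, 2]) + margin)
  structure(list(image = as_gray_image(image[r1:r2, c1:c2, drop = FALSE]),
                 mask = mask[r1:r2, c1:c2, drop = FALSE],
                 origin = c(r1, c1), label = label),
            class = "sperm_crop")
}

#' @export
print.sperm_crop <- function(x, ...) {
  cat(sprintf("<sperm_crop> %d x %d at origin (%d, %d), mask area %d%s\n",
              nrow(x$image), ncol(x$image), x$origin[1], x$origin[2],
              sum(x$mask), if (is.null(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}
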