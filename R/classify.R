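#' Joint rank-difference and darkness criterion
#'
#' `C = alpha * dARD + (1 - alpha) * 255 * P`: a weighted combination of
#' the shape term (average rank difference of the centroid-distance
#' waveform) and the darkness term (gray percentage rescaled to the 0-255
#' range so both terms share a scale).
#'
#' @param dard average rank difference (>= 0).
#' @param p darkness fraction in `[0, 1]`.
#' @param alpha weight of the shape term, in `[0, 1]`.
#' @return scalar criterion value (vectorized over inputs).
#' @export
joint_criterion <- function(dard, p, alpha) {
  if (any(alpha < 0 | alpha > 1)) stopf("alpha must lie in [0, 1]")
  if (any(p < 0 | p > 1)) stopf("darkness fraction must lie in [0, 1]")
  if (any(dard < 0)) stopf("dARD must be non-negative")
  alpha * dard + (1 - alpha) * 255 * p
}

normalize_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("normal", "abnormal"))
  if (length(bad)) stopf("labels must be 'normal'/'abnormal' (got %s)",
                         paste(bad, collapse = ", "))
  labels
}

#' Best dividing line for a scalar criterion
#'
#' Scans candidate thresholds (midpoints between consecutive sorted unique
#' values, plus one candidate below the minimum and one above the maximum,
#' so the trivial single-class rules are always available) and returns the
#' threshold maximizing the accuracy of the rule "value below the dividing
#' line is normal" (`direction = "below"`; `"above"` reverses the rule).
#' Ties are broken by the smallest dividing line.
#'
#' @param values numeric criterion values, one per sperm.
#' @param labels `"normal"` / `"abnormal"` per sperm; both classes must be
#'   present.
#' @param direction which side of the line is normal.
#' @return `list(dl, accuracy, direction)`.
#' @export
find_dividing_line <- function(values, labels, direction = c("below", "above")) {
  direction <- match.arg(direction)
  labels <- normalize_labels(labels)
  if (length(values) != length(labels)) stopf("values/labels length mismatch")
  if (length(unique(labels)) < 2L) stopf("both classes must be present")
  u <- sort(unique(values))
  cand <- c(u[1] - 1, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  is_normal <- labels == "normal"
  acc <- vapply(cand, function(dl) {
    pred_normal <- if (direction == "below") values < dl else values > dl
    mean(pred_normal == is_normal)
  }, 0)
  best <- which.max(acc)  # first maximum = smallest candidate DL
  list(dl = cand[best], accuracy = acc[best], direction = direction)
}

#' Sweep the joint-criterion weight alpha
#'
#' For each weight in the grid, combines the per-sperm dARD and darkness
#' values into the joint criterion, finds its best dividing line and
#' records the resulting accuracy. The default grid is 0.1 to 0.9 in steps
#' of 0.1.
#'
#' @param dards numeric vector of average rank differences.
#' @param ps numeric vector of darkness fractions.
#' @param labels `"normal"` / `"abnormal"` per sperm.
#' @param alphas weight grid.
#' @return data frame with columns `alpha`, `dl`, `accuracy`; the row index
#'   of the best weight (highest accuracy, ties to the lower alpha) is in
#'   attribute `"best"`.
#' @export
alpha_sweep <- function(dards, ps, labels, alphas = seq(0.1, 0.9, by = 0.1)) {
  if (!length(alphas)) stopf("empty alpha grid")
  if (length(dards) != length(ps)) stopf("dards/ps length mismatch")
  rows <- lapply(alphas, function(a) {
    fit <- find_dividing_line(joint_criterion(dards, ps, a), labels)
    data.frame(alpha = a, dl = fit$dl, accuracy = fit$accuracy)
  })
  out <- do.call(rbind, rows)
  attr(out, "best") <- which.max(out$accuracy)
  out
}

#' Fused gray-spiral + dARD feature vectors
#'
#' Per sperm: the 256 word ranks of its m = 8 gray-spiral rank profile
#' (ordered by word value) with the sperm's dARD appended, giving
#' length-257 vectors — the SVM input.
#'
#' @param gray_profiles list of `rank_profile` objects with `m = 8`.
#' @param dards numeric vector aligned with `gray_profiles`.
#' @return numeric matrix, one row per sperm, 257 columns.
#' @export
build_fused_features <- function(gray_profiles, dards) {
  if (length(gray_profiles) != length(dards)) {
    stopf("profiles/dards length mismatch")
  }
  feats <- t(vapply(seq_along(gray_profiles), function(i) {
    p <- gray_profiles[[i]]
    if (p$m != 8L) stopf("fused features need m = 8 profiles (got m = %d)", p$m)
    c(p$ranks, dards[i])
  }, numeric(257)))
  colnames(feats) <- c(paste0("rank_w", 0:255), "dard")
  feats
}

#' Train and evaluate the fused SVM
#'
#' The training set is the five most representative sperms of each class —
#' smallest total `D_m` of the gray-spiral profiles within the class — and
#' the remaining sperms are the test set. Features are standardized per
#' dimension over the full feature matrix (rank entries and dARD live on
#' different scales; population statistics use no labels and avoid the
#' degenerate scale estimates a ten-sample training set gives), the RBF
#' C-SVC is fitted with the given configuration, and accuracy is reported
#' on the test set.
#'
#' @param features numeric feature matrix (e.g. [build_fused_features()]).
#' @param labels `"normal"` / `"abnormal"` per row of `features`.
#' @param gray_profiles optional list of `rank_profile`s used to pick the
#'   representative training sperms; if `NULL`, `train_indices` must be
#'   given.
#' @param n_train_per_class representatives per class (default 5).
#' @param train_indices explicit training-set rows (overrides the
#'   representativeness rule).
#' @param config an [svm_config()].
#' @return an `eval_report` for the test set, with the fitted model in
#'   `$model` and the training indices in `$train_indices`.
#' @export
svm_train_test <- function(features, labels, gray_profiles = NULL,
                           n_train_per_class = 5, train_indices = NULL,
                           config = svm_config()) {
  labels <- normalize_labels(labels)
  n <- nrow(features)
  if (is.null(train_indices)) {
    if (is.null(gray_profiles)) stopf("need gray_profiles or train_indices")
    train_indices <- integer(0)
    for (cls in c("normal", "abnormal")) {
      idx <- which(labels == cls)
      if (length(idx) < n_train_per_class) {
        stopf("class '%s' has %d sperms; need at least %d", cls,
              length(idx), n_train_per_class)
      }
      reps <- select_representatives(gray_profiles[idx], n_train_per_class,
                                     class = cls)
      train_indices <- c(train_indices, idx[reps$indices])
    }
  }
  test_indices <- setdiff(seq_len(n), train_indices)
  if (!length(test_indices)) stopf("no test samples left")

  mu <- colMeans(features)
  sg <- apply(features, 2, stats::sd)
  sg[sg == 0 | is.na(sg)] <- 1
  std <- sweep(sweep(features, 2, mu), 2, sg, `/`)

  model <- svm_fit(std[train_indices, , drop = FALSE],
                   factor(labels[train_indices], levels = c("normal", "abnormal")),
                   config)
  pred <- predict(model, std[test_indices, , drop = FALSE])
  report <- evaluate(as.character(pred), labels[test_indices])
  report$model <- model
  report$train_indices <- train_indices
  report$config_echo <- c(unclass(config), list(gamma_used = model$gamma,
                                                n_train = length(train_indices)))
  report
}

# Nearest-neighbour resampling of a gray image to (h, w).
resample_image <- function(image, h, w) {
  r_src <- pmin(nrow(image), pmax(1L, round(seq_len(h) * nrow(image) / h)))
  c_src <- pmin(ncol(image), pmax(1L, round(seq_len(w) * ncol(image) / w)))
  image[r_src, c_src, drop = FALSE]
}

#' K-nearest-neighbour baseline on raw pixel differences
#'
#' Resamples every crop to a common frame (the median reference extent,
#' nearest-neighbour interpolation), ranks references by the sum of
#' absolute pixel differences to the test image, and labels the test sperm
#' normal when more than `normal_cut` of the `k` closest references are
#' normal.
#'
#' @param test a `sperm_crop` (or gray matrix).
#' @param refs list of reference `sperm_crop`s (or gray matrices).
#' @param ref_labels `"normal"` / `"abnormal"` per reference.
#' @param k neighbourhood size (default 10, `k <= length(refs)`).
#' @param normal_cut normal-vote threshold: the test sperm is normal when
#'   strictly more than this many neighbours are normal. Defaults to 3 for
#'   k = 10 (the reference cut) and to a simple majority, `floor(k / 2)`,
#'   otherwise.
#' @return predicted label; neighbour indices in attribute `"neighbors"`.
#' @export
knn_classify <- function(test, refs, ref_labels, k = 10, normal_cut = NULL) {
  ref_labels <- normalize_labels(ref_labels)
  if (k > length(refs)) stopf("k exceeds the number of references")
  if (is.null(normal_cut)) normal_cut <- if (k == 10) 3 else floor(k / 2)
  as_img <- function(x) if (inherits(x, "sperm_crop")) x$image else x
  imgs <- lapply(refs, as_img)
  hs <- vapply(imgs, nrow, 0L); ws <- vapply(imgs, ncol, 0L)
  h <- round(stats::median(hs)); w <- round(stats::median(ws))
  frame <- vapply(imgs, function(im) as.numeric(resample_image(im, h, w)),
                  numeric(h * w))
  tv <- as.numeric(resample_image(as_img(test), h, w))
  d <- colSums(abs(frame - tv))
  nb <- order(d, seq_along(d))[seq_len(k)]
  votes <- sum(ref_labels[nb] == "normal")
  out <- if (votes > normal_cut) "normal" else "abnormal"
  attr(out, "neighbors") <- nb
  out
}

#' Ellipse-model (ovality) baseline
#'
#' Rotates the head so its principal axis (from the mask's second moments)
#' is horizontal, takes the bounding rectangle of the rotated boundary
#' pixels, and computes the ovality — long side over short side. Heads with
#' ovality strictly inside `band` are normal: too close to a circle
#' (ovality near 1) or too slim (near 2 and beyond) is abnormal.
#'
#' @param mask logical head mask.
#' @param band open normality interval for the ovality (default
#'   `c(1.2, 1.8)`).
#' @return `list(ovality, label)`.
#' @export
ellipse_classify <- function(mask, band = c(1.2, 1.8)) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stopf("empty mask")
  ctr <- colMeans(idx)
  pts <- sweep(idx, 2, ctr)
  cv <- crossprod(pts) / nrow(pts)
  eg <- eigen(cv, symmetric = TRUE)
  ax <- eg$vectors[, 1]
  angle <- atan2(ax[1], ax[2])          # principal axis angle vs columns
  rot <- cbind(c(cos(angle), -sin(angle)), c(sin(angle), cos(angle)))
  rp <- pts %*% rot
  ext <- c(diff(range(rp[, 1])), diff(range(rp[, 2]))) + 1  # pixel extents
  long <- max(ext); short <- min(ext)
  ovality <- if (short <= 1e-9) Inf else long / short
  label <- if (is.finite(ovality) && ovality > band[1] && ovality < band[2])
    "normal" else "abnormal"
  list(ovality = ovality, label = label)
}

#' Accuracy and confusion counts
#'
#' @param pred,truth aligned label vectors (`"normal"` / `"abnormal"`).
#' @param config_echo optional list of parameters to carry in the report.
#' @return an `eval_report`: `list(n_correct, n_total, accuracy, per_class,
#'   config_echo)`.
#' @export
evaluate <- function(pred, truth, config_echo = NULL) {
  pred <- as.character(pred); truth <- as.character(truth)
  if (length(pred) != length(truth)) stopf("pred/truth length mismatch")
  lev <- c("normal", "abnormal")
  tab <- table(factor(truth, lev), factor(pred, lev), dnn = c("truth", "pred"))
  n_correct <- sum(diag(tab))
  structure(list(n_correct = n_correct, n_total = length(truth),
                 accuracy = n_correct / length(truth), per_class = tab,
                 config_echo = config_echo),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.4f (%d/%d)\n",
              x$accuracy, x$n_correct, x$n_total))
  print(x$per_class)
  invisible(x)
}
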