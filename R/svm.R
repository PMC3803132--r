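#' C-SVC configuration
#'
#' Defaults follow the reference setup: C-SVC with an RBF kernel
#' `exp(-gamma * ||u - v||^2)`, `gamma = 1/k` where `k` is the feature
#' dimension, `cost = 1`, stopping tolerance `eps = 0.001`, equal class
#' weights. (Cache size and shrinking switches of external solvers have no
#' analogue in this in-package solver and are accepted but ignored.)
#'
#' @param cost penalty parameter C of the error term (> 0).
#' @param gamma RBF width; `NULL` means `1 / feature dimension`, set at fit
#'   time.
#' @param eps KKT violation tolerance for the optimizer.
#' @param max_iter iteration cap for the optimizer.
#' @return an `svm_config` list.
#' @export
svm_config <- function(cost = 1, gamma = NULL, eps = 0.001, max_iter = 10000L) {
  if (cost <= 0) stopf("cost must be > 0")
  if (!is.null(gamma) && gamma <= 0) stopf("gamma must be > 0")
  structure(list(svm_type = "C-SVC", kernel = "RBF", cost = cost,
                 gamma = gamma, eps = eps, max_iter = as.integer(max_iter)),
            class = "svm_config")
}

rbf_kernel_matrix <- function(x, y, gamma) {
  # ||u - v||^2 = |u|^2 + |v|^2 - 2 u.v
  xn <- rowSums(x^2)
  yn <- rowSums(y^2)
  d2 <- outer(xn, yn, `+`) - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Fit a C-SVC with RBF kernel by sequential minimal optimization
#'
#' Deterministic SMO: sweeps examples in index order and pairs each
#' KKT-violating multiplier with the partner maximizing `|E_i - E_j|`
#' (lowest index on ties). Intended for the small training sets this
#' pipeline uses (ten representative sperms); no shrinking or caching.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y labels coercible to two classes; the first level maps to +1.
#' @param config an [svm_config()].
#' @return an `svm_model` with multipliers, bias and training data.
#' @export
svm_fit <- function(x, y, config = svm_config()) {
  x <- as.matrix(x)
  yf <- factor(y)
  if (nlevels(yf) != 2L) stopf("svm_fit needs exactly two classes")
  ysign <- ifelse(as.integer(yf) == 1L, 1, -1)
  n <- nrow(x)
  gamma <- if (is.null(config$gamma)) 1 / ncol(x) else config$gamma
  K <- rbf_kernel_matrix(x, x, gamma)
  C <- config$cost
  tol <- config$eps

  alpha <- numeric(n)
  b <- 0
  f_cache <- function() as.vector(K %*% (alpha * ysign)) + b
  iter <- 0L
  changed <- TRUE
  while (changed && iter < config$max_iter) {
    changed <- FALSE
    iter <- iter + 1L
    E <- f_cache() - ysign
    for (i in seq_len(n)) {
      ri <- E[i] * ysign[i]
      if ((ri < -tol && alpha[i] < C) || (ri > tol && alpha[i] > 0)) {
        j <- which.max(abs(E[i] - E))
        if (j == i) next
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (ysign[i] != ysign[j]) {
          lo <- max(0, aj_old - ai_old); hi <- min(C, C + aj_old - ai_old)
        } else {
          lo <- max(0, ai_old + aj_old - C); hi <- min(C, ai_old + aj_old)
        }
        if (lo >= hi) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - ysign[j] * (E[i] - E[j]) / eta
        aj <- min(max(aj, lo), hi)
        if (abs(aj - aj_old) < 1e-12) next
        ai <- ai_old + ysign[i] * ysign[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - E[i] - ysign[i] * (ai - ai_old) * K[i, i] -
          ysign[j] * (aj - aj_old) * K[i, j]
        b2 <- b - E[j] - ysign[i] * (ai - ai_old) * K[i, j] -
          ysign[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else
          (b1 + b2) / 2
        E <- f_cache() - ysign
        changed <- TRUE
      }
    }
  }
  structure(list(x = x, ysign = ysign, levels = levels(yf), alpha = alpha,
                 b = b, gamma = gamma, config = config, iterations = iter),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model> RBF C-SVC: %d SV of %d, gamma=%.4g, cost=%g\n",
              sum(x$alpha > 1e-8), nrow(x$x), x$gamma, x$config$cost))
  invisible(x)
}

#' Decision values and labels for new samples
#'
#' @param object an `svm_model`.
#' @param newdata numeric matrix of samples (rows).
#' @param ... unused.
#' @return factor of predicted labels; decision values in attribute
#'   `"decision"`.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  K <- rbf_kernel_matrix(newdata, object$x, object$gamma)
  dec <- as.vector(K %*% (object$alpha * object$ysign)) + object$b
  lab <- factor(ifelse(dec >= 0, object$levels[1], object$levels[2]),
                levels = object$levels)
  attr(lab, "decision") <- dec
  lab
}
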