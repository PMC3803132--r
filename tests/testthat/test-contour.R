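adjacent8 <- function(p, q) max(abs(p - q)) == 1L ||
  (all(p == q) && FALSE)

test_that("trace_contour walks a filled square in order", {
  m <- matrix(FALSE, 7, 7); m[2:6, 2:6] <- TRUE
  ct <- trace_contour(m)
  pts <- ct$points
  expect_identical(nrow(pts), 16L)               # 5x5 square: 16 edge pixels
  expect_identical(pts[1, ], c(2L, 2L))          # top-most then left-most
  expect_identical(nrow(unique(pts)), 16L)
  for (i in seq_len(16)) {
    expect_true(adjacent8(pts[i, ], pts[wrap_index(i + 1L, 16L), ]))
  }
  # clockwise: the second point is to the east of the start
  expect_identical(pts[2, ], c(2L, 3L))
})

test_that("trace_contour rejects degenerate and split masks", {
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_error(trace_contour(single), "degenerate")
  two <- matrix(FALSE, 9, 9); two[2:3, 2:3] <- TRUE; two[6:7, 6:7] <- TRUE
  expect_error(trace_contour(two), "one component")
})

test_that("disc contour length matches brute-force boundary enumeration", {
  m <- disc_mask(20)
  ct <- trace_contour(m)
  # oracle: pixels of the mask with at least one 4-neighbour background
  # (the inner boundary an 8-connected trace walks)
  idx <- which(m, arr.ind = TRUE)
  is_boundary <- vapply(seq_len(nrow(idx)), function(i) {
    r <- idx[i, 1]; c <- idx[i, 2]
    !(m[r - 1, c] && m[r + 1, c] && m[r, c - 1] && m[r, c + 1])
  }, TRUE)
  expect_lt(abs(nrow(ct$points) - sum(is_boundary)) / sum(is_boundary), 0.1)
})

test_that("contour centroid is the mean of edge points and is equivariant", {
  sq <- structure(list(points = cbind(c(0, 0, 10, 10), c(0, 10, 10, 0))),
                  class = "contour")
  expect_identical(contour_centroid(sq), c(5, 5))
  shifted <- structure(list(points = sq$points +
                              matrix(c(3, -2), 4, 2, byrow = TRUE)),
                       class = "contour")
  expect_identical(contour_centroid(shifted), c(8, 3))

  m <- matrix(FALSE, 61, 81)
  rr <- matrix(seq_len(61), 61, 81); cc <- matrix(seq_len(81), 61, 81, byrow = TRUE)
  m[(rr - 30)^2 + (cc - 40)^2 <= 15^2] <- TRUE
  ct <- trace_contour(m)
  expect_lt(max(abs(contour_centroid(ct) - c(30, 40))), 0.5)
})

test_that("distance waveform is near-constant on a disc and scales with size", {
  ct <- trace_contour(disc_mask(15))
  wv <- distance_waveform(ct)
  expect_true(all(abs(wv$values - 15) <= 1))

  small <- distance_waveform(trace_contour(disc_mask(8)))
  big <- distance_waveform(trace_contour(disc_mask(16)))
  expect_true(all(abs(big$values - 16) <= 1) && all(abs(small$values - 8) <= 1))
})

test_that("waveforms are exactly translation invariant", {
  base <- ellipse_mask(12, 7, pad = 3)
  embedded <- matrix(FALSE, nrow(base) + 20, ncol(base) + 20)
  embedded[9 + seq_len(nrow(base)), 5 + seq_len(ncol(base))] <- base
  expect_identical(distance_waveform(trace_contour(base))$values,
                   distance_waveform(trace_contour(embedded))$values)
  expect_identical(symmetry_waveform(trace_contour(base))$values,
                   symmetry_waveform(trace_contour(embedded))$values)
})

test_that("90-degree rotation circularly shifts the distance waveform", {
  m <- ellipse_mask(12, 7, pad = 3)
  rot <- t(m)[ncol(m):1, , drop = FALSE]       # 90 degree rotation
  v1 <- distance_waveform(trace_contour(m))$values
  v2 <- distance_waveform(trace_contour(rot))$values
  expect_identical(length(v1), length(v2))
  L <- length(v1)
  shift_err <- vapply(seq_len(L) - 1L, function(s) {
    max(abs(v1 - v2[wrap_index(seq_len(L) + s, L)]))
  }, 0)
  expect_lt(min(shift_err), 1e-9)
})

test_that("percent_sym is 1 on symmetric waveforms and matches brute force", {
  expect_equal(percent_sym(c(1, 2, 3, 2, 1), k = 3), 1.0)
  expect_equal(percent_sym(c(5, 5, 5, 5), k = 2), 1.0)
  # circular palindrome about k = 1
  expect_equal(percent_sym(c(9, 4, 7, 7, 4), k = 1), 1.0)

  A <- c(1, 4, 1, 1, 1); k <- 2
  L <- length(A)
  num <- 0; den <- 0
  for (i in seq_len(L)) {                      # independent hand expansion
    j <- ((2 * k - i - 1) %% L) + 1
    num <- num + abs(A[i] - A[j])
    den <- den + 2 * sqrt(A[i] * A[j])
  }
  expect_equal(percent_sym(A, k), 1 - num / den)

  # property: <= 1 with equality only for exact symmetry
  set.seed(42)
  for (rep in 1:20) {
    x <- runif(11, 0.5, 4)
    ps <- percent_sym(x, sample(11, 1))
    expect_lte(ps, 1)
  }
  expect_lt(percent_sym(c(1, 2, 8, 2, 1), k = 1), 1)
  expect_error(percent_sym(c(0, 1, 2), k = 1), "zero")
})

test_that("symmetry scores find the axis of an ellipse and flatten on a circle", {
  m <- ellipse_mask(16, 9, pad = 3)
  ct <- trace_contour(m)
  s <- symmetry_scores(ct)
  best <- which.min(s)
  # true axis endpoints: contour points at extreme columns (major axis)
  # or extreme rows (minor axis); both are valid mirror axes
  pts <- ct$points
  axis_idx <- c(which(pts[, 2] == min(pts[, 2])), which(pts[, 2] == max(pts[, 2])),
                which(pts[, 1] == min(pts[, 1])), which(pts[, 1] == max(pts[, 1])))
  L <- nrow(pts)
  ring_dist <- min(pmin(abs(best - axis_idx), L - abs(best - axis_idx)))
  expect_lte(ring_dist, 2)

  # near-full symmetry everywhere on a circle: every score is small
  # relative to the summed squared distances it differences
  ct_c <- trace_contour(disc_mask(14))
  sc <- symmetry_scores(ct_c)
  pc <- ct_c$points; Lc <- nrow(pc)
  half <- (Lc - 1) %/% 2
  totals <- vapply(seq_len(Lc), function(n) {
    j <- seq_len(half)
    fwd <- wrap_index(n + j, Lc); bwd <- wrap_index(n - j, Lc)
    sum((pc[fwd, 1] - pc[n, 1])^2 + (pc[fwd, 2] - pc[n, 2])^2) +
      sum((pc[bwd, 1] - pc[n, 1])^2 + (pc[bwd, 2] - pc[n, 2])^2)
  }, 0)
  expect_lt(max(sc) / mean(totals), 0.05)
})

test_that("symmetry waveform matches the circle chord profile", {
  ct <- trace_contour(disc_mask(15))
  wv <- symmetry_waveform(ct)
  L <- nrow(ct$points)
  j <- 0:(L %/% 2)
  expected <- 2 * 15 * abs(sin(2 * pi * j / L))   # chord between points 2j apart
  expect_lt(max(abs(wv$values - expected)), 2)
})

test_that("symmetry waveform mirrors exactly and depends on the anchor", {
  m <- ellipse_mask(14, 8, pad = 3)
  mir <- m[, ncol(m):1, drop = FALSE]
  v1 <- symmetry_waveform(trace_contour(m))$values
  v2 <- symmetry_waveform(trace_contour(mir))$values
  expect_equal(v1, v2, tolerance = 1e-9)
  # documented starting-point sensitivity: a different anchor gives a
  # different waveform
  ct <- trace_contour(m)
  k0 <- which.min(symmetry_scores(ct))
  alt <- wrap_index(k0 + 7L, nrow(ct$points))
  expect_false(isTRUE(all.equal(symmetry_waveform(ct, k = k0)$values,
                                symmetry_waveform(ct, k = alt)$values)))
})
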