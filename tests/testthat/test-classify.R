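test_that("joint criterion is the exact weighted combination", {
  expect_identical(joint_criterion(137.2, 0.9, 1), 137.2)
  expect_identical(joint_criterion(137.2, 0.4, 0), 102)
  expect_equal(joint_criterion(100, 0.268, 0.8), 93.668)
  expect_error(joint_criterion(10, 0.5, 1.2), "alpha")
  expect_error(joint_criterion(10, 1.4, 0.5), "darkness")
  expect_error(joint_criterion(-3, 0.5, 0.5), "non-negative")
})

test_that("find_dividing_line maximizes accuracy over midpoint candidates", {
  fit <- find_dividing_line(c(1, 2, 8, 9), c("normal", "normal", "abnormal", "abnormal"))
  expect_identical(fit$dl, 5)
  expect_identical(fit$accuracy, 1)

  # brute-force oracle over a dense threshold grid on random data
  set.seed(17)
  for (rep in 1:10) {
    v <- round(runif(30, 0, 10), 2)
    lab <- sample(c("normal", "abnormal"), 30, replace = TRUE,
                  prob = c(0.5, 0.5))
    if (length(unique(lab)) < 2) next
    fit <- find_dividing_line(v, lab)
    grid <- seq(min(v) - 1, max(v) + 1, by = 0.005)
    oracle <- max(vapply(grid, function(t) mean((v < t) == (lab == "normal")), 0))
    expect_equal(fit$accuracy, oracle)
    # trivial single-class rules are always available
    expect_gte(fit$accuracy, max(mean(lab == "normal"), mean(lab == "abnormal")))
  }

  # flipping the labels mirrors the rule direction
  v <- c(1, 3, 4, 6, 7, 9)
  lab <- c("normal", "normal", "abnormal", "normal", "abnormal", "abnormal")
  flip <- ifelse(lab == "normal", "abnormal", "normal")
  expect_identical(find_dividing_line(v, lab, "below")$accuracy,
                   find_dividing_line(v, flip, "above")$accuracy)
  expect_error(find_dividing_line(v, rep("normal", 6)), "both classes")
})

test_that("alpha_sweep covers the grid and collapses to single features at the ends", {
  set.seed(4)
  dards <- c(rnorm(20, 50, 5), rnorm(20, 150, 5))
  ps <- c(runif(20, 0.1, 0.3), runif(20, 0.6, 0.9))
  labels <- rep(c("normal", "abnormal"), each = 20)
  tab <- alpha_sweep(dards, ps, labels)
  expect_identical(nrow(tab), 9L)
  expect_equal(tab$alpha, seq(0.1, 0.9, by = 0.1))
  expect_true(all(tab$accuracy == 1))            # jointly separable

  # endpoint equivalence with the single-feature dividing lines
  ends <- alpha_sweep(dards, ps, labels, alphas = c(0, 1))
  expect_identical(ends$accuracy[ends$alpha == 1],
                   find_dividing_line(dards, labels)$accuracy)
  expect_identical(ends$accuracy[ends$alpha == 0],
                   find_dividing_line(ps, labels)$accuracy)

  # uninformative dards: every alpha < 1 rides on the darkness feature
  tab2 <- alpha_sweep(rep(100, 40), ps, labels)
  expect_true(all(tab2$accuracy == find_dividing_line(ps, labels)$accuracy))
  expect_error(alpha_sweep(dards, ps, labels, alphas = numeric()), "empty")
})

test_that("fused features have the documented shape and invariants", {
  set.seed(2)
  profs <- lapply(1:6, function(i) word_histogram(rank_binarize(runif(300)), 8))
  dards <- runif(6, 50, 200)
  feats <- build_fused_features(profs, dards)
  expect_identical(dim(feats), c(6L, 257L))
  for (i in 1:6) expect_setequal(feats[i, 1:256], 1:256)
  expect_identical(feats[, 257], dards)
  # identical profiles differ only in the last entry
  f2 <- build_fused_features(list(profs[[1]], profs[[1]]), c(10, 20))
  expect_identical(f2[1, 1:256], f2[2, 1:256])
  expect_false(f2[1, 257] == f2[2, 257])
  bad <- word_histogram(rank_binarize(runif(40)), 5)
  expect_error(build_fused_features(list(bad), 1), "m = 8")
})

test_that("knn_classify follows the vote cut on pixel differences", {
  refs <- c(lapply(1:6, function(i) disc_crop(8, intensity = 90 + i)),
            lapply(1:6, function(i) disc_crop(8, intensity = 180 + i)))
  labels <- rep(c("normal", "abnormal"), each = 6)
  got <- knn_classify(disc_crop(8, intensity = 91), refs, labels, k = 1)
  expect_identical(as.character(got), "normal")
  expect_identical(
    as.character(knn_classify(disc_crop(8, 150), refs[1:6], labels[1:6], k = 3)),
    "normal")
  # with k = 10 and cut 3, four normal neighbours suffice
  got2 <- knn_classify(disc_crop(8, intensity = 140), refs, labels, k = 10)
  nb <- attr(got2, "neighbors")
  votes <- sum(labels[nb] == "normal")
  expect_identical(as.character(got2),
                   if (votes > 3) "normal" else "abnormal")
  expect_error(knn_classify(disc_crop(8), refs, labels, k = 20), "exceeds")
})

test_that("ellipse ovality matches construction and rotation invariance", {
  ell <- ellipse_mask(15, 10)
  got <- ellipse_classify(ell)
  expect_equal(got$ovality, 1.5, tolerance = 0.05)
  expect_identical(got$label, "normal")

  circ <- ellipse_classify(disc_mask(12))
  expect_equal(circ$ovality, 1.0, tolerance = 0.05)
  expect_identical(circ$label, "abnormal")

  slim <- ellipse_classify(ellipse_mask(20, 10))
  expect_equal(slim$ovality, 2.0, tolerance = 0.05)
  expect_identical(slim$label, "abnormal")

  # rotated copies keep the ovality within 5%
  for (th in c(0.3, 0.8, 1.2, 2.4)) {
    n <- 61
    rr <- matrix(seq_len(n), n, n) - 31
    cc <- t(rr)
    rot <- ((cc * cos(th) + rr * sin(th)) / 15)^2 +
      ((-cc * sin(th) + rr * cos(th)) / 10)^2 <= 1
    expect_lt(abs(ellipse_classify(rot)$ovality - 1.5) / 1.5, 0.05)
  }

  line <- matrix(FALSE, 9, 30); line[5, 2:29] <- TRUE
  expect_identical(ellipse_classify(line)$label, "abnormal")
  expect_error(ellipse_classify(matrix(FALSE, 4, 4)), "empty")
})

test_that("evaluate reports accuracy and confusion counts", {
  p <- c("normal", "abnormal", "normal")
  expect_identical(evaluate(p, p)$accuracy, 1)
  opp <- c("abnormal", "normal", "abnormal")
  expect_identical(evaluate(p, opp)$accuracy, 0)
  truth <- rep(c("normal", "abnormal"), each = 80)
  pred <- truth
  pred[c(1:20, 81:97)] <- ifelse(truth[c(1:20, 81:97)] == "normal",
                                 "abnormal", "normal")   # 37 mistakes
  rep <- evaluate(pred, truth)
  expect_identical(rep$n_correct, 123L)
  expect_identical(rep$accuracy, 0.76875)
  expect_identical(sum(rep$per_class), 160L)
  expect_error(evaluate(p, p[1:2]), "mismatch")
})
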