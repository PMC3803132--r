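test_that("rank_binarize applies the circular rise rule", {
  expect_identical(as.integer(rank_binarize(c(1, 2, 3, 4))), c(0L, 1L, 1L, 1L))
  expect_identical(as.integer(rank_binarize(c(7, 7, 7))), c(0L, 0L, 0L))
  x <- c(3, 1, 4, 1, 5, 9, 2.6)
  expect_identical(as.integer(rank_binarize(x)), as.integer(rank_binarize(3.7 * x)))
  expect_error(rank_binarize(5), "at least 2")
})

test_that("word_histogram counts circular windows with the tie rule", {
  all0 <- rank_binarize(rep(1, 12))
  p <- word_histogram(all0, 5)
  expect_identical(p$probs[1], 1)
  expect_identical(p$ranks[1], 1L)
  expect_identical(sort(p$ranks), 1:32)         # permutation, ties by word value
  expect_identical(p$ranks[2], 2L)

  p2 <- word_histogram(structure(c(1L, 0L, 1L, 0L), class = "rank_code"), 2)
  expect_identical(p2$counts, c(0L, 2L, 2L, 0L))
  expect_identical(p2$ranks[2], 1L)             # word 1 beats word 2 on the tie
  expect_identical(p2$ranks[3], 2L)

  expect_error(word_histogram(all0, 0), "1..16")
  expect_error(word_histogram(all0, 17), "1..16")
  expect_error(word_histogram(rank_binarize(c(1, 2)), 5), "shorter")
})

test_that("histograms, ranks, D_m and rank sums match brute-force enumeration", {
  set.seed(7)
  for (case in 1:30) {
    L <- sample(4:12, 1)
    m <- sample(1:3, 1)
    x <- runif(L)
    y <- runif(sample(4:12, 1))
    bits_x <- as.integer(rank_binarize(x))
    bits_y <- as.integer(rank_binarize(y))
    px <- word_histogram(rank_binarize(x), m)
    py <- word_histogram(rank_binarize(y), m)
    ox <- oracle_profile(bits_x, m)
    oy <- oracle_profile(bits_y, m)
    expect_identical(px$counts, ox$counts)
    expect_identical(px$ranks, ox$ranks)
    expect_equal(px$probs, ox$probs)
    expect_equal(dm_distance(px, py), oracle_dm(ox, oy))
    support <- ox$probs + oy$probs > 0
    expect_equal(rank_difference_sum(px, py),
                 sum(abs(ox$ranks[support] - oy$ranks[support])))
  }
})

test_that("D_m is a bounded symmetric dissimilarity", {
  set.seed(11)
  profs <- lapply(1:8, function(i) word_histogram(rank_binarize(runif(40)), 5))
  for (i in 1:8) expect_identical(dm_distance(profs[[i]], profs[[i]]), 0)
  for (i in 1:7) {
    d <- dm_distance(profs[[i]], profs[[i + 1]])
    expect_gte(d, 0); expect_lte(d, 1)
    expect_identical(d, dm_distance(profs[[i + 1]], profs[[i]]))
  }
  # disjoint supports: all-zero code vs all-one code
  a <- word_histogram(structure(rep(0L, 10), class = "rank_code"), 3)
  b <- word_histogram(structure(rep(1L, 10), class = "rank_code"), 3)
  expect_identical(dm_distance(a, b), 1)
  expect_error(dm_distance(a, word_histogram(rank_binarize(runif(10)), 5)),
               "different word widths")
})

test_that("rank profiles are exactly start-point and scale invariant", {
  set.seed(3)
  x <- runif(60)
  p0 <- word_histogram(rank_binarize(x), 5)
  for (s in c(1, 7, 23, 59)) {
    shifted <- x[wrap_index(seq_along(x) + s, length(x))]
    ps <- word_histogram(rank_binarize(shifted), 5)
    expect_identical(p0$counts, ps$counts)
    expect_identical(dm_distance(p0, ps), 0)
  }
  for (cc in c(0.004, 3.7, 2000)) {
    expect_identical(dm_distance(p0, word_histogram(rank_binarize(cc * x), 5)), 0)
  }
})

test_that("representative selection minimizes total D_m with input-order ties", {
  base <- word_histogram(rank_binarize(c(1, 3, 2, 5, 4, 6, 2, 8)), 3)
  clones <- list(base, base, base, base, base)
  ms <- select_representatives(clones, 3)
  expect_identical(ms$indices, 1:3)
  expect_identical(select_representatives(clones, 5)$indices, 1:5)

  # one outlier among clones is never selected for k < n; the constant
  # sequence gives an all-zero code whose rank order differs from base
  outlier <- word_histogram(rank_binarize(rep(1, 8)), 3)
  expect_gt(dm_distance(base, outlier), 0)
  mixed <- list(base, base, outlier, base, base)
  totals <- rowSums(dm_matrix(mixed))
  expect_identical(which.max(totals), 3L)       # brute-force check
  for (k in 1:4) {
    expect_false(3L %in% select_representatives(mixed, k)$indices)
  }
  expect_error(select_representatives(list(), 1), "empty")
  expect_error(select_representatives(mixed, 6), "k must be")
})

test_that("average_rank_difference is the arithmetic mean over the models", {
  set.seed(9)
  test_p <- word_histogram(rank_binarize(runif(30)), 5)
  models <- lapply(1:10, function(i) word_histogram(rank_binarize(runif(30)), 5))
  ms <- structure(list(profiles = models, indices = 1:10, class = "normal"),
                  class = "model_set")
  expected <- mean(vapply(models, function(m) rank_difference_sum(test_p, m), 0))
  expect_equal(average_rank_difference(test_p, ms), expected)
  expect_identical(average_rank_difference(test_p, list(test_p, test_p)), 0)
  two <- list(models[[1]], test_p)
  s1 <- rank_difference_sum(test_p, models[[1]])
  expect_equal(average_rank_difference(test_p, two), mean(c(s1, 0)))
  expect_error(average_rank_difference(test_p, list()), "empty")
})
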