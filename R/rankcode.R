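#' Rank-binarize a circular sequence
#'
#' Bit `n` is 1 if `x[n] > x[n - 1]` and 0 otherwise (ties give 0). The
#' sequence is circular: the predecessor of the first element is the last,
#' so the code has the same length as the input and is independent of where
#' the sequence starts (a circular shift of the input circularly shifts the
#' code).
#'
#' @param x numeric vector of length >= 2, treated as circular.
#' @return a `rank_code`: integer vector of 0/1 bits.
#' @export
rank_binarize <- function(x) {
  x <- if (inherits(x, "waveform")) x$values else as.numeric(x)
  n <- length(x)
  if (n < 2L) stopf("rank_binarize needs at least 2 values")
  prev <- x[c(n, seq_len(n - 1L))]
  structure(as.integer(x > prev), class = "rank_code")
}

#' Word histogram, probabilities and ranks of a rank code
#'
#' Slides a window of `m` bits (stride 1, wrapping at the seam, so there are
#' exactly `length(code)` windows) over the circular code and interprets
#' each window as an integer, most-significant bit first in sequence order.
#' Word counts are normalized to probabilities and converted to ranks:
#' rank 1 is the most frequent word, ties broken by ascending word value.
#'
#' @param code a `rank_code` (or 0/1 integer vector).
#' @param m word width in bits, `1 <= m <= 16`, `m <= length(code)`.
#' @return a `rank_profile`: `list(m, counts, probs, ranks)`, each vector
#'   indexed by word value `0 .. 2^m - 1` (R index = word + 1).
#' @export
word_histogram <- function(code, m) {
  bits <- as.integer(unclass(code))
  if (!all(bits %in% c(0L, 1L))) stopf("code must be binary")
  if (!is_count(m) || m < 1 || m > 16) stopf("m must be an integer in 1..16")
  L <- length(bits)
  if (L < m) stopf("code shorter than word width")
  words <- integer(L)
  for (j in 0:(m - 1L)) {
    words <- words + bits[wrap_index(seq_len(L) + j, L)] * 2L^(m - 1L - j)
  }
  counts <- tabulate(words + 1L, nbins = 2L^m)
  probs <- counts / L
  ranks <- integer(2L^m)
  ranks[order(-counts, seq_len(2L^m))] <- seq_len(2L^m)
  structure(list(m = as.integer(m), counts = counts, probs = probs,
                 ranks = ranks), class = "rank_profile")
}

#' @export
print.rank_profile <- function(x, ...) {
  top <- order(x$ranks)[seq_len(min(3L, length(x$ranks)))]
  cat(sprintf("<rank_profile> m=%d, %d windows; top words: %s\n",
              x$m, sum(x$counts),
              paste(sprintf("%d (p=%.3f)", top - 1L, x$probs[top]),
                    collapse = ", ")))
  invisible(x)
}

#' Rank-profile serialization
#'
#' @param profile a `rank_profile`.
#' @return data frame with columns `word`, `count`, `prob`, `rank`.
#' @export
profile_table <- function(profile) {
  data.frame(word = seq_along(profile$counts) - 1L, count = profile$counts,
             prob = profile$probs, rank = profile$ranks)
}

check_same_m <- function(a, b) {
  if (!inherits(a, "rank_profile") || !inherits(b, "rank_profile")) {
    stopf("expected rank_profile objects")
  }
  if (a$m != b$m) stopf("profiles have different word widths (%d vs %d)", a$m, b$m)
}

#' Normalized rank-difference dissimilarity between two profiles
#'
#' `D_m(S1, S2) = sum_k |R1(w_k) - R2(w_k)| p1(w_k) p2(w_k) /
#' ((2^m - 1) sum_k p1(w_k) p2(w_k))`. Lies in `[0, 1]`, is 0 for identical
#' profiles and symmetric in its arguments. When the supports are disjoint
#' (`sum p1 p2 = 0`) the ratio is 0/0; it is defined here as 1, the
#' maximal-dissimilarity reading.
#'
#' @param a,b `rank_profile` objects with equal `m`.
#' @return scalar dissimilarity in `[0, 1]`.
#' @export
dm_distance <- function(a, b) {
  check_same_m(a, b)
  pp <- a$probs * b$probs
  den <- sum(pp)
  if (den == 0) return(1)
  sum(abs(a$ranks - b$ranks) * pp) / ((2^a$m - 1) * den)
}

#' Unnormalized rank-difference sum between two profiles
#'
#' `sum_k |R1(w_k) - R2(w_k)|` over words occurring in at least one of the
#' two profiles. This is the quantity averaged by
#' [average_rank_difference()]: its magnitude (tens to hundreds for m = 5)
#' matches the dividing lines used by the joint criterion, unlike the
#' normalized `D_m` in `[0, 1]`.
#'
#' @param a,b `rank_profile` objects with equal `m`.
#' @return non-negative scalar.
#' @export
rank_difference_sum <- function(a, b) {
  check_same_m(a, b)
  support <- a$probs + b$probs > 0
  sum(abs(a$ranks[support] - b$ranks[support]))
}

#' Pairwise D_m matrix
#'
#' @param profiles list of `rank_profile` objects with equal `m`.
#' @return symmetric numeric matrix of [dm_distance()] values.
#' @export
dm_matrix <- function(profiles) {
  n <- length(profiles)
  d <- matrix(0, n, n)
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- dm_distance(profiles[[i]], profiles[[j]])
    }
  }
  d
}

#' Select the most representative profiles of a set
#'
#' A profile's representativeness is the sum of its `D_m` distances to all
#' other profiles in the list; the `k` profiles with the smallest totals are
#' the model ("criterion") set, ties broken by input order. Returned in
#' input order.
#'
#' @param profiles non-empty list of `rank_profile` objects.
#' @param k number of representatives, `1 <= k <= length(profiles)`.
#' @param class optional class tag carried on the model set.
#' @return a `model_set`: `list(profiles, indices, class)`.
#' @export
select_representatives <- function(profiles, k, class = NULL) {
  if (!length(profiles)) stopf("empty profile list")
  if (!is_count(k) || k < 1 || k > length(profiles)) {
    stopf("k must be in 1..%d", length(profiles))
  }
  totals <- rowSums(dm_matrix(profiles))
  sel <- sort(order(totals, seq_along(totals))[seq_len(k)])
  structure(list(profiles = profiles[sel], indices = sel, class = class),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("<model_set> %d representatives%s: indices %s\n",
              length(x$profiles),
              if (is.null(x$class)) "" else paste0(" (", x$class, ")"),
              paste(x$indices, collapse = ", ")))
  invisible(x)
}

#' Average rank difference against a model set (dARD)
#'
#' Arithmetic mean of [rank_difference_sum()] between a test profile and
#' every model profile. This scalar is the shape term of the joint
#' criterion.
#'
#' @param test a `rank_profile`.
#' @param models a `model_set` (or plain list of `rank_profile`s).
#' @return non-negative scalar.
#' @export
average_rank_difference <- function(test, models) {
  profs <- if (inherits(models, "model_set")) models$profiles else models
  if (!length(profs)) stopf("empty model set")
  mean(vapply(profs, function(mdl) rank_difference_sum(test, mdl), 0))
}
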