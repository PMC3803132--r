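# Internal helpers shared across modules.

# Circular 1-based index: maps any integer onto 1..n.
wrap_index <- function(i, n) ((i - 1L) %% n) + 1L

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_matrix <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  r_src <- seq_len(h) - dr
  c_src <- seq_len(w) - dc
  r_ok <- r_src >= 1L & r_src <= h
  c_ok <- c_src >= 1L & c_src <= w
  out[r_ok, c_ok] <- m[r_src[r_ok], c_src[c_ok], drop = FALSE]
  out
}
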