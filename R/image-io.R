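#' Grayscale image container
#'
#' Images are plain integer matrices with intensities in `[0, 255]`,
#' indexed `image[row, col]` with row 1 at the top. `as_gray_image()`
#' validates and coerces a numeric matrix into this form.
#'
#' @param x numeric matrix with values in `[0, 255]`.
#' @return an integer matrix of class `gray_image`.
#' @export
as_gray_image <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stopf("image must be a numeric matrix")
  if (anyNA(x)) stopf("image contains NA intensities")
  if (min(x) < 0 || max(x) > 255) stopf("intensities must lie in [0, 255]")
  out <- matrix(as.integer(round(x)), nrow(x), ncol(x))
  class(out) <- c("gray_image", class(out))
  out
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, intensities %d..%d\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Read / write grayscale images
#'
#' The canonical on-disk format is plain-text PGM (magic `P2`), which needs
#' no external library. PNG is supported when the `png` package is
#' installed. `read_gray_image()` / `write_gray_image()` dispatch on the
#' file extension (`.pgm`, `.png`).
#'
#' @param path file path.
#' @return `read_*` returns a `gray_image`; `write_*` returns `path`
#'   invisibly.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pgm = read_pgm(path),
    png = read_png_gray(path),
    stopf("unsupported image extension: '%s' (use .pgm or .png)", ext)
  )
}

#' @param image a `gray_image` or numeric matrix in `[0, 255]`.
#' @rdname read_gray_image
#' @export
write_gray_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pgm = write_pgm(image, path),
    png = write_png_gray(image, path),
    stopf("unsupported image extension: '%s' (use .pgm or .png)", ext)
  )
}

#' @rdname read_gray_image
#' @export
read_pgm <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)
  tokens <- unlist(strsplit(paste(raw, collapse = " "), "[[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) < 4L || tokens[1] != "P2") {
    stopf("'%s' is not a plain (P2) PGM file", path)
  }
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  px <- as.integer(tokens[-(1:4)])
  if (length(px) != h * w) stopf("PGM pixel count mismatch in '%s'", path)
  m <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
  if (maxval != 255L) m <- round(m * (255 / maxval))
  as_gray_image(m)
}

#' @rdname read_gray_image
#' @export
write_pgm <- function(image, path) {
  image <- as_gray_image(image)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), "255"), con)
  # one image row per line; plain PGM caps line length at 70 chars, but
  # every consumer in this package (and netpbm) tokenises on whitespace
  apply(image, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

read_png_gray <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stopf("reading PNG requires the 'png' package; use PGM instead")
  }
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3L, dim(a)[3]), drop = FALSE], c(1, 2), mean)
  as_gray_image(round(a * 255))
}

write_png_gray <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stopf("writing PNG requires the 'png' package; use PGM instead")
  }
  image <- as_gray_image(image)
  png::writePNG(matrix(image / 255, nrow(image), ncol(image)), path)
  invisible(path)
}
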