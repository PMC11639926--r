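#' @useDynLib siribruise, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif median sd setNames
#' @importFrom utils read.csv write.csv
NULL

# ---- internal image helpers -------------------------------------------------

# validate a single-channel image: numeric matrix, finite, >= 0
check_gray <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  if (any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  if (any(x < 0))
    stop(sprintf("'%s' contains negative values", name), call. = FALSE)
  invisible(x)
}

check_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s have mismatched shapes (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

#' Quantize a unit-scale image to 8-bit levels
#'
#' Maps intensities in \[0,1\] to integer grey levels 0..255 with
#' round-half-up, clipping out-of-range values.  This is the single place the
#' package converts between its internal real-valued representation and the
#' 8-bit scale on which acquisition constants (such as the background mask
#' threshold) are defined.
#'
#' @param x numeric matrix (or vector) of intensities, nominally in \[0,1\].
#' @return integer grey levels in 0..255, same shape as `x`.
#' @export
quantize8 <- function(x) {
  lv <- floor(pmin(pmax(x, 0), 1) * 255 + 0.5)
  storage.mode(lv) <- "integer"
  lv
}

#' Linearly rescale image intensities to \[0,1\] over a pixel subset
#'
#' @param x numeric matrix.
#' @param mask logical matrix selecting the pixels that define the range; the
#'   rescaling is applied everywhere but pixels outside the mask are set to 0.
#'   `NULL` uses all pixels.
#' @return list with `image` (rescaled matrix) and `range` (the original
#'   c(min, max) used, so the scaling is invertible/reportable).
#' @export
rescale_unit <- function(x, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(x), ncol(x))
  m <- as_mask_matrix(mask)
  check_same_shape(x, m)
  v <- x[m]
  if (!length(v)) stop("empty mask: nothing to rescale", call. = FALSE)
  rng <- range(v)
  out <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) else x * 0
  out[!m] <- 0
  out <- pmin(pmax(out, 0), 1)
  list(image = out, range = rng)
}

# accept a siri_mask or a plain logical matrix
as_mask_matrix <- function(mask) {
  if (inherits(mask, "siri_mask")) mask <- mask$mask
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix or a 'siri_mask'", call. = FALSE)
  mask
}

# ---- plain-text / PNG image I/O --------------------------------------------

#' Read a grayscale image from PNG or PGM
#'
#' PNG files (8- or 16-bit, single channel; the first channel is taken if the
#' file has several) require the `png` package.  PGM files may be ASCII (P2)
#' or binary (P5).  Intensities are returned on the unit scale \[0,1\].
#'
#' @param path file path; format chosen by extension (.png, .pgm).
#' @return numeric matrix in \[0,1\].
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the 'png' package", call. = FALSE)
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(img)
  }
  if (ext == "pgm") return(read_pgm(path))
  stop("unsupported image format: ", ext, call. = FALSE)
}

#' Write a grayscale image to PNG or PGM
#'
#' @param x numeric matrix in \[0,1\].
#' @param path output path; format chosen by extension.
#' @param bits bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_gray <- function(x, path, bits = 8) {
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16", call. = FALSE)
  x <- pmin(pmax(x, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("writing PNG requires the 'png' package", call. = FALSE)
    png::writePNG(x, path, dpi = NULL)
    return(invisible(path))
  }
  if (ext == "pgm") return(write_pgm(x, path, bits = bits))
  stop("unsupported image format: ", ext, call. = FALSE)
}

# ASCII (P2) and binary (P5) portable graymap reader
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  # header tokens, skipping comments
  tokens <- integer(0)
  while (length(tokens) < 3) {
    ch <- rawToChar(readBin(con, "raw", 1))
    if (ch == "#") {
      repeat { c2 <- rawToChar(readBin(con, "raw", 1)); if (c2 %in% c("\n", "\r")) break }
    } else if (grepl("[0-9]", ch)) {
      num <- ch
      repeat {
        c2 <- rawToChar(readBin(con, "raw", 1))
        if (!grepl("[0-9]", c2)) break
        num <- paste0(num, c2)
      }
      tokens <- c(tokens, as.integer(num))
    }
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  n <- w * h
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    size <- if (maxval > 255) 2L else 1L
    vals <- readBin(con, "integer", n = n, size = size, signed = FALSE,
                    endian = "big")
  }
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(x, path, bits = 8) {
  maxval <- if (bits == 16L) 65535L else 255L
  lv <- floor(pmin(pmax(x, 0), 1) * maxval + 0.5)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(x), nrow(x)), as.character(maxval)), con)
  write(t(lv), file = con, ncolumns = min(ncol(x), 16))
  invisible(path)
}
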