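#' Coerce and validate a grayscale image
#'
#' Images throughout the package are plain numeric matrices with intensities
#' on the 8-bit convention (nominal range 0--255, stored as doubles). This
#' helper validates the contract every pipeline stage relies on: a finite
#' numeric matrix of size at least 3 x 3.
#'
#' @param x numeric matrix (or object coercible to one).
#' @param min_dim minimum number of rows and columns required.
#' @return the validated matrix (invisibly unchanged).
#' @export
as_gray_image <- function(x, min_dim = 3L) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("image must be a numeric matrix")
  }
  if (nrow(x) < min_dim || ncol(x) < min_dim) {
    stop(sprintf("image must be at least %dx%d", min_dim, min_dim))
  }
  if (!all(is.finite(x))) stop("image contains non-finite values")
  storage.mode(x) <- "double"
  x
}

#' Clip intensities to the 8-bit display range
#'
#' @param x numeric matrix.
#' @param lo,hi clipping bounds (default 0 and 255).
#' @return matrix with values forced into `[lo, hi]`.
#' @export
clip_gray <- function(x, lo = 0, hi = 255) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

# Replicate-pad a matrix by r rows/cols on every side.
pad_replicate <- function(x, r) {
  if (r <= 0) return(x)
  ri <- c(rep(1L, r), seq_len(nrow(x)), rep(nrow(x), r))
  ci <- c(rep(1L, r), seq_len(ncol(x)), rep(ncol(x), r))
  x[ri, ci, drop = FALSE]
}

# Normalized 1D Gaussian kernel truncated at `radius` (default 3 sigma).
gaussian_kernel <- function(sigma, radius = NULL) {
  if (sigma <= 0) stop("sigma must be positive")
  if (is.null(radius)) radius <- as.integer(ceiling(3 * sigma))
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with replicate borders, used for the bilateral
# guidance image, histogram smoothing and the SSIM window.
gaussian_blur <- function(img, sigma, radius = NULL) {
  k <- gaussian_kernel(sigma, radius)
  r <- (length(k) - 1L) %/% 2L
  p <- pad_replicate(img, r)
  h <- nrow(img); w <- ncol(img)
  # horizontal pass
  tmp <- matrix(0, h + 2 * r, w)
  for (i in seq_along(k)) {
    tmp <- tmp + k[i] * p[, i:(i + w - 1L), drop = FALSE]
  }
  out <- matrix(0, h, w)
  for (i in seq_along(k)) {
    out <- out + k[i] * tmp[i:(i + h - 1L), , drop = FALSE]
  }
  out
}

# Run a block with a private RNG stream; restores the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Read a grayscale image from disk
#'
#' Supports plain/binary PGM (`.pgm`) natively and PNG (`.png`) through the
#' optional \pkg{png} package. PNG samples in `[0, 1]` are rescaled to the
#' 0--255 convention; RGB(A) input is converted to luma by channel average.
#'
#' @param path file path; the format is inferred from the extension.
#' @return numeric matrix of intensities in `[0, 255]`.
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the 'png' package")
    }
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3L, dim(a)[3]), drop = FALSE], c(1, 2), mean)
    return(a * 255)
  }
  stop("unsupported image format: ", ext)
}

#' Write a grayscale image to disk
#'
#' @param img numeric matrix, intensities on the 0--255 scale (clipped on
#'   write).
#' @param path output path ending in `.pgm` or `.png`.
#' @param max_val maximum gray value recorded in PGM headers.
#' @export
write_gray <- function(img, path, max_val = 255L) {
  img <- clip_gray(as_gray_image(img))
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(write_pgm(img, path, max_val))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("writing PNG requires the 'png' package")
    }
    return(invisible(png::writePNG(img / 255, path)))
  }
  stop("unsupported image format: ", ext)
}

# Plain-text (P2) and binary (P5) PGM, 8- or 16-bit.
read_pgm <- function(path) {
  magic <- readChar(path, 2L, useBytes = TRUE)
  if (identical(magic, "P2")) {
    toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
    nums <- as.numeric(toks[-1])
    w <- nums[1]; h <- nums[2]; mx <- nums[3]
    vals <- nums[-(1:3)]
    if (length(vals) != w * h) stop("truncated PGM data")
  } else if (identical(magic, "P5")) {
    con <- file(path, "rb")
    on.exit(close(con))
    readChar(con, 2L, useBytes = TRUE)
    read_token <- function() {
      tok <- ""
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0) stop("truncated PGM header")
        if (ch == "#") {
          repeat {
            ch <- readChar(con, 1L, useBytes = TRUE)
            if (length(ch) == 0 || ch == "\n") break
          }
        } else if (grepl("[0-9]", ch)) {
          tok <- paste0(tok, ch)
        } else if (nzchar(tok)) {
          return(as.integer(tok))
        }
      }
    }
    w <- read_token(); h <- read_token(); mx <- read_token()
    n <- w * h
    if (mx < 256) {
      vals <- as.integer(readBin(con, "integer", n = n, size = 1L, signed = FALSE))
    } else {
      vals <- readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = "big")
    }
  } else {
    stop("not a PGM file: ", path)
  }
  img <- matrix(as.numeric(vals), nrow = h, ncol = w, byrow = TRUE)
  if (mx != 255) img <- img * (255 / mx)
  img
}

write_pgm <- function(img, path, max_val = 255L) {
  v <- matrix(as.integer(round(img * (max_val / 255))), nrow = nrow(img))
  lines <- c("P2", paste(ncol(img), nrow(img)), as.character(max_val),
             apply(v, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
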