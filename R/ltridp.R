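# Neighbour ordering for the 3x3 texture window: clockwise from the
# top-left corner, i.e. p1=NW, p2=N, p3=NE, p4=E, p5=SE, p6=S, p7=SW, p8=W.
# Any fixed circular order gives the same code up to a bit rotation; this
# one is the package constant.
ltridp_offsets <- function() {
  cbind(dr = c(-1L, -1L, -1L, 0L, 1L, 1L, 1L, 0L),
        dc = c(-1L, 0L, 1L, 1L, 1L, 0L, -1L, -1L))
}

#' Local tri-directional magnitude bits for one 3x3 window
#'
#' For each neighbour `p_t` (circular index, `t = 1..8`) two squared-difference
#' magnitudes are compared: `M1 = (p_{t-1} - p_c)^2 + (p_{t+1} - p_c)^2` and
#' `M2 = (p_{t-1} - p_c)^2 + (p_{t+1} - p_t)^2`. The bit for `t` is 1 when
#' `M1 >= M2` (ties count as 1). Eight bits form the texture code of the
#' centre pixel.
#'
#' @param window 3x3 numeric matrix.
#' @return integer vector of 8 bits (positions follow the package neighbour
#'   order, see [ltridp_map()]).
#' @export
ltridp_window <- function(window) {
  if (!is.matrix(window) || any(dim(window) != c(3L, 3L))) {
    stop("window must be a 3x3 matrix")
  }
  off <- ltridp_offsets()
  pc <- window[2, 2]
  p <- window[cbind(2L + off[, "dr"], 2L + off[, "dc"])]
  prev <- p[c(8L, 1:7)]
  nxt <- p[c(2:8, 1L)]
  m1 <- (prev - pc)^2 + (nxt - pc)^2
  m2 <- (prev - pc)^2 + (nxt - p)^2
  as.integer(m1 >= m2)
}

#' Per-pixel LTriDP texture map
#'
#' Slides the 3x3 tri-directional pattern over the image (replicate padding
#' at the border) and packs the 8 magnitude bits of each pixel into a code
#' `sum(2^(t-1) * bit_t)` in `[0, 255]`. Codes depend only on intensity
#' differences, so they are invariant to adding a constant to the image; a
#' constant image maps to code 255 everywhere.
#'
#' @param img numeric matrix, at least 3x3.
#' @return object of class `texture_map`: list with `code` (integer matrix)
#'   and `bits` (H x W x 8 integer array of the per-neighbour magnitude
#'   bits).
#' @export
ltridp_map <- function(img) {
  img <- as_gray_image(img)
  h <- nrow(img); w <- ncol(img)
  p <- pad_replicate(img, 1L)
  off <- ltridp_offsets()
  shift <- function(dr, dc) p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc), drop = FALSE]
  nb <- lapply(seq_len(8L), function(t) shift(off[t, 1], off[t, 2]))
  bits <- array(0L, c(h, w, 8L))
  code <- matrix(0L, h, w)
  for (t in seq_len(8L)) {
    prev <- nb[[if (t == 1L) 8L else t - 1L]]
    nxt <- nb[[if (t == 8L) 1L else t + 1L]]
    m1 <- (prev - img)^2 + (nxt - img)^2
    m2 <- (prev - img)^2 + (nxt - nb[[t]])^2
    b <- m1 >= m2
    bits[, , t] <- as.integer(b)
    code <- code + as.integer(b) * as.integer(2^(t - 1L))
  }
  structure(list(code = code, bits = bits), class = "texture_map")
}
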