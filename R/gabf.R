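#' Parameters for the Gaussian-adaptive bilateral filter
#'
#' @param sigma_spatial spatial kernel standard deviation in pixels.
#' @param sigma_range range kernel standard deviation in intensity units
#'   (default a tenth of the 8-bit dynamic range).
#' @param guidance_sigma standard deviation of the Gaussian low-pass that
#'   builds the guidance image.
#' @return object of class `gabf_params`.
#' @export
gabf_params <- function(sigma_spatial = 1.8, sigma_range = 25.5,
                        guidance_sigma = 1.0) {
  if (sigma_spatial <= 0 || sigma_range <= 0 || guidance_sigma <= 0) {
    stop("all GABF sigmas must be positive")
  }
  structure(list(sigma_spatial = sigma_spatial, sigma_range = sigma_range,
                 guidance_sigma = guidance_sigma), class = "gabf_params")
}

#' Gaussian low-pass guidance image
#'
#' Replicate-border separable Gaussian blur; preserves the image mean for a
#' constant image exactly and is the guidance signal for [gabf()].
#'
#' @param img numeric matrix.
#' @param guidance_sigma blur standard deviation (> 0).
#' @return blurred image, same shape.
#' @export
gaussian_guidance <- function(img, guidance_sigma) {
  if (guidance_sigma <= 0) stop("guidance_sigma must be positive")
  gaussian_blur(as_gray_image(img), guidance_sigma)
}

#' Gaussian-adaptive (guided) bilateral filter
#'
#' Joint bilateral filter whose range weights are computed on a Gaussian
#' low-pass guidance image rather than the input itself: for each pixel the
#' output is the normalized weighted mean of its neighbours within radius
#' `ceil(3 * sigma_spatial)`, weights = spatial Gaussian x
#' `exp(-(G(p) - G(q))^2 / (2 sigma_range^2))` with `G` the guidance.
#' Being a convex combination of neighbours it preserves constants exactly
#' and never leaves the input intensity range.
#'
#' @param img numeric matrix.
#' @param params a [gabf_params()].
#' @return filtered image, same shape.
#' @export
gabf <- function(img, params = gabf_params()) {
  img <- as_gray_image(img)
  stopifnot(inherits(params, "gabf_params"))
  r <- as.integer(ceiling(3 * params$sigma_spatial))
  G <- gaussian_guidance(img, params$guidance_sigma)
  h <- nrow(img); w <- ncol(img)
  ip <- pad_replicate(img, r)
  gp <- pad_replicate(G, r)
  num <- matrix(0, h, w); den <- matrix(0, h, w)
  two_ss <- 2 * params$sigma_spatial^2
  two_sr <- 2 * params$sigma_range^2
  for (dy in -r:r) {
    for (dx in -r:r) {
      ws <- exp(-(dy * dy + dx * dx) / two_ss)
      gs <- gp[(1 + r + dy):(h + r + dy), (1 + r + dx):(w + r + dx), drop = FALSE]
      is <- ip[(1 + r + dy):(h + r + dy), (1 + r + dx):(w + r + dx), drop = FALSE]
      wgt <- ws * exp(-(G - gs)^2 / two_sr)
      num <- num + wgt * is
      den <- den + wgt
    }
  }
  num / den
}
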