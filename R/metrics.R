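# --- ROI handling -----------------------------------------------------------

#' Resolve a region of interest to a logical mask
#'
#' ROIs for the homogeneous-region metrics can be given as a logical mask of
#' the image shape or as a half-open rectangle `c(r0, c0, r1, c1)` in
#' 0-based coordinates (rows `r0 <= r < r1`, columns `c0 <= c < c1`).
#'
#' @param roi logical matrix or length-4 numeric rectangle; `NULL` selects
#'   the whole image.
#' @param dim_img image dimensions `(height, width)`.
#' @return logical mask.
#' @export
roi_mask <- function(roi, dim_img) {
  if (is.null(roi)) return(matrix(TRUE, dim_img[1], dim_img[2]))
  if (is.logical(roi) && is.matrix(roi)) {
    stopifnot(all(dim(roi) == dim_img))
    if (!any(roi)) stop("ROI is empty")
    return(roi)
  }
  stopifnot(is.numeric(roi), length(roi) == 4L)
  r0 <- roi[1]; c0 <- roi[2]; r1 <- roi[3]; c1 <- roi[4]
  if (r0 < 0 || c0 < 0 || r1 > dim_img[1] || c1 > dim_img[2] ||
      r1 <= r0 || c1 <= c0) {
    stop("ROI rectangle out of bounds or empty")
  }
  m <- matrix(FALSE, dim_img[1], dim_img[2])
  m[(r0 + 1):r1, (c0 + 1):c1] <- TRUE
  m
}

# --- no-reference speckle metrics ------------------------------------------

#' Speckle index: std/mean over a homogeneous region
#'
#' @param img numeric matrix.
#' @param roi see [roi_mask()].
#' @return `sd/mean` of the ROI pixels (scale invariant).
#' @export
speckle_index <- function(img, roi = NULL) {
  v <- img[roi_mask(roi, dim(img))]
  m <- mean(v)
  if (m == 0) stop("ROI mean is zero; speckle index undefined")
  sd(v) / m
}

#' Speckle suppression index
#'
#' Ratio of the despeckled image's speckle index to the noisy image's on the
#' same homogeneous ROI. Values below 1 indicate speckle was suppressed;
#' lower is better.
#'
#' @param noisy,despeckled images of identical shape.
#' @inheritParams speckle_index
#' @return `SI(despeckled) / SI(noisy)`.
#' @export
ssi <- function(noisy, despeckled, roi = NULL) {
  stopifnot(all(dim(noisy) == dim(despeckled)))
  si_n <- speckle_index(noisy, roi)
  if (si_n == 0) stop("noisy ROI has zero variance; SSI undefined")
  speckle_index(despeckled, roi) / si_n
}

#' Speckle suppression and mean preservation index
#'
#' `SMPI = (R + |E[Xn] - E[Xd]|) * sd(Xd) / sd(Xn)` with
#' `R = (max(Xd) - min(Xd)) / E[Xn]`, max/min taken over the despeckled ROI
#' pixels. Penalizes filters that suppress variance by shifting the mean;
#' lower is better.
#'
#' @inheritParams ssi
#' @return SMPI value.
#' @export
smpi <- function(noisy, despeckled, roi = NULL) {
  stopifnot(all(dim(noisy) == dim(despeckled)))
  m <- roi_mask(roi, dim(noisy))
  xn <- noisy[m]; xd <- despeckled[m]
  sn <- sd(xn)
  if (sn == 0) stop("noisy ROI has zero variance; SMPI undefined")
  if (mean(xn) == 0) stop("noisy ROI mean is zero; SMPI undefined")
  R <- (max(xd) - min(xd)) / mean(xn)
  (R + abs(mean(xn) - mean(xd))) * sd(xd) / sn
}

# --- full-reference metrics -------------------------------------------------

#' Mean squared error and peak signal-to-noise ratio
#'
#' PSNR uses the 8-bit peak: `10 log10(255^2 / MSE)`. Identical images give
#' `MSE = 0` and `PSNR = Inf`.
#'
#' @param ground,test images of identical shape.
#' @return list with elements `mse` and `psnr` (dB).
#' @export
mse_psnr <- function(ground, test) {
  stopifnot(all(dim(ground) == dim(test)))
  mse <- mean((ground - test)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(255^2 / mse)
  list(mse = mse, psnr = psnr)
}

#' Structural similarity index
#'
#' Windowed SSIM with the canonical constants: 11x11 Gaussian window of
#' standard deviation 1.5, `K1 = 0.01`, `K2 = 0.03`, dynamic range
#' `L = 255`; local moments use replicate borders and the map is averaged
#' over all pixels.
#'
#' @param ground,test images of identical shape.
#' @return mean SSIM (1 for identical images).
#' @export
ssim <- function(ground, test) {
  stopifnot(all(dim(ground) == dim(test)))
  C1 <- (0.01 * 255)^2
  C2 <- (0.03 * 255)^2
  blur <- function(x) gaussian_blur(x, 1.5, radius = 5L)
  mu_x <- blur(ground); mu_y <- blur(test)
  sxx <- blur(ground^2) - mu_x^2
  syy <- blur(test^2) - mu_y^2
  sxy <- blur(ground * test) - mu_x * mu_y
  map <- ((2 * mu_x * mu_y + C1) * (2 * sxy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2))
  mean(map)
}

# 3x3 Laplacian with replicate borders.
laplacian <- function(img) {
  p <- pad_replicate(img, 1L)
  h <- nrow(img); w <- ncol(img)
  p[1:h, 2:(w + 1)] + p[3:(h + 2), 2:(w + 1)] +
    p[2:(h + 1), 1:w] + p[2:(h + 1), 3:(w + 2)] - 4 * img
}

#' Edge preservation index
#'
#' Normalized correlation of the mean-centred Laplacian responses of the
#' reference and test images. Reported in `[0, 1]`; a negative correlation
#' is clipped to 0 and flagged via the `"negative_correlation"` attribute.
#'
#' @param ground,test images of identical shape, neither constant.
#' @return EPI in `[0, 1]`.
#' @export
epi <- function(ground, test) {
  stopifnot(all(dim(ground) == dim(test)))
  hg <- laplacian(ground); hg <- hg - mean(hg)
  hd <- laplacian(test); hd <- hd - mean(hd)
  denom <- sqrt(sum(hg^2) * sum(hd^2))
  if (denom == 0) stop("constant image: EPI undefined")
  value <- sum(hg * hd) / denom
  out <- max(value, 0)
  if (value < 0) attr(out, "negative_correlation") <- TRUE
  out
}

#' Autocorrelation resolution metric
#'
#' Fraction of pixels in the normalized autocorrelation function of the
#' mean-removed image that exceed 75% of its peak. Broader correlation
#' (blur) gives larger alpha; white noise approaches `1/(M*N)` (only the
#' zero-lag peak). Invariant to intensity scaling.
#'
#' @param img non-constant numeric matrix.
#' @param threshold fraction of the peak (default 0.75).
#' @return alpha in `(0, 1]`.
#' @export
resolution_alpha <- function(img, threshold = 0.75) {
  x <- img - mean(img)
  if (all(x == 0)) stop("constant image: autocorrelation undefined")
  f <- fft(x)
  ac <- Re(fft(f * Conj(f), inverse = TRUE)) / length(x)
  mean(ac > threshold * ac[1, 1])
}

#' Full quality report for a despeckling run
#'
#' Computes every implemented criterion in one call: the no-reference
#' speckle statistics on a homogeneous ROI and, when a clean reference is
#' supplied, the full-reference measures.
#'
#' @param despeckled filtered image.
#' @param noisy speckled input image.
#' @param ground optional noise-free reference.
#' @param roi homogeneous ROI for SI/SSI/SMPI (see [roi_mask()]).
#' @return object of class `metrics_report` (named list; full-reference
#'   entries are `NA` without `ground`).
#' @export
quality_report <- function(despeckled, noisy, ground = NULL, roi = NULL) {
  rep <- list(
    si = speckle_index(despeckled, roi),
    ssi = ssi(noisy, despeckled, roi),
    smpi = smpi(noisy, despeckled, roi),
    alpha = resolution_alpha(despeckled),
    mse = NA_real_, psnr = NA_real_, ssim = NA_real_, epi = NA_real_,
    roi = roi
  )
  if (!is.null(ground)) {
    mp <- mse_psnr(ground, despeckled)
    rep$mse <- mp$mse
    rep$psnr <- mp$psnr
    rep$ssim <- ssim(ground, despeckled)
    rep$epi <- epi(ground, despeckled)
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Despeckling quality report\n")
  for (nm in c("si", "ssi", "smpi", "alpha", "mse", "psnr", "ssim", "epi")) {
    if (!is.na(x[[nm]])) cat(sprintf("  %-5s %g\n", toupper(nm), x[[nm]]))
  }
  invisible(x)
}
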