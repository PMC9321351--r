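#' Describe a synthetic cyst phantom
#'
#' A phantom is a noise-free scene on a homogeneous background containing
#' anechoic cysts (near-zero amplitude discs) and hyperechoic scatterer
#' regions whose amplitude is ten times the background, the classic test
#' object for ultrasound despeckling. Disc edges are softened by a short
#' linear taper so that filter evaluation is not dominated by synthetic
#' staircase edges.
#'
#' @param shape integer `(height, width)`.
#' @param cysts list of discs, each `list(center = c(row, col), radius = r)`,
#'   rendered at zero amplitude. 1-based pixel coordinates.
#' @param brights list of discs rendered at ten times `background_mean`.
#' @param background_mean background intensity (8-bit scale).
#' @param taper edge softening width in pixels.
#' @return object of class `phantom_spec`.
#' @seealso [generate_phantom()], [cyst_phantom_spec()]
#' @export
phantom_spec <- function(shape, cysts = list(), brights = list(),
                         background_mean = 100, taper = 2) {
  stopifnot(length(shape) == 2L, all(shape >= 3), background_mean >= 0,
            taper >= 0)
  shape <- as.integer(shape)
  check_disc <- function(d) {
    stopifnot(is.list(d), length(d$center) == 2L, d$radius > 0)
    if (d$center[1] - d$radius < 1 || d$center[1] + d$radius > shape[1] ||
        d$center[2] - d$radius < 1 || d$center[2] + d$radius > shape[2]) {
      stop("phantom region extends outside the image bounds")
    }
  }
  lapply(cysts, check_disc)
  lapply(brights, check_disc)
  for (a in cysts) for (b in brights) {
    d <- sqrt(sum((a$center - b$center)^2))
    if (d < a$radius + b$radius + taper) {
      stop("cyst and bright regions must not overlap")
    }
  }
  structure(list(shape = shape, cysts = cysts, brights = brights,
                 background_mean = background_mean, taper = taper),
            class = "phantom_spec")
}

#' Default three-cyst phantom layout
#'
#' Three anechoic cysts of graded radius plus three small bright scatterer
#' spots, scaled to the requested image size. The upper-left region holds the
#' features; the lower-right quadrant stays homogeneous so that speckle
#' statistics (SI/SSI/SMPI) can be measured on a clean background ROI.
#'
#' @param shape integer `(height, width)`, at least 64 x 64.
#' @param background_mean background intensity.
#' @return a [phantom_spec()].
#' @export
cyst_phantom_spec <- function(shape = c(256L, 256L), background_mean = 100) {
  stopifnot(all(shape >= 64))
  s <- min(shape) / 256
  disc <- function(r, c, rad) list(center = c(r, c) * s, radius = rad * s)
  phantom_spec(
    shape = shape,
    cysts = list(disc(60, 60, 18), disc(60, 196, 14), disc(196, 60, 22)),
    brights = list(disc(40, 128, 2.5), disc(128, 40, 2.5), disc(96, 96, 2.5)),
    background_mean = background_mean
  )
}

#' Render the noise-free phantom image
#'
#' The clean scene is deterministic: background at `background_mean`, cysts
#' at 0, bright regions at `10 * background_mean`, with a linear taper of
#' width `spec$taper` across each disc boundary. The `seed` argument exists
#' for interface symmetry with the stochastic generators and is unused.
#'
#' @param spec a [phantom_spec()].
#' @param seed ignored (the clean phantom is deterministic).
#' @return numeric matrix (clean image `Y`).
#' @export
generate_phantom <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$shape[1]; w <- spec$shape[2]
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  # soft membership of each disc: 1 inside, 0 outside, linear over the taper
  soft_mask <- function(discs) {
    m <- matrix(0, h, w)
    for (d in discs) {
      dist <- sqrt((rr - d$center[1])^2 + (cc - d$center[2])^2)
      if (spec$taper > 0) {
        wgt <- pmin(1, pmax(0, (d$radius - dist) / spec$taper + 1))
      } else {
        wgt <- as.numeric(dist <= d$radius)
      }
      m <- pmax(m, wgt)
    }
    m
  }
  wc <- soft_mask(spec$cysts)
  wb <- soft_mask(spec$brights)
  amp <- (1 - wc) + 9 * wb      # 0 in cysts, 1 background, 10 in brights
  spec$background_mean * amp
}

#' Unit-mean Rayleigh speckle field
#'
#' Fully developed speckle has Rayleigh-distributed amplitude in homogeneous
#' regions. Samples are drawn from a Rayleigh distribution and rescaled by
#' its theoretical mean so the field is unit mean; its coefficient of
#' variation (speckle index) is the Rayleigh constant
#' `sqrt(4/pi - 1) ~= 0.5227`.
#'
#' @param shape integer `(height, width)`.
#' @param seed RNG seed; identical seeds give bit-identical fields.
#' @return object of class `speckle_field` with elements `coefficients`
#'   (matrix), `sigma` (field standard deviation, here the Rayleigh constant)
#'   and `seed`.
#' @export
rayleigh_speckle <- function(shape, seed) {
  stopifnot(length(shape) == 2L, all(shape >= 1))
  shape <- as.integer(shape)
  coef <- with_seed(seed, {
    # Rayleigh(scale = 1) via inverse CDF; mean = sqrt(pi/2)
    u <- runif(prod(shape))
    matrix(sqrt(-2 * log(u)) / sqrt(pi / 2), shape[1], shape[2])
  })
  structure(list(coefficients = coef, sigma = sqrt(4 / pi - 1), seed = seed),
            class = "speckle_field")
}

#' Inject multiplicative speckle
#'
#' Applies the multiplicative noise model `X = Y * S + A`: `S` is a
#' unit-mean speckle field of standard deviation `sigma`, realised as
#' `S = 1 + sigma * G` with `G` standard normal and clipped below at zero;
#' `A` is optional zero-mean Gaussian additive noise (default off). The
#' output is clipped to the 8-bit range `[0, 255]`.
#'
#' @param clean noise-free image `Y` (matrix, intensities `>= 0`).
#' @param sigma speckle standard deviation in `[0, 1.5]`.
#' @param seed RNG seed.
#' @param additive_sigma standard deviation of the additive term `A`.
#' @return speckled image `X`, same shape as `clean`.
#' @export
apply_speckle <- function(clean, sigma, seed, additive_sigma = 0) {
  clean <- as_gray_image(clean)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("sigma must be a single non-negative number")
  }
  if (sigma > 1.5) stop("sigma must not exceed 1.5")
  if (sigma == 0 && additive_sigma == 0) return(clean)
  x <- with_seed(seed, {
    s <- pmax(1 + sigma * matrix(rnorm(length(clean)), nrow(clean)), 0)
    out <- clean * s
    if (additive_sigma > 0) {
      out <- out + additive_sigma * matrix(rnorm(length(clean)), nrow(clean))
    }
    out
  })
  clip_gray(x)
}

#' Multiply a clean image by a fully developed Rayleigh speckle field
#'
#' Convenience wrapper combining [rayleigh_speckle()] with the multiplicative
#' model (no additive term); used when the homogeneous-region amplitude
#' statistics, rather than a parametric noise level, are the quantity under
#' study.
#'
#' @inheritParams apply_speckle
#' @return speckled image clipped to `[0, 255]`.
#' @export
apply_rayleigh_speckle <- function(clean, seed) {
  clean <- as_gray_image(clean)
  s <- rayleigh_speckle(dim(clean), seed)
  clip_gray(clean * s$coefficients)
}
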