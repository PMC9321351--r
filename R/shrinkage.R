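#' Homomorphic log transform of a patch group
#'
#' Multiplicative speckle becomes (approximately) additive noise in the log
#' domain. Each `n x n` slice of the group tensor is vectorized column-major
#' into a column of an `(n^2) x k` matrix and `log(x + offset)` is applied
#' entrywise; the offset (default 1) keeps zero-valued cyst pixels finite
#' and is undone by [exp_transform()].
#'
#' @param group a `patch_group` (or bare numeric array / matrix).
#' @param offset positive constant added before the log.
#' @return object of class `log_group`: list with `matrix` (`n^2 x k`),
#'   `offset`, `k` and `patch_size`.
#' @export
log_transform <- function(group, offset = 1) {
  tensor <- if (inherits(group, "patch_group")) group$tensor else group
  if (is.matrix(tensor)) tensor <- array(tensor, c(dim(tensor), 1L))
  if (any(tensor < 0)) stop("intensities must be non-negative")
  if (offset < 0 || (offset == 0 && any(tensor == 0))) {
    stop("offset must be > 0 when zero intensities are present")
  }
  n <- dim(tensor)[1]; k <- dim(tensor)[3]
  m <- matrix(log(as.vector(tensor) + offset), n * dim(tensor)[2], k)
  structure(list(matrix = m, offset = offset, k = k, patch_size = n),
            class = "log_group")
}

#' Invert [log_transform()]
#'
#' @param lg a `log_group`, or a bare matrix with `offset` given.
#' @param offset offset used in the forward transform.
#' @return `n x n x k` array of intensities (`exp(x) - offset`, floored at 0).
#' @export
exp_transform <- function(lg, offset = NULL) {
  if (inherits(lg, "log_group")) {
    m <- lg$matrix; offset <- lg$offset; n <- lg$patch_size; k <- lg$k
  } else {
    m <- lg
    if (is.null(offset)) stop("offset required for a bare matrix")
    n <- as.integer(sqrt(nrow(m))); k <- ncol(m)
  }
  pmax(array(exp(as.vector(m)) - offset, c(n, n, k)), 0)
}

#' Log-domain noise standard deviation for a given speckle level
#'
#' For the parametric speckle model `S = 1 + sigma * G` (`G` standard
#' normal, floored at a small positive value so the logarithm stays finite)
#' this returns `sd(log S)`, computed by deterministic Gauss quadrature of
#' the first two moments against the normal density. For small `sigma` the
#' value approaches `sigma` itself (`log(1 + x) ~ x`).
#'
#' @param sigma_speckle speckle standard deviation, `>= 0`.
#' @param floor_value lower clamp on `S` before the log (default 1e-2).
#' @return log-domain standard deviation (monotone increasing in
#'   `sigma_speckle`).
#' @export
estimate_sigma_log <- function(sigma_speckle, floor_value = 1e-2) {
  if (sigma_speckle < 0) stop("sigma_speckle must be >= 0")
  if (sigma_speckle == 0) return(0)
  lf <- log(floor_value)
  gcut <- (floor_value - 1) / sigma_speckle
  mom <- function(p) {
    smooth <- integrate(function(g) log(1 + sigma_speckle * g)^p * dnorm(g),
                        lower = gcut, upper = 10,
                        rel.tol = 1e-10, abs.tol = 1e-12)$value
    smooth + lf^p * pnorm(gcut)
  }
  m1 <- mom(1); m2 <- mom(2)
  sqrt(max(m2 - m1^2, 0))
}

#' WNNM-style singular value shrinkage weights
#'
#' `w_i = r * sqrt(k) * sigma_log^2 / (sqrt(max(s_i^2 - k * sigma_log^2, 0))
#' + eps)`: components whose energy is explained by noise
#' (`s_i^2 <= k sigma^2`) receive an enormous weight and are zeroed by the
#' soft-threshold, while strong structure (large `s_i`) is barely touched.
#' Weights are non-decreasing as the singular values decrease.
#'
#' @param singular_values non-negative, sorted descending.
#' @param sigma_log log-domain noise standard deviation.
#' @param k group depth (number of stacked patches).
#' @param r positive scale constant of the weighting (default 1).
#' @param eps division-by-zero guard.
#' @return object of class `shrinkage_weights`: list with `w`, `r`, `epsilon`.
#' @export
shrinkage_weights <- function(singular_values, sigma_log, k, r = 1,
                              eps = 1e-16) {
  if (any(singular_values < 0) || sigma_log < 0 || r <= 0 || k < 1) {
    stop("invalid shrinkage inputs")
  }
  if (is.unsorted(rev(singular_values))) {
    stop("singular values must be sorted descending")
  }
  w <- r * sqrt(k) * sigma_log^2 /
    (sqrt(pmax(singular_values^2 - k * sigma_log^2, 0)) + eps)
  structure(list(w = w, r = r, epsilon = eps), class = "shrinkage_weights")
}

#' Weighted singular value soft-thresholding
#'
#' Returns `U diag(max(s - w, 0)) V^T` for the SVD `M = U diag(s) V^T`.
#' Never increases any singular value, the rank, or the Frobenius norm.
#'
#' @param M numeric matrix (finite entries).
#' @param w a [shrinkage_weights()] object or numeric vector of length
#'   `min(dim(M))` (recycled if scalar).
#' @return matrix of the same shape as `M`.
#' @export
svd_soft_threshold <- function(M, w) {
  if (!all(is.finite(M))) stop("matrix must be finite")
  if (inherits(w, "shrinkage_weights")) w <- w$w
  sv <- svd(M)
  w <- rep_len(w, length(sv$d))
  d <- pmax(sv$d - w, 0)
  sv$u %*% (d * t(sv$v))
}

#' Despeckle one patch group in the log domain
#'
#' The full per-group pipeline: log transform, unfold to an `(n^2) x k`
#' matrix, SVD, WNNM weights from the log-domain noise level, soft
#' thresholding, fold back and exponentiate. Group geometry (origins, MI
#' scores, depth) is preserved.
#'
#' @param group a `patch_group`.
#' @param sigma_speckle speckle standard deviation of the noise model.
#' @param r weight scale constant.
#' @param offset log-transform offset.
#' @param sigma_log optional precomputed log-domain noise sd (saves the
#'   quadrature when despeckling many groups).
#' @return a despeckled `patch_group`.
#' @export
despeckle_group <- function(group, sigma_speckle, r = 1, offset = 1,
                            sigma_log = NULL) {
  stopifnot(inherits(group, "patch_group"))
  if (is.null(sigma_log)) sigma_log <- estimate_sigma_log(sigma_speckle)
  lg <- log_transform(group, offset)
  sv <- svd(lg$matrix)
  w <- shrinkage_weights(sv$d, sigma_log, lg$k, r)$w
  d <- pmax(sv$d - w, 0)
  est <- sv$u %*% (d * t(sv$v))
  out <- group
  out$tensor <- exp_transform(est, offset)
  out
}

#' Re-aggregate despeckled groups into an image (destensorization)
#'
#' Every slice of every group is written back at its own origin and
#' overlapping contributions are combined as a weighted average with
#' `q_m = 1 - NMI(reference, slice m)`; the reference slice itself carries
#' weight 1 (its `1 - NMI` would be 0 and discard it). Pixels where all
#' covering slices have zero weight fall back to the unweighted mean of the
#' covering slices; pixels covered by no group are copied from `fallback`
#' with a warning.
#'
#' @param groups list of (despeckled) `patch_group` objects.
#' @param shape output `(height, width)`.
#' @param fallback image used for uncovered pixels (default 0 with warning).
#' @return numeric matrix of the aggregated image.
#' @export
destensorize <- function(groups, shape, fallback = NULL) {
  h <- shape[1]; w <- shape[2]
  num <- matrix(0, h, w); den <- matrix(0, h, w)
  usum <- matrix(0, h, w); ucnt <- matrix(0, h, w)
  for (g in groups) {
    stopifnot(inherits(g, "patch_group"))
    n <- dim(g$tensor)[1]
    k <- dim(g$tensor)[3]
    q <- c(1, pmax(1 - g$mi_scores[-1], 0))
    for (m in seq_len(k)) {
      rs <- (g$origins[m, 1] + 1L):(g$origins[m, 1] + n)
      cs <- (g$origins[m, 2] + 1L):(g$origins[m, 2] + n)
      slice <- g$tensor[, , m]
      num[rs, cs] <- num[rs, cs] + q[m] * slice
      den[rs, cs] <- den[rs, cs] + q[m]
      usum[rs, cs] <- usum[rs, cs] + slice
      ucnt[rs, cs] <- ucnt[rs, cs] + 1
    }
  }
  out <- matrix(0, h, w)
  pos <- den > 0
  out[pos] <- num[pos] / den[pos]
  zeroq <- !pos & ucnt > 0
  out[zeroq] <- usum[zeroq] / ucnt[zeroq]
  uncovered <- ucnt == 0
  if (any(uncovered)) {
    warning(sum(uncovered), " pixels not covered by any group")
    if (!is.null(fallback)) out[uncovered] <- fallback[uncovered]
  }
  out
}
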