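# Intensity -> histogram bin codes shared by the entropy estimators and the
# fast matcher: the 0--255 range is split into `bins` equal cells.
quantize_gray <- function(x, bins = 256L) {
  as.integer(pmin(bins - 1L, pmax(0L, floor(x * (bins / 256)))))
}

#' Shannon entropy of a patch (bits)
#'
#' Plug-in estimate from the normalized intensity histogram of the patch,
#' `H = -sum p log2 p` with empty bins contributing zero.
#'
#' @param patch numeric matrix or vector of intensities in `[0, 255]`.
#' @param bins number of histogram bins (default 256, one per 8-bit level).
#' @return entropy in bits, `0 <= H <= log2(min(bins, n))`.
#' @export
patch_entropy <- function(patch, bins = 256L) {
  if (bins < 2L) stop("bins must be >= 2")
  q <- quantize_gray(patch, bins)
  p <- tabulate(q + 1L, bins)
  p <- p[p > 0] / length(q)
  -sum(p * log2(p))
}

#' Joint entropy of two equally shaped patches (bits)
#'
#' Entropy of the joint two-dimensional histogram over co-located pixel
#' pairs. Satisfies `max(H(a), H(b)) <= H(a,b) <= H(a) + H(b)`.
#'
#' @param a,b patches of identical shape.
#' @inheritParams patch_entropy
#' @return joint entropy in bits.
#' @export
joint_entropy <- function(a, b, bins = 256L) {
  if (length(a) != length(b)) stop("patches must have the same shape")
  if (bins < 2L) stop("bins must be >= 2")
  code <- quantize_gray(a, bins) * bins + quantize_gray(b, bins)
  p <- as.numeric(table(code)) / length(code)
  -sum(p * log2(p))
}

#' Mutual information between two patches (bits)
#'
#' `MI(a, b) = H(a) + H(b) - H(a, b)`; non-negative, symmetric and bounded
#' by `min(H(a), H(b))`.
#'
#' @inheritParams joint_entropy
#' @return mutual information in bits.
#' @export
mutual_information <- function(a, b, bins = 256L) {
  mi <- patch_entropy(a, bins) + patch_entropy(b, bins) - joint_entropy(a, b, bins)
  max(mi, 0)
}

#' Normalized mutual information in `[0, 1]`
#'
#' `NMI = MI / max(eps, min(H(a), H(b)))`, so a patch compared with itself
#' scores 1 and statistically unrelated patches score near 0. Two constant
#' patches score 1 when their (binned) values agree and 0 otherwise; a
#' single constant patch scores 0 against anything non-constant. Keeping the
#' score in `[0, 1]` makes the aggregation weight `q = 1 - NMI` well posed.
#'
#' @inheritParams joint_entropy
#' @param eps guard against division by zero.
#' @return normalized MI in `[0, 1]`.
#' @export
normalized_mi <- function(a, b, bins = 256L, eps = 1e-16) {
  if (length(a) != length(b)) stop("patches must have the same shape")
  ha <- patch_entropy(a, bins)
  hb <- patch_entropy(b, bins)
  if (ha == 0 && hb == 0) {
    return(as.numeric(quantize_gray(a[1], bins) == quantize_gray(b[1], bins)))
  }
  mi <- max(ha + hb - joint_entropy(a, b, bins), 0)
  min(1, mi / max(eps, min(ha, hb)))
}
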