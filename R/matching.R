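#' Group similar patches within one superpixel cluster
#'
#' Implements the block-matching stage: reference patches are tiled over the
#' image at `stride` (with edge snapping so the last row/column of patch
#' positions is always included) and kept when their centre pixel belongs to
#' `cluster_id`. For every reference, all patches whose centre lies in the
#' same cluster (optionally restricted to a Chebyshev `search_radius` around
#' the reference, the BM3D-style tractability knob) are ranked by normalized
#' mutual information, descending, with ties broken by candidate origin in
#' (row, col) scan order. Candidates scoring at least `nmi_threshold` are
#' kept and the group is truncated to `k_max` slices including the
#' reference.
#'
#' The result is a list of `patch_group` objects: `tensor` is an
#' `n x n x k` stack whose first slice is the reference patch bit-exactly,
#' `origins` holds the 0-based (row, col) of each slice's top-left corner,
#' and `mi_scores` the NMI of each slice against the reference
#' (`mi_scores[1] == 1`). NMI scores are snapped to 12 decimal places before
#' thresholding and ranking so that equally informative candidates tie
#' exactly and the (row, col) tie-break is reproducible across platforms.
#'
#' @param img numeric matrix.
#' @param labels a `label_map` from [slic_superpixels()] (or an integer
#'   matrix of cluster ids).
#' @param cluster_id cluster to process (1-based label value).
#' @param patch_size odd patch side, typically 5 or 7.
#' @param k_max maximum group depth including the reference.
#' @param nmi_threshold minimum NMI for a candidate to join the group.
#' @param stride spacing of reference patches; default `patch_size - 1`
#'   (one-pixel overlap).
#' @param search_radius Chebyshev radius (in pixels, on patch origins)
#'   limiting the candidate search; `Inf` searches the whole cluster.
#' @param bins histogram bins for the MI estimate.
#' @return list of `patch_group` objects (empty, with a warning, for an
#'   empty cluster).
#' @export
group_patches <- function(img, labels, cluster_id, patch_size = 5L,
                          k_max = 16L, nmi_threshold = 0.3,
                          stride = patch_size - 1L, search_radius = Inf,
                          bins = 256L) {
  img <- as_gray_image(img)
  lab <- if (inherits(labels, "label_map")) labels$labels else labels
  stopifnot(is.matrix(lab), all(dim(lab) == dim(img)))
  patch_size <- as.integer(patch_size)
  if (patch_size < 3L || patch_size %% 2L == 0L) {
    stop("patch_size must be odd and >= 3")
  }
  if (patch_size > min(dim(img))) stop("patch larger than image")
  if (k_max < 1L) stop("k_max must be >= 1")
  if (stride < 1L) stop("stride must be >= 1")
  h <- nrow(img); w <- ncol(img)
  half <- patch_size %/% 2L

  member <- which(lab == cluster_id)
  if (length(member) == 0L) {
    warning("cluster ", cluster_id, " is empty; no groups built")
    return(list())
  }

  # tile reference origins (0-based) with edge snapping
  tile <- function(n) {
    s <- seq.int(0L, n - patch_size, by = stride)
    if (s[length(s)] != n - patch_size) s <- c(s, n - patch_size)
    s
  }
  refs <- as.matrix(expand.grid(r = tile(h), c = tile(w)))
  in_cluster <- lab[cbind(refs[, 1] + half + 1L, refs[, 2] + half + 1L)] == cluster_id
  refs <- refs[in_cluster, , drop = FALSE]
  if (nrow(refs) == 0L) {
    # no tiled position centres in this cluster: snap one reference so the
    # cluster still gets a group
    cen <- arrayInd(member, dim(lab))
    target <- colMeans(cen)
    d2 <- (cen[, 1] - target[1])^2 + (cen[, 2] - target[2])^2
    px <- cen[which.min(d2), ]
    refs <- matrix(c(pmin(pmax(px[1] - 1L - half, 0L), h - patch_size),
                     pmin(pmax(px[2] - 1L - half, 0L), w - patch_size)),
                   nrow = 1L)
  }

  qimg <- matrix(quantize_gray(img, bins), h, w)
  storage.mode(refs) <- "integer"
  storage.mode(lab) <- "integer"
  matched <- match_patches_cpp(qimg, lab, as.integer(cluster_id),
                               refs, patch_size,
                               as.integer(k_max), nmi_threshold,
                               as.double(search_radius), as.integer(bins))
  lapply(matched, function(m) {
    k <- nrow(m$origins)
    tensor <- array(0, c(patch_size, patch_size, k))
    for (s in seq_len(k)) {
      r0 <- m$origins[s, 1]; c0 <- m$origins[s, 2]
      tensor[, , s] <- img[(r0 + 1L):(r0 + patch_size),
                           (c0 + 1L):(c0 + patch_size)]
    }
    structure(list(tensor = tensor, origins = m$origins, mi_scores = m$nmi,
                   cluster_id = cluster_id),
              class = "patch_group")
  })
}
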