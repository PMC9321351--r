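#' Number of clusters from histogram peaks
#'
#' The cluster count K for superpixel segmentation is taken as the number of
#' local maxima of the smoothed 256-bin intensity histogram. The histogram is
#' smoothed with a Gaussian kernel and a peak must rise above its surrounding
#' saddles by a minimum prominence (a fraction of the pixel count) to be
#' counted; the global maximum's prominence is measured against the lowest
#' bin. When no peak qualifies, K falls back to 1.
#'
#' @param img numeric matrix, intensities on the 0--255 scale (clipped for
#'   binning).
#' @param smooth_width Gaussian smoothing width in bins (kernel standard
#'   deviation = `smooth_width / 2`); 0 disables smoothing.
#' @param min_prominence_frac minimum peak prominence as a fraction of the
#'   total pixel count.
#' @param k_max upper clamp for K.
#' @return integer K >= 1.
#' @export
count_histogram_peaks <- function(img, smooth_width = 5, min_prominence_frac = 0.01,
                                  k_max = 64L) {
  img <- as_gray_image(img, min_dim = 1L)
  bins <- tabulate(pmin(255L, pmax(0L, as.integer(floor(img)))) + 1L, 256L)
  if (smooth_width > 0) {
    k <- gaussian_kernel(smooth_width / 2)
    r <- (length(k) - 1L) %/% 2L
    padded <- c(rep(0, r), bins, rep(0, r))
    bins <- vapply(seq_len(256L), function(i) sum(k * padded[i:(i + 2L * r)]), 0)
  }
  thr <- min_prominence_frac * length(img)
  n <- length(bins)
  peaks <- 0L
  for (i in seq_len(n)) {
    lo <- if (i > 1L) bins[i - 1L] else -Inf
    hi <- if (i < n) bins[i + 1L] else -Inf
    if (bins[i] <= lo || bins[i] < hi) next   # plateau credit to leftmost bin
    # prominence: drop to the deepest saddle before a higher bin on each side
    left <- bins[seq_len(i - 1L)]
    right <- if (i < n) bins[(i + 1L):n] else numeric(0)
    saddle_side <- function(v) {
      higher <- which(v > bins[i])
      if (length(higher) == 0) return(if (length(v)) min(v) else min(bins))
      min(v[seq(from = length(v), to = max(higher))])
    }
    saddle_l <- saddle_side(rev(left))
    saddle_r <- saddle_side(right)
    prom <- bins[i] - max(saddle_l, saddle_r)
    if (prom >= thr) peaks <- peaks + 1L
  }
  max(1L, min(as.integer(k_max), peaks))
}

#' Texture-augmented SLIC superpixels
#'
#' Grayscale SLIC clustering with an extra texture feature: each pixel is
#' assigned to the nearest cluster centre under
#' `D = sqrt((dg/Ng)^2 + (dS/NS)^2 + (dT/NT)^2)` where `dg` is the absolute
#' gray difference, `dS` the Euclidean spatial distance and `dT` the absolute
#' difference of LTriDP texture codes. Centres start on a regular grid with
#' spacing `S = sqrt(P/K)`, each centre searches a `2S x 2S` window, and the
#' centre update averages only pixels whose gray value is within one cluster
#' standard deviation of the centre gray (restricted update; when the cluster
#' is gray-degenerate the full cluster is used). The procedure is
#' deterministic.
#'
#' @param img numeric matrix.
#' @param tex a [ltridp_map()] `texture_map` (or `NULL` to recompute).
#' @param K number of clusters (e.g. from [count_histogram_peaks()]).
#' @param iters number of assignment/update sweeps.
#' @param n_g,n_t normalizers for the gray and texture distances (defaults
#'   255, the maximum possible difference for 8-bit data).
#' @return object of class `label_map`: list with `labels` (integer matrix,
#'   values `1..K_eff`), `K` (number of non-empty clusters after compaction)
#'   and `centers` (data frame of gray/row/col/texture per cluster).
#' @export
slic_superpixels <- function(img, tex = NULL, K, iters = 10L, n_g = 255, n_t = 255) {
  img <- as_gray_image(img)
  if (is.null(tex)) tex <- ltridp_map(img)
  stopifnot(inherits(tex, "texture_map"))
  h <- nrow(img); w <- ncol(img); P <- h * w
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K > P) stop("K exceeds the number of pixels")
  S <- sqrt(P / K)
  tcode <- tex$code

  # regular grid of K seed centres
  gr <- max(1L, round(sqrt(K * h / w)))
  gc <- ceiling(K / gr)
  while (gr * gc < K) gr <- gr + 1L
  seeds <- expand.grid(
    r = (seq_len(gr) - 0.5) * h / gr,
    c = (seq_len(gc) - 0.5) * w / gc
  )[seq_len(K), ]
  cr <- seeds$r; cc <- seeds$c
  ri <- pmin(h, pmax(1L, round(cr))); ci <- pmin(w, pmax(1L, round(cc)))
  cg <- img[cbind(ri, ci)]
  ct <- as.numeric(tcode[cbind(ri, ci)])

  rowm <- matrix(seq_len(h), h, w)
  colm <- matrix(seq_len(w), h, w, byrow = TRUE)
  dist_to <- function(k, rows, cols) {
    dg <- abs(cg[k] - img[rows, cols, drop = FALSE]) / n_g
    ds <- sqrt((rowm[rows, cols, drop = FALSE] - cr[k])^2 +
               (colm[rows, cols, drop = FALSE] - cc[k])^2) / S
    dt <- abs(ct[k] - tcode[rows, cols, drop = FALSE]) / n_t
    sqrt(dg^2 + ds^2 + dt^2)
  }

  labels <- matrix(NA_integer_, h, w)
  for (it in seq_len(iters)) {
    best <- matrix(Inf, h, w)
    labels[] <- NA_integer_
    for (k in seq_len(K)) {
      rows <- max(1L, floor(cr[k] - S)):min(h, ceiling(cr[k] + S))
      cols <- max(1L, floor(cc[k] - S)):min(w, ceiling(cc[k] + S))
      d <- dist_to(k, rows, cols)
      sub <- best[rows, cols, drop = FALSE]
      upd <- d < sub
      sub[upd] <- d[upd]
      best[rows, cols] <- sub
      lsub <- labels[rows, cols, drop = FALSE]
      lsub[upd] <- k
      labels[rows, cols] <- lsub
    }
    # orphan pixels outside every search window: nearest centre globally
    if (anyNA(labels)) {
      orphan <- which(is.na(labels))
      bo <- best[orphan]
      for (k in seq_len(K)) {
        d <- dist_to(k, seq_len(h), seq_len(w))[orphan]
        take <- d < bo
        bo[take] <- d[take]
        labels[orphan[take]] <- k
      }
      best[orphan] <- bo
    }
    # centre update over the restricted set |gray(C_K) - gray(p)| < sigma_K
    for (k in seq_len(K)) {
      idx <- which(labels == k)
      if (length(idx) == 0L) next
      g <- img[idx]
      sk <- sd(g)
      sel <- if (is.na(sk) || sk == 0) rep(TRUE, length(idx)) else abs(cg[k] - g) < sk
      if (!any(sel)) sel <- rep(TRUE, length(idx))
      use <- idx[sel]
      cg[k] <- mean(img[use])
      cr[k] <- mean(rowm[use])
      cc[k] <- mean(colm[use])
    }
  }

  # compact away empty clusters so every surviving label is non-empty
  occupied <- sort(unique(as.integer(labels)))
  remap <- integer(K); remap[occupied] <- seq_along(occupied)
  labels[] <- remap[labels]
  centers <- data.frame(gray = cg[occupied], row = cr[occupied],
                        col = cc[occupied], texture = ct[occupied])
  structure(list(labels = labels, K = length(occupied), centers = centers),
            class = "label_map")
}

#' Export a label map as run-length encoded text
#'
#' @param lab a `label_map`.
#' @param path output file.
#' @export
write_labels_rle <- function(lab, path) {
  stopifnot(inherits(lab, "label_map"))
  r <- rle(as.integer(t(lab$labels)))
  lines <- c(paste("usdespeckle-labels", nrow(lab$labels), ncol(lab$labels), lab$K),
             paste(r$lengths, r$values, sep = "x", collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_labels_rle
#' @export
read_labels_rle <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  stopifnot(hdr[1] == "usdespeckle-labels")
  h <- as.integer(hdr[2]); w <- as.integer(hdr[3]); K <- as.integer(hdr[4])
  parts <- do.call(rbind, strsplit(strsplit(lines[2], " ")[[1]], "x"))
  v <- inverse.rle(list(lengths = as.integer(parts[, 1]),
                        values = as.integer(parts[, 2])))
  structure(list(labels = matrix(v, h, w, byrow = TRUE), K = K, centers = NULL),
            class = "label_map")
}
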