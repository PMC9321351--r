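# Independent brute-force oracles. These deliberately avoid the package's
# vectorized/compiled code paths: plain loops and direct evaluation of the
# defining formulas.

rand_patch <- function(n = 5L, lo = 0L, hi = 255L) {
  matrix(sample(lo:hi, n * n, replace = TRUE), n, n)
}

# --- texture ---------------------------------------------------------------

# Direct evaluation of the two magnitude formulas (no algebraic
# simplification), circular neighbour indexing t = 1..8 clockwise from NW.
oracle_ltridp_bits <- function(window) {
  off <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  pc <- window[2, 2]
  p <- numeric(8)
  for (t in 1:8) p[t] <- window[2 + off[t, 1], 2 + off[t, 2]]
  bits <- integer(8)
  for (t in 1:8) {
    prev <- p[ifelse(t == 1, 8, t - 1)]
    nxt <- p[ifelse(t == 8, 1, t + 1)]
    m1 <- (prev - pc)^2 + (nxt - pc)^2
    m2 <- (prev - pc)^2 + (nxt - p[t])^2
    bits[t] <- as.integer(m1 >= m2)
  }
  bits
}

oracle_ltridp_code_map <- function(img) {
  h <- nrow(img); w <- ncol(img)
  pad <- img[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      bits <- oracle_ltridp_bits(pad[i:(i + 2), j:(j + 2)])
      out[i, j] <- as.integer(sum(bits * 2^(0:7)))
    }
  }
  out
}

# --- information measures --------------------------------------------------

oracle_entropy <- function(patch, bins = 256L) {
  q <- floor(pmin(bins - 1, pmax(0, as.vector(patch) * bins / 256)))
  p <- as.numeric(table(q)) / length(q)
  -sum(p * log2(p))
}

oracle_joint_entropy <- function(a, b, bins = 256L) {
  qa <- floor(pmin(bins - 1, pmax(0, as.vector(a) * bins / 256)))
  qb <- floor(pmin(bins - 1, pmax(0, as.vector(b) * bins / 256)))
  p <- as.numeric(table(paste(qa, qb))) / length(qa)
  -sum(p * log2(p))
}

oracle_mi <- function(a, b, bins = 256L) {
  oracle_entropy(a, bins) + oracle_entropy(b, bins) -
    oracle_joint_entropy(a, b, bins)
}

oracle_nmi <- function(a, b, bins = 256L) {
  ha <- oracle_entropy(a, bins); hb <- oracle_entropy(b, bins)
  if (ha == 0 && hb == 0) {
    qa <- floor(a[1] * bins / 256); qb <- floor(b[1] * bins / 256)
    return(as.numeric(qa == qb))
  }
  min(1, max(oracle_mi(a, b, bins), 0) / max(1e-16, min(ha, hb)))
}

# Exhaustive grouping by NMI over all candidate origins (stride 1) whose
# patch centre carries the cluster label.
oracle_group <- function(img, labels, cluster, ref, patch, k_max, thr,
                         bins = 256L) {
  h <- nrow(img); w <- ncol(img); half <- patch %/% 2
  refp <- img[ref[1] + 1:patch, ref[2] + 1:patch]
  cand <- NULL
  for (r in 0:(h - patch)) {
    for (c in 0:(w - patch)) {
      if (r == ref[1] && c == ref[2]) next
      if (labels[r + half + 1, c + half + 1] != cluster) next
      nmi <- round(oracle_nmi(refp, img[r + 1:patch, c + 1:patch], bins), 12)
      if (nmi >= thr) cand <- rbind(cand, c(nmi, r, c))
    }
  }
  if (is.null(cand)) return(list(origins = matrix(ref, 1), nmi = 1))
  o <- order(-cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[o, , drop = FALSE]
  keep <- min(nrow(cand), k_max - 1)
  list(origins = rbind(ref, cand[seq_len(keep), 2:3, drop = FALSE]),
       nmi = c(1, cand[seq_len(keep), 1]))
}

# --- linear algebra --------------------------------------------------------

# SVD soft-threshold via an eigendecomposition of M^T M, independent of
# base::svd. Assumes M has full column rank (true a.s. for random input).
oracle_svd_soft_threshold <- function(M, w) {
  e <- eigen(crossprod(M), symmetric = TRUE)
  d <- sqrt(pmax(e$values, 0))
  V <- e$vectors
  U <- M %*% V %*% diag(1 / d)
  U %*% diag(pmax(d - rep_len(w, length(d)), 0)) %*% t(V)
}

# --- aggregation -----------------------------------------------------------

oracle_destensorize <- function(groups, shape) {
  num <- matrix(0, shape[1], shape[2]); den <- matrix(0, shape[1], shape[2])
  us <- matrix(0, shape[1], shape[2]); uc <- matrix(0, shape[1], shape[2])
  for (g in groups) {
    k <- dim(g$tensor)[3]; n <- dim(g$tensor)[1]
    for (m in seq_len(k)) {
      q <- if (m == 1) 1 else max(1 - g$mi_scores[m], 0)
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          r <- g$origins[m, 1] + i; c <- g$origins[m, 2] + j
          num[r, c] <- num[r, c] + q * g$tensor[i, j, m]
          den[r, c] <- den[r, c] + q
          us[r, c] <- us[r, c] + g$tensor[i, j, m]
          uc[r, c] <- uc[r, c] + 1
        }
      }
    }
  }
  out <- matrix(0, shape[1], shape[2])
  for (r in seq_len(shape[1])) {
    for (c in seq_len(shape[2])) {
      if (den[r, c] > 0) out[r, c] <- num[r, c] / den[r, c]
      else if (uc[r, c] > 0) out[r, c] <- us[r, c] / uc[r, c]
    }
  }
  out
}

# --- metrics (double-loop references) --------------------------------------

oracle_epi <- function(g, d) {
  lap <- function(x) {
    h <- nrow(x); w <- ncol(x)
    pad <- x[c(1, seq_len(h), h), c(1, seq_len(w), w)]
    out <- matrix(0, h, w)
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        out[i, j] <- pad[i, j + 1] + pad[i + 2, j + 1] + pad[i + 1, j] +
          pad[i + 1, j + 2] - 4 * pad[i + 1, j + 1]
      }
    }
    out
  }
  hg <- lap(g); hg <- hg - mean(hg)
  hd <- lap(d); hd <- hd - mean(hd)
  max(sum(hg * hd) / sqrt(sum(hg^2) * sum(hd^2)), 0)
}

oracle_alpha <- function(img, threshold = 0.75) {
  x <- img - mean(img)
  h <- nrow(x); w <- ncol(x)
  ac <- matrix(0, h, w)
  for (du in 0:(h - 1)) {
    for (dv in 0:(w - 1)) {
      s <- 0
      for (i in seq_len(h)) {
        for (j in seq_len(w)) {
          s <- s + x[i, j] * x[(i - 1 + du) %% h + 1, (j - 1 + dv) %% w + 1]
        }
      }
      ac[du + 1, dv + 1] <- s
    }
  }
  mean(ac > threshold * ac[1, 1])
}

# plain two-feature (gray + spatial) SLIC mirroring the package's
# initialization and restricted centre update, used for the
# texture-weight-off equivalence check
oracle_plain_slic <- function(img, K, iters) {
  h <- nrow(img); w <- ncol(img); P <- h * w
  S <- sqrt(P / K)
  gr <- max(1, round(sqrt(K * h / w))); gc <- ceiling(K / gr)
  while (gr * gc < K) gr <- gr + 1
  seeds <- expand.grid(r = (seq_len(gr) - 0.5) * h / gr,
                       c = (seq_len(gc) - 0.5) * w / gc)[seq_len(K), ]
  cr <- seeds$r; cc <- seeds$c
  ri <- pmin(h, pmax(1, round(cr))); ci <- pmin(w, pmax(1, round(cc)))
  cg <- img[cbind(ri, ci)]
  labels <- matrix(NA_integer_, h, w)
  for (it in seq_len(iters)) {
    best <- matrix(Inf, h, w)
    labels[] <- NA_integer_
    for (k in seq_len(K)) {
      for (i in max(1, floor(cr[k] - S)):min(h, ceiling(cr[k] + S))) {
        for (j in max(1, floor(cc[k] - S)):min(w, ceiling(cc[k] + S))) {
          d <- sqrt((abs(cg[k] - img[i, j]) / 255)^2 +
                    ((i - cr[k])^2 + (j - cc[k])^2) / S^2)
          if (d < best[i, j]) { best[i, j] <- d; labels[i, j] <- k }
        }
      }
    }
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (is.na(labels[i, j])) {
        for (k in seq_len(K)) {
          d <- sqrt((abs(cg[k] - img[i, j]) / 255)^2 +
                    ((i - cr[k])^2 + (j - cc[k])^2) / S^2)
          if (d < best[i, j]) { best[i, j] <- d; labels[i, j] <- k }
        }
      }
    }
    for (k in seq_len(K)) {
      idx <- which(labels == k)
      if (!length(idx)) next
      g <- img[idx]
      sk <- stats::sd(g)
      sel <- if (is.na(sk) || sk == 0) rep(TRUE, length(idx)) else abs(cg[k] - g) < sk
      if (!any(sel)) sel <- rep(TRUE, length(idx))
      use <- idx[sel]
      cg[k] <- mean(img[use])
      cr[k] <- mean((use - 1) %% h + 1)
      cc[k] <- mean((use - 1) %/% h + 1)
    }
  }
  labels
}
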