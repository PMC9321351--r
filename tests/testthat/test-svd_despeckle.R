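make_group <- function(tensor, origins, mi = NULL) {
  k <- dim(tensor)[3]
  structure(list(tensor = tensor, origins = origins,
                 mi_scores = if (is.null(mi)) rep(1, k) else mi,
                 cluster_id = 1L), class = "patch_group")
}

test_that("log/exp transforms are exact inverses", {
  expect_equal(log_transform(array(0, c(3, 3, 1)), offset = 1)$matrix[1, 1], 0)
  set.seed(41)
  tensor <- array(runif(5 * 5 * 4, 0, 255), c(5, 5, 4))
  lg <- log_transform(tensor, offset = 1)
  expect_equal(exp_transform(lg), tensor, tolerance = 1e-12)
  # multiplicative pairs become additive for strictly positive data
  y <- runif(100, 1, 10); s <- runif(100, 0.5, 2)
  expect_equal(log(y * s), log(y) + log(s), tolerance = 1e-12)
  m <- array(y * s, c(10, 10, 1))
  expect_equal(log_transform(m, offset = 1e-300)$matrix,
               matrix(log(y) + log(s), 100, 1), tolerance = 1e-9)
  expect_error(log_transform(array(-1, c(3, 3, 1))), "non-negative")
})

test_that("estimate_sigma_log tracks the log-domain noise level", {
  expect_identical(estimate_sigma_log(0), 0)
  # small-sigma regime: ln(1+x) ~ x; compare to a 1e6-sample Monte-Carlo
  got <- estimate_sigma_log(0.1)
  mc <- withr::with_seed(99, sd(log(1 + 0.1 * rnorm(1e6))))
  expect_lt(abs(got - mc) / mc, 0.05)
  expect_lt(abs(got - 0.1) / 0.1, 0.05)
  # monotone in sigma
  vals <- vapply(c(0.05, 0.1, 0.3, 0.6, 1.0), estimate_sigma_log, 0)
  expect_true(all(diff(vals) > 0))
  expect_error(estimate_sigma_log(-1), ">= 0")
})

test_that("shrinkage weights behave like WNNM", {
  s <- c(10, 5, 2, 0.5)
  expect_equal(shrinkage_weights(s, 0, k = 8)$w, rep(0, 4))
  # noise-dominated components get the 1/eps blow-up
  w <- shrinkage_weights(s, sigma_log = 1, k = 8)$w
  expect_true(all(w[s^2 <= 8] > 1e10))
  set.seed(42)
  for (i in 1:20) {
    sv <- sort(runif(6, 0, 20), decreasing = TRUE)
    w <- shrinkage_weights(sv, sigma_log = 0.3, k = 10, r = 1.5)$w
    expect_true(all(diff(w) >= 0))   # non-decreasing as s decreases
    expect_true(all(w >= 0) && all(is.finite(w)))
  }
  expect_error(shrinkage_weights(c(1, 5), 0.1, 4), "descending")
  expect_error(shrinkage_weights(c(-1, -2), 0.1, 4))
})

test_that("svd_soft_threshold equals the independent reconstruction oracle", {
  m <- diag(c(5, 3, 1))
  expect_equal(svd_soft_threshold(m, c(2, 2, 2)), diag(c(3, 1, 0)),
               tolerance = 1e-12)
  set.seed(43)
  M <- matrix(rnorm(25 * 8), 25, 8)
  expect_equal(svd_soft_threshold(M, rep(0, 8)), M, tolerance = 1e-10)
  # rank-1, weight above the top singular value: everything shrinks away
  r1 <- outer(rnorm(10), rnorm(6))
  expect_equal(svd_soft_threshold(r1, svd(r1)$d[1] + 1),
               matrix(0, 10, 6), tolerance = 1e-10)
  for (i in 1:25) {
    M <- matrix(rnorm(25 * 8, sd = 3), 25, 8)
    w <- runif(8, 0, 4)
    got <- svd_soft_threshold(M, w)
    ref <- oracle_svd_soft_threshold(M, w)
    expect_lt(norm(got - ref, "F"), 1e-8)
    # contraction properties
    expect_lte(sum(svd(got)$d), sum(svd(M)$d) + 1e-9)
    expect_lte(norm(got, "F"), norm(M, "F") + 1e-9)
    expect_true(all(svd(got)$d <= svd(M)$d + 1e-9))
  }
  expect_error(svd_soft_threshold(matrix(c(1, NA, 2, 3), 2), 0), "finite")
})

test_that("despeckle_group denoises without touching geometry", {
  set.seed(44)
  tensor <- array(runif(5 * 5 * 8, 10, 200), c(5, 5, 8))
  origins <- cbind(sample(0:20, 8), sample(0:20, 8))
  g <- make_group(tensor, origins)
  # sigma 0 is a no-op
  out0 <- despeckle_group(g, sigma_speckle = 0)
  expect_equal(out0$tensor, tensor, tolerance = 1e-8)
  expect_identical(out0$origins, origins)

  # identical clean patches + independent speckle: shrinkage moves every
  # slice closer to the truth
  clean <- matrix(runif(25, 50, 150), 5, 5)
  noisy <- array(0, c(5, 5, 8))
  withr::with_seed(7, {
    for (m in 1:8) {
      noisy[, , m] <- clean * pmax(1 + 0.2 * matrix(rnorm(25), 5, 5), 0)
    }
  })
  gn <- make_group(noisy, origins)
  den <- despeckle_group(gn, sigma_speckle = 0.2)
  err_in <- mean(vapply(1:8, function(m) sqrt(sum((noisy[, , m] - clean)^2)), 0))
  err_out <- mean(vapply(1:8, function(m) sqrt(sum((den$tensor[, , m] - clean)^2)), 0))
  expect_lt(err_out, err_in)
  expect_true(all(den$tensor >= 0))
})

test_that("destensorize equals the per-pixel accumulation oracle", {
  # single group, k = 1: the patch is copied to its origin
  p <- matrix(1:25, 5, 5)
  g1 <- make_group(array(p, c(5, 5, 1)), cbind(2L, 3L))
  out <- suppressWarnings(
    destensorize(list(g1), c(10, 10), fallback = matrix(0, 10, 10)))
  expect_equal(out[3:7, 4:8], p)
  expect_true(all(out[1:2, ] == 0))

  # overlapping identical slices agree on the overlap
  g2 <- make_group(array(rep(7, 50), c(5, 5, 2)),
                   rbind(c(0L, 0L), c(0L, 2L)), mi = c(1, 0.5))
  out2 <- suppressWarnings(destensorize(list(g2), c(8, 8)))
  expect_true(all(out2[1:5, 1:7] == 7))

  # random overlapping groups vs the brute-force oracle
  set.seed(45)
  groups <- lapply(1:6, function(i) {
    k <- sample(2:5, 1)
    make_group(array(runif(25 * k, 0, 255), c(5, 5, k)),
               cbind(sample(0:11, k, TRUE), sample(0:11, k, TRUE)),
               mi = c(1, runif(k - 1)))
  })
  got <- suppressWarnings(destensorize(groups, c(16, 16)))
  ref <- oracle_destensorize(groups, c(16, 16))
  expect_equal(got, ref, tolerance = 1e-12)

  # constant groups reconstruct the constant exactly
  gc <- lapply(1:3, function(i) {
    make_group(array(42, c(5, 5, 2)), rbind(c(0L, 0L), c(1L, 1L)) + 2L * i,
               mi = c(1, 1))  # q = 0 for the duplicate slice
  })
  outc <- suppressWarnings(destensorize(gc, c(12, 12)))
  covered <- outc != 0
  expect_true(all(outc[covered] == 42))

  # uncovered pixels fall back to the supplied image with a warning
  fb <- matrix(9, 10, 10)
  expect_warning(outf <- destensorize(list(g1), c(10, 10), fallback = fb),
                 "not covered")
  expect_true(all(outf[1:2, ] == 9))
})
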