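test_that("entropy examples and bounds", {
  expect_equal(patch_entropy(matrix(37, 5, 5)), 0)
  expect_equal(patch_entropy(c(rep(0, 8), rep(255, 8))), 1)
  set.seed(21)
  p <- rand_patch(5)
  expect_equal(patch_entropy(p), oracle_entropy(p), tolerance = 1e-12)
  expect_lte(patch_entropy(p), log2(25))
  expect_gte(patch_entropy(p), 0)
  expect_error(patch_entropy(p, bins = 1), "bins")
})

test_that("joint entropy examples and bounds", {
  set.seed(22)
  a <- rand_patch(5); b <- rand_patch(5)
  expect_equal(joint_entropy(a, a), patch_entropy(a), tolerance = 1e-12)
  expect_equal(joint_entropy(matrix(9, 5, 5), b), patch_entropy(b),
               tolerance = 1e-12)
  h <- joint_entropy(a, b)
  expect_gte(h + 1e-12, max(patch_entropy(a), patch_entropy(b)))
  expect_lte(h, patch_entropy(a) + patch_entropy(b) + 1e-12)
  expect_error(joint_entropy(a, rand_patch(7)), "shape")
})

test_that("MI identities hold against the brute-force histogram oracle", {
  set.seed(23)
  for (i in 1:60) {
    a <- rand_patch(5); b <- rand_patch(5)
    mi <- mutual_information(a, b)
    expect_equal(mi, max(oracle_mi(a, b), 0), tolerance = 1e-9)
    expect_equal(mi, mutual_information(b, a), tolerance = 1e-9)
    expect_gte(mi, 0)
    expect_lte(mi, min(patch_entropy(a), patch_entropy(b)) + 1e-9)
  }
  a <- rand_patch(5)
  expect_equal(mutual_information(a, a), patch_entropy(a), tolerance = 1e-12)
  expect_equal(mutual_information(matrix(4, 5, 5), a), 0)
})

test_that("normalized MI stays in [0,1] with the documented conventions", {
  set.seed(24)
  a <- rand_patch(5); b <- rand_patch(5)
  expect_equal(normalized_mi(a, a), 1)
  expect_equal(normalized_mi(matrix(1, 5, 5), a), 0)
  expect_equal(normalized_mi(matrix(8, 5, 5), matrix(8, 5, 5)), 1)
  expect_equal(normalized_mi(matrix(8, 5, 5), matrix(9, 5, 5)), 0)
  for (i in 1:40) {
    a <- rand_patch(5); b <- rand_patch(5)
    v <- normalized_mi(a, b)
    expect_equal(v, oracle_nmi(a, b), tolerance = 1e-9)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  # the compiled matcher scores identically to the R definition
  for (i in 1:40) {
    a <- rand_patch(5); b <- rand_patch(5)
    got <- usdespeckle:::nmi_cpp(as.vector(a), as.vector(b), 256L)
    expect_equal(got, normalized_mi(a, b), tolerance = 1e-9)
  }
})

test_that("group_patches matches the exhaustive search oracle", {
  set.seed(30)
  img <- matrix(as.numeric(sample(0:255, 16 * 16, replace = TRUE)), 16, 16)
  lab <- matrix(1L, 16, 16)
  groups <- group_patches(img, lab, 1L, patch_size = 5, k_max = 6,
                          nmi_threshold = 0.2, stride = 4)
  expect_gt(length(groups), 0)
  for (g in groups) {
    ref <- g$origins[1, ]
    o <- oracle_group(img, lab, 1, ref, 5, 6, 0.2)
    expect_equal(unname(g$origins) * 1, unname(o$origins) * 1)
    expect_equal(g$mi_scores, o$nmi, tolerance = 1e-9)
    # slice 0 is the reference patch bit-exactly
    expect_identical(g$tensor[, , 1], img[ref[1] + 1:5, ref[2] + 1:5])
    expect_false(any(duplicated(g$origins)))
  }
})

test_that("grouping honours ties, duplicates and coverage", {
  # constant cluster: all candidates tie at NMI 1, scan order decides
  img <- matrix(50, 12, 12)
  g <- group_patches(img, matrix(1L, 12, 12), 1L, patch_size = 5, k_max = 4,
                     stride = 4)[[1]]
  expect_identical(dim(g$tensor)[3], 4L)
  expect_equal(g$mi_scores, rep(1, 4))
  expect_equal(unname(g$origins[2:4, ]),
               rbind(c(0, 1), c(0, 2), c(0, 3)))   # (row, col) scan order

  # exact duplicate of the reference ranks first with NMI 1; coarse
  # intensity levels keep the competing patches below MI saturation
  set.seed(33)
  img2 <- matrix(sample(seq(0, 224, by = 32), 20 * 20, replace = TRUE), 20, 20)
  img2[9:13, 9:13] <- img2[1:5, 1:5]
  g2 <- group_patches(img2, matrix(1L, 20, 20), 1L, patch_size = 5,
                      k_max = 3, nmi_threshold = 0.1, stride = 19)[[1]]
  expect_equal(unname(g2$origins[2, ]), c(8, 8))
  expect_equal(g2$mi_scores[2], 1)

  # coverage: union of group footprints contains every pixel
  set.seed(34)
  img3 <- matrix(sample(0:255, 24 * 24, replace = TRUE), 24, 24)
  lab3 <- slic_superpixels(img3, K = 2, iters = 3)
  covered <- matrix(FALSE, 24, 24)
  for (k in seq_len(lab3$K)) {
    for (g in group_patches(img3, lab3, k, patch_size = 5, stride = 4)) {
      for (m in seq_len(nrow(g$origins))) {
        covered[g$origins[m, 1] + 1:5, g$origins[m, 2] + 1:5] <- TRUE
      }
    }
  }
  expect_true(all(covered))

  # empty cluster warns and returns nothing
  expect_warning(out <- group_patches(img, matrix(1L, 12, 12), 2L), "empty")
  expect_identical(out, list())
})

test_that("grouping is deterministic and respects the search radius", {
  set.seed(35)
  img <- matrix(sample(0:255, 30 * 30, replace = TRUE), 30, 30)
  lab <- matrix(1L, 30, 30)
  a <- group_patches(img, lab, 1L, patch_size = 5, search_radius = 6)
  b <- group_patches(img, lab, 1L, patch_size = 5, search_radius = 6)
  expect_identical(a, b)
  for (g in a) {
    d <- abs(sweep(g$origins, 2, g$origins[1, ]))
    expect_true(all(d <= 6))
  }
})
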