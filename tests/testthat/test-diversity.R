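test_that("relative abundance normalises rows and rejects all-zero samples", {
  tb <- ft(matrix(c(2, 2, 0, 5), nrow = 2, byrow = TRUE))
  rel <- relative_abundance(tb)
  expect_equal(unname(unclass(rel)[1, ]), c(0.5, 0.5))
  expect_equal(unname(unclass(rel)[2, ]), c(0, 1))
  expect_equal(unname(rowSums(unclass(rel))), c(1, 1), tolerance = 1e-9)
  bad <- ft(matrix(c(1, 1, 0, 0), nrow = 2, byrow = TRUE))
  expect_error(relative_abundance(bad), "S2")
})

test_that("Chao1 uses the bias-corrected form and never drops below observed", {
  res <- alpha_diversity(c(5, 2, 1, 1, 1))
  expect_equal(res$observed, 5)
  expect_equal(res$chao1, 6.5)
  expect_equal(alpha_diversity(c(0, 0, 0))$chao1, 0)
  # no singletons: correction vanishes
  res2 <- alpha_diversity(c(3, 3, 4))
  expect_equal(res2$chao1, res2$observed)
  expect_error(alpha_diversity(c(1.5, 2)), "integer")
  expect_error(alpha_diversity(c(-1, 2)), "non-negative")
  # property sweep vs an independent published implementation (vegan)
  withr::with_seed(11, {
    for (i in 1:25) {
      counts <- rpois(30, lambda = sample(1:3, 1))
      ours <- alpha_diversity(counts)
      expect_gte(ours$chao1, ours$observed)
      ref <- unname(vegan::estimateR(counts)["S.chao1"])
      expect_equal(ours$chao1, ref, tolerance = 1e-10)
    }
  })
})

test_that("Bray-Curtis matches hand arithmetic and its invariants", {
  tb <- ft(matrix(c(2, 1, 0, 0, 1, 3), nrow = 2, byrow = TRUE))
  d <- bray_curtis_matrix(tb, relative = FALSE)
  expect_equal(unclass(d)[1, 2], 5 / 7, tolerance = 1e-12)
  # identity, symmetry, range, disjoint supports
  withr::with_seed(4, {
    m <- matrix(rexp(60), nrow = 6)
    tb2 <- ft(m)
    d2 <- unclass(bray_curtis_matrix(tb2))
    expect_equal(max(abs(d2 - t(d2))), 0)
    expect_equal(unname(diag(d2)), rep(0, 6))
    expect_true(all(d2 >= 0 & d2 <= 1))
    # invariance under joint feature permutation
    perm <- sample(ncol(m))
    d3 <- unclass(bray_curtis_matrix(ft(m[, perm])))
    expect_equal(d2, d3, tolerance = 1e-12)
  })
  disj <- ft(matrix(c(1, 0, 0, 2), nrow = 2, byrow = TRUE))
  expect_equal(unclass(bray_curtis_matrix(disj))[1, 2], 1)
  zz <- ft(matrix(0, nrow = 2, ncol = 3))
  expect_error(bray_curtis_matrix(zz, relative = FALSE), "all-zero")
})

test_that("PCoA reconstructs Euclidean configurations", {
  # four collinear points, spacing 1
  pts <- matrix(0:3, ncol = 1, dimnames = list(paste0("S", 1:4), "x"))
  D <- as.matrix(dist(pts))
  ord <- pcoa(dist_matrix(D), n_axes = 3)
  ax1 <- ord$coordinates[, 1]
  expect_equal(as.matrix(dist(ax1)), D, ignore_attr = TRUE, tolerance = 1e-8)
  # sum of positive eigenvalues equals total centered sum of squares
  withr::with_seed(8, {
    X <- matrix(rnorm(5 * 3), 5, dimnames = list(paste0("S", 1:5), NULL))
    D2 <- as.matrix(dist(X))
    ord2 <- pcoa(dist_matrix(D2), n_axes = 4)
    css <- sum(scale(X, scale = FALSE)^2)
    expect_equal(sum(ord2$eigenvalues[ord2$eigenvalues > 0]), css,
                 tolerance = 1e-8)
    # full-rank reconstruction of all pairwise distances
    rec <- as.matrix(dist(ord2$coordinates))
    expect_equal(rec, D2, ignore_attr = TRUE, tolerance = 1e-8)
    expect_true(all(diff(ord2$eigenvalues) <= 1e-12))
    expect_true(all(ord2$proportion_explained >= 0 &
                    ord2$proportion_explained <= 1))
  })
  # all-identical samples
  z <- matrix(0, 3, 3, dimnames = list(paste0("S", 1:3), paste0("S", 1:3)))
  expect_equal(unname(pcoa(dist_matrix(z), 1)$coordinates[, 1]), rep(0, 3))
  asym <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(pcoa(asym), "symmetric")
})

test_that("PERMANOVA matches full enumeration, vegan, and relabeling invariance", {
  withr::with_seed(10, {
    X <- matrix(runif(6 * 4), 6, dimnames = list(paste0("S", 1:6), NULL))
    d <- bray_curtis_matrix(ft(X))
    g <- rep(c("CC", "AA"), each = 3)
    exact <- permanova(d, g, n_perm = "exact")
    expect_equal(exact$n_perm, 20)
    # brute-force enumeration oracle: p = share of arrangements with F >= F_obs
    combs <- utils::combn(6, 3)
    f_all <- apply(combs, 2, function(idx) {
      gg <- rep("B", 6); gg[idx] <- "A"
      pupomics:::permanova_f(unclass(d)^2, gg)
    })
    expect_equal(exact$p_value, mean(f_all >= exact$statistic - 1e-12))
    # pseudo-F agrees with vegan's adonis2
    ref <- vegan::adonis2(stats::as.dist(unclass(d)) ~ g, permutations = 99)
    expect_equal(exact$statistic, ref$F[1], tolerance = 1e-10)
    # relabeling invariance: permuting samples together with labels
    perm <- sample(6)
    d_perm <- dist_matrix(unclass(d)[perm, perm])
    expect_equal(permanova(d_perm, g[perm], n_perm = "exact")$statistic,
                 exact$statistic, tolerance = 1e-12)
  })
  expect_error(permanova(dist_matrix(matrix(0, 3, 3,
    dimnames = list(letters[1:3], letters[1:3]))), c("A", "A", "B")),
    "fewer than 2")
})

test_that("PERMANOVA p-values are uniform under the null on a small batch", {
  # the full 1000-simulation calibration lives with the acceptance checks;
  # here a Kolmogorov-Smirnov look at the null p distribution
  withr::with_seed(18, {
    p_vals <- vapply(seq_len(100), function(i) {
      X <- matrix(rlnorm(12 * 8), 12, dimnames = list(paste0("S", 1:12), NULL))
      d <- bray_curtis_matrix(ft(X))
      permanova(d, rep(c("CC", "AA"), each = 6), n_perm = 199,
                seed = i)$p_value
    }, numeric(1))
    ks <- suppressWarnings(stats::ks.test(p_vals, "punif"))
    expect_gt(ks$p.value, 0.01)
  })
})

test_that("rank-sum test enumerates exactly, handles ties, is scale invariant", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value,
               rank_sum_test(c(10, 20, 30), c(40, 50, 60))$p_value)
  # identical samples under the approximation path
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
  # matches stats::wilcox.test on random inputs
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- rnorm(7); y <- rnorm(9)
      expect_equal(rank_sum_test(x, y)$p_value,
                   stats::wilcox.test(x, y, exact = FALSE)$p.value,
                   tolerance = 1e-12)
    }
  })
})
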