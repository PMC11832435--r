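two_class_data <- function(seed, n = 16, p = 5, shift = 3) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    y <- rep(c("A", "B"), each = n / 2)
    X[y == "B", 1] <- X[y == "B", 1] + shift
    list(X = X, y = y)
  })
}

test_that("structural invariants hold on random fits", {
  withr::with_seed(1, {
    for (i in 1:20) {
      n <- sample(8:20, 1); p <- sample(3:10, 1)
      X <- matrix(rnorm(n * p), n, p)
      y <- sample(rep(c("A", "B"), length.out = n))
      while (min(base::table(y)) < 3) y <- sample(rep(c("A", "B"), length.out = n))
      mod <- fit_plsda(X, y)
      expect_equal(sum(mod$weights[, 1]^2), 1, tolerance = 1e-10)
      expect_equal(sum(mod$weights[, 2]^2), 1, tolerance = 1e-10)
      expect_lt(abs(sum(mod$scores[, 1] * mod$scores[, 2])), 1e-8)
      v <- vip_scores(mod)
      expect_equal(sum(v^2), length(mod$features), tolerance = 1e-8)
    }
  })
})

test_that("a single perfectly separating feature takes all the weight", {
  withr::with_seed(2, {
    X <- cbind(sep = rep(c(0, 10), each = 5))
    y <- rep(c("A", "B"), each = 5)
    mod <- fit_plsda(X, y, n_components = 1)
    expect_equal(unname(abs(mod$weights[1, 1])), 1, tolerance = 1e-12)
    expect_equal(unname(vip_scores(mod)), 1)  # p = 1 forces VIP = 1
  })
})

test_that("scores and weights match an independent SVD-based PLS solver", {
  d <- two_class_data(3, n = 8, p = 5)
  mod <- fit_plsda(d$X, d$y)
  ora <- svd_pls1_oracle(d$X, d$y)
  for (a in 1:2) {
    sgn <- sign(sum(mod$weights[, a] * ora$weights[, a]))
    expect_equal(unname(mod$weights[, a]), sgn * ora$weights[, a],
                 tolerance = 1e-6)
    expect_equal(unname(mod$scores[, a]), sgn * ora$scores[, a],
                 tolerance = 1e-6)
  }
})

test_that("degenerate inputs are rejected and zero-variance features dropped", {
  d <- two_class_data(4)
  expect_error(fit_plsda(d$X, rep("A", nrow(d$X))), "two classes")
  expect_error(fit_plsda(d$X[1:6, ], c("A", "A", "A", "B", "B", "A")),
               ">= 3 samples")
  expect_error(fit_plsda(d$X, d$y, n_components = 99), "rank")
  Xz <- cbind(d$X, flat = 1)
  expect_warning(mod <- fit_plsda(Xz, d$y), "zero-variance")
  v <- vip_scores(mod)
  expect_equal(unname(v["flat"]), 0)
  expect_equal(sum(v^2), ncol(d$X), tolerance = 1e-8)
})

test_that("the informative feature attains the maximum VIP", {
  hits <- vapply(1:50, function(s) {
    d <- two_class_data(s, n = 16, p = 10, shift = 3)
    v <- vip_scores(fit_plsda(d$X, d$y))
    names(which.max(v)) == "v1"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("abundance ratio follows the linear-mean and pseudocount policy", {
  m <- matrix(c(2, 2, 1, 1, 0, 0, 0.5, 0.5), ncol = 2,
              dimnames = list(paste0("S", 1:4), c("f1", "f2")))
  md <- sample_metadata(tibble::tibble(
    sample_id = rownames(m), group = c("AA", "AA", "CC", "CC"),
    timepoint = "HFD", generation = "pup", dyad_id = NA))
  tb <- feature_table(m, "lipid")
  r <- abundance_ratio(tb, md, "AA", "CC")
  expect_equal(unname(r["f1"]), 2)
  # f2: contrast mean 0 -> pseudocount half the smallest positive value
  expect_equal(unname(r["f2"]), 0.25 / 0.5)
  expect_error(abundance_ratio(tb, md, "CA", "CC"), "no samples")
  # identical groups give ratio 1
  m2 <- matrix(rep(c(1, 2), 4), ncol = 2, byrow = TRUE,
               dimnames = list(paste0("S", 1:4), c("f1", "f2")))
  expect_equal(unname(abundance_ratio(feature_table(m2, "lipid"), md,
                                      "AA", "CC")), c(1, 1))
})

test_that("the ratio-plus-VIP decision rule matches its boundary grid", {
  grid <- expand.grid(ratio = c(0.5, 0.66, 0.7, 1.0, 1.2, 1.25),
                      vip = c(0.9, 1.0, 1.1))
  res <- de_decision_rule(grid$ratio, grid$vip)
  manual_flag <- (grid$ratio < 0.66 | grid$ratio > 1.2) & grid$vip > 1
  expect_equal(res$flagged, manual_flag)
  expect_identical(res$direction[res$flagged & grid$ratio > 1.2][1], "elevated")
  expect_identical(res$direction[res$flagged & grid$ratio < 0.66][1], "depleted")
  # boundary values are strict: 0.66 and 1.2 themselves never flag
  expect_false(any(res$flagged[grid$ratio %in% c(0.66, 1.2)]))
  expect_false(any(res$flagged[grid$vip <= 1]))
  # tightening thresholds never enlarges the flagged set
  tight <- de_decision_rule(grid$ratio, grid$vip, ratio_low = 0.5,
                            ratio_high = 1.5, vip_threshold = 1.05)
  expect_true(all(which(tight$flagged) %in% which(res$flagged)))
})

test_that("planted fold-1.5 lipids are recovered at paper thresholds; nulls pass rarely", {
  sens_spec <- vapply(1:40, function(s) {
    withr::with_seed(s, {
      n <- 20  # 10 per group
      grp <- rep(c("AA", "CC"), each = 10)
      base_mean <- 100
      m <- sapply(1:10, function(j) {
        mu <- base_mean
        v <- stats::rnorm(n, mu, 0.2 * mu)  # CV 20%
        pmax(v, 1)
      })
      # first 5 lipids carry a 1.5-fold elevation in AA
      m[grp == "AA", 1:5] <- m[grp == "AA", 1:5] * 1.5
      dimnames(m) <- list(paste0("S", 1:n), paste0("L", 1:10))
      md <- sample_metadata(tibble::tibble(
        sample_id = rownames(m), group = grp, timepoint = "HFD",
        generation = "pup", dyad_id = NA))
      res <- screen_de_lipids(feature_table(m, "lipid"), md, "AA")
      c(sens = mean(res$flagged[1:5]), fpr = mean(res$flagged[6:10]))
    })
  }, numeric(2))
  expect_gte(mean(sens_spec["sens", ]), 0.8)
  expect_lte(mean(sens_spec["fpr", ]), 0.1)
})

test_that("metabolite content applies C * A / m", {
  expect_equal(metabolite_content(10, 2, 25), 0.8)
  expect_equal(metabolite_content(7.3, 1, 1), 7.3)
  expect_error(metabolite_content(10, 2, 0), "m must be > 0")
})
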