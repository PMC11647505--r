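test_that("median-of-ratios size factors match hand-computed cases", {
  k <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("f", 1:3), c("a", "b")))
  expect_equal(size_factors(k), c(a = 1, b = 1))
  k2 <- k
  k2[, 2] <- 2 * k2[, 1]
  expect_equal(size_factors(k2), c(a = 1 / sqrt(2), b = sqrt(2)))
  # single sample
  expect_equal(size_factors(k[, 1, drop = FALSE]), c(a = 1))
  # no feature nonzero everywhere
  k3 <- matrix(c(5, 0, 0, 7), 2, dimnames = list(NULL, c("a", "b")))
  expect_error(size_factors(k3), "pseudo")
  expect_silent(size_factors(k3, pseudo_reference = TRUE))
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(41)
  k <- matrix(rnbinom(300 * 6, mu = 150, size = 10), 300,
              dimnames = list(NULL, paste0("s", 1:6)))
  k <- sweep(k, 2, c(0.6, 1, 1.4, 0.8, 1.2, 1.9), "*")
  k <- round(k)
  ours <- size_factors(k)
  ref <- DESeq2::estimateSizeFactorsForMatrix(k)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
})

test_that("scaling one sample scales its factor relative to the rest", {
  set.seed(53)
  k <- matrix(rnbinom(500 * 4, mu = 200, size = 10), 500,
              dimnames = list(NULL, paste0("s", 1:4)))
  f0 <- size_factors(k)
  k2 <- k
  k2[, 2] <- k2[, 2] * 3
  f1 <- size_factors(k2)
  expect_equal(f1[2] / f1[1], 3 * f0[2] / f0[1], tolerance = 1e-9)
  expect_equal(f1[3] / f1[4], f0[3] / f0[4], tolerance = 1e-9)
})

test_that("moment dispersion estimates recover truth at large n", {
  cond <- rep(c("WT", "KO"), each = 500)
  set.seed(61)
  # NB with alpha = 0.1: estimates concentrate near truth
  k <- matrix(rnbinom(150 * 1000, mu = 200, size = 10), 150)
  a <- estimate_dispersion(k, rep(1, 1000), cond)
  expect_true(all(a > 0.07 & a < 0.13))
  # Poisson: estimates collapse toward the floor
  kp <- matrix(rpois(150 * 1000, 100), 150)
  ap <- estimate_dispersion(kp, rep(1, 1000), cond)
  expect_true(mean(ap) < 0.002)
  # constant counts: exactly the floor
  kc <- matrix(7, 3, 4)
  expect_equal(unname(estimate_dispersion(kc, rep(1, 4),
                                          rep(c("A", "B"), 2))),
               rep(1e-8, 3))
  expect_error(estimate_dispersion(kc, rep(1, 4),
                                   c("A", "A", "A", "B")),
               "replicates")
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
})

test_that("Wald test handles symmetric, zero and all-zero features", {
  k <- matrix(c(50, 60, 55, 52, 58, 56,   # no change
                0, 0, 0, 40, 44, 38,      # WT all zero
                0, 0, 0, 0, 0, 0),        # all zero
              nrow = 3, byrow = TRUE,
              dimnames = list(c("flat", "up", "none"), NULL))
  cond <- rep(c("WT", "KO"), each = 3)
  res <- nb_wald_test(k, cond, sf = rep(1, 6))
  flat <- res[res$feature_key == "flat", ]
  expect_lt(abs(flat$log2fc), 0.1)
  expect_gt(flat$pvalue, 0.5)
  expect_false(flat$significant)
  up <- res[res$feature_key == "up", ]
  expect_true(is.finite(up$log2fc) && up$log2fc > 4)
  none <- res[res$feature_key == "none", ]
  expect_true(is.na(none$pvalue) && is.na(none$padj))
  # BH m excludes the all-zero feature
  expect_equal(res$padj[!is.na(res$padj)],
               p.adjust(res$pvalue[!is.na(res$pvalue)], "BH"))
  expect_error(nb_wald_test(k, rep("WT", 6)), "two conditions")
})

test_that("identical groups give null-like results across many features", {
  feats <- tibble::tibble(
    feature_key = sprintf("f%03d", 1:300), class = "miRNA",
    ref_group = list("x"), base_mean = 200, dispersion = 0.1, log2fc = 0
  )
  cs <- simulate_counts(feats, sim_config(seed = 71, n_per_condition = 3))
  res <- nb_wald_test(cs$counts, cs$samples$condition)
  expect_lt(mean(res$pvalue < 0.05), 0.12)
  expect_lt(abs(median(res$log2fc)), 0.15)
  expect_equal(sum(res$significant), 0)
})

test_that("overlap analysis reports shared and concordant calls", {
  mk <- function(keys, lfc, padj) {
    tibble::tibble(feature_key = keys, log2fc = lfc, padj = padj)
  }
  a <- mk(c("x", "y", "z", "w"), c(-2, -1.5, -3, 0.2),
          c(0.01, 0.01, 0.01, 0.9))
  b <- mk(c("x", "y", "z", "w"), c(-2, 1.8, -2.5, 0.1),
          c(0.2, 0.01, 0.02, 0.01))
  ov <- overlap_analysis(a, b)
  expect_equal(ov$n_a, 3)
  expect_equal(ov$n_b, 3)
  expect_equal(sort(ov$intersection), c("y", "z"))
  expect_equal(ov$frac_of_a, 2 / 3)
  expect_equal(ov$down_both, "z")
  expect_equal(sort(ov$concordant), "z")
  # identical sets overlap fully
  ov2 <- overlap_analysis(a, a)
  expect_equal(ov2$frac_of_a, 1)
  # empty B side
  b0 <- mk("x", -2, 0.9)
  expect_equal(overlap_analysis(a, b0)$n_both, 0)
  expect_warning(overlap_analysis(a, mk("q", -2, 0.01)), "disjoint")
})
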