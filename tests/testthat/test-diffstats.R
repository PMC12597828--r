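test_that("median-of-ratios matches symmetry, scaling and the DESeq2 oracle", {
  m <- matrix(rep(c(10, 20, 30, 40), 3), ncol = 3)
  expect_equal(unname(median_of_ratios(m)), rep(1, 3))

  set.seed(61)
  counts <- matrix(rnbinom(400, mu = 100, size = 20), ncol = 4)
  doubled <- counts
  doubled[, 3] <- doubled[, 3] * 2
  sf <- median_of_ratios(doubled)
  expect_equal(sf[3] / sf[1], 2, tolerance = 0.1, ignore_attr = TRUE)

  # single-feature table: factors proportional to that feature's counts
  one <- matrix(c(10, 20, 40), 1)
  expect_equal(unname(median_of_ratios(one) / median_of_ratios(one)[1]),
               c(1, 2, 4))

  # equivariance: scaling one sample's counts by c scales its factor by c
  # relative to the others (size factors are defined up to a common rescale)
  allnz <- matrix(rnbinom(600, mu = 200, size = 50) + 1, ncol = 3)
  sc <- allnz
  sc[, 2] <- sc[, 2] * 3
  r0 <- median_of_ratios(allnz); r1 <- median_of_ratios(sc)
  expect_equal((r1[2] / r1[1]) / (r0[2] / r0[1]), 3,
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(median_of_ratios(matrix(c(0, 1, 1, 0), 2)), "nonzero")

  # independent cross-check against DESeq2's estimator
  skip_if_not_installed("DESeq2")
  expect_equal(unname(median_of_ratios(counts)),
               unname(DESeq2::estimateSizeFactorsForMatrix(counts)),
               tolerance = 1e-6)
})

test_that("NB Wald test recovers planted fold changes and flags degenerate input", {
  # 10% planted fraction keeps the median-of-ratios reference unconfounded
  sim <- simulate_replicate_peak_counts(600, 60, lfc = 2, dispersion = 0.02,
                                        depth_factors = rep(1, 12),
                                        base_mean = 500, seed = 62)
  res <- nb_wald_test(sim$counts, sim$conditions)
  expect_lt(abs(median(res$lfc[sim$truth]) - 2), 0.2)
  expect_lt(abs(median(res$lfc[!sim$truth])), 0.1)

  # identical counts in both conditions -> lfc exactly 0
  counts <- rbind(flat = rep(25, 6), zero = rep(0, 6),
                  other = c(40, 44, 36, 41, 39, 40))
  res2 <- nb_wald_test(counts, rep(c("a", "b"), each = 3),
                       size_factors = rep(1, 6))
  expect_equal(res2["flat", "lfc"], 0)
  expect_true(is.na(res2["zero", "pvalue"]))

  expect_error(nb_wald_test(counts, rep("a", 6)), "two conditions")
  expect_error(nb_wald_test(counts, c("a", "a", "a", "a", "b", "b")[1:5]),
               "per sample")
  expect_error(nb_wald_test(counts[, 1:3], c("a", "a", "b"),
                            size_factors = rep(1, 3)), "two samples")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(!is.unsorted(q))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significance presets and the low-count prefilter apply as published", {
  expect_true(significant_features(1.2, 0.04, "gene"))
  expect_false(significant_features(0.8, 0.04, "gene"))
  expect_true(significant_features(0.8, 0.04, "peak"))
  expect_false(significant_features(1.2, 0.06, "gene"))
  expect_false(significant_features(1.0, 0.04, "gene"))  # strict lfc bound

  counts <- rbind(a = c(11, 12, 13), b = c(10, 50, 50), c = c(90, 11, 12))
  expect_equal(unname(filter_low_counts(counts)), c(TRUE, FALSE, TRUE))
  # count of exactly 10 fails "greater than ten"
  expect_false(filter_low_counts(rbind(c(10, 11, 11)))[1])
})

test_that("genes are grouped by edge distance to their domain's TetO", {
  dom <- gr1("chrS", 1e6, 5e6)
  dom$teto_pos <- 3e6
  teto <- gr1("chrS", 3e6 - 100, 3e6 + 100)
  genes <- gr1("chrS",
               c(2.99e6, 3.05e6, 3.15e6, 3.6e6, 2.55e6, 7e6),
               c(3.01e6, 3.08e6, 3.2e6, 3.7e6, 2.7e6, 7.1e6))
  g <- gene_distance_groups(genes, teto, dom)
  expect_equal(as.character(g),
               c("overlapping_TetO", "0-100kb", "100-250kb", ">500kb",
                 "250-500kb", "outside_domain"))

  # gene spanning two domains goes to the nearer TetO, with a warning
  doms <- gr1("chrS", c(1e6, 5.5e6), c(5.4e6, 9e6))
  doms$teto_pos <- c(3e6, 6e6)
  wide <- gr1("chrS", 5.3e6, 5.6e6)
  expect_warning(gw <- gene_distance_groups(wide, teto, doms), "nearer")
  expect_equal(as.character(gw), "250-500kb")  # 5.6e6 edge is 400 kb from 6e6
})

test_that("distance-group shift tests match the U oracle and detect shifts", {
  # brute-force concordant-pair count on a 3 vs 3 toy set
  x <- c(5, 9, 11); ctrl <- c(1, 7, 10)
  res <- group_shift_test(c(x, ctrl),
                          factor(rep(c("g", "outside_domain"), each = 3)))
  u_brute <- sum(outer(x, ctrl, ">")) + 0.5 * sum(outer(x, ctrl, "=="))
  expect_equal(res$U, u_brute)

  # identical distributions: U near n1 n2 / 2, p not significant
  set.seed(63)
  z <- rnorm(50)
  res0 <- group_shift_test(c(z, z),
                           factor(rep(c("g", "outside_domain"), each = 50)))
  expect_equal(res0$U, 50 * 50 / 2)
  expect_gt(res0$pvalue, 0.5)

  # constant shift of 3 at n = 50: overwhelming evidence
  res3 <- group_shift_test(c(z + 3, z),
                           factor(rep(c("g", "outside_domain"), each = 50)))
  expect_lt(res3$pvalue, 1e-6)

  # empty non-control group reports NA, BH across groups
  lfc <- c(z, z + 1)
  grp <- factor(rep(c("outside_domain", "far"), each = 50),
                levels = c("outside_domain", "far", "empty"))
  resm <- group_shift_test(lfc, grp)
  expect_true(is.na(resm$pvalue[resm$group == "empty"]))
  expect_true(all(resm$qvalue >= resm$pvalue, na.rm = TRUE))
  expect_error(group_shift_test(z, factor(rep("g", 50))), "control")
})
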