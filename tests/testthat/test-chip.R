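test_that("peak filtering cuts at the signal threshold and keeps overlap maxima", {
  pk <- make_peaks(c(100, 300, 500), c(200, 400, 600), c(34.9, 35.0, 40))
  kept <- filter_peaks(pk, 35)
  expect_equal(kept$signalValue, c(35.0, 40))  # threshold inclusive

  ov <- make_peaks(c(100, 150), c(200, 250), c(50, 60))
  expect_equal(filter_peaks(ov, 35)$signalValue, 60)

  dis <- make_peaks(c(100, 300, 500), c(150, 350, 550), c(40, 50, 60))
  expect_length(filter_peaks(dis, 35), 3)

  # overlap chains resolve by single linkage, ties leftmost
  chain <- make_peaks(c(100, 180, 260), c(200, 280, 360), c(50, 50, 40))
  expect_equal(GenomicRanges::start(filter_peaks(chain, 35)), 100)
})

test_that("center-resize scaling averages peak-center signal", {
  tr <- make_track(1, 10000, 2)
  pk <- make_peaks(c(1000, 5000), c(1200, 5200), c(40, 40))
  expect_equal(scaling_factor(tr, pk, "center_resize"), 2)
  expect_equal(scale_track(tr, 2)$score, 1)

  # two peaks whose 10 bp center windows average 1 and 3 -> factor 2
  tr2 <- make_track(c(1, 1081, 1121, 5081, 5121),
                    c(1080, 1120, 5080, 5120, 9000),
                    c(0, 1, 0, 3, 0))
  pk2 <- make_peaks(c(1001, 5001), c(1200, 5200), c(40, 40))
  expect_equal(scaling_factor(tr2, pk2, "center_resize"), 2)

  # scale equivariance: scaling_factor(track / c) = factor / c
  tr3 <- tr2
  tr3$score <- tr3$score / 4
  expect_equal(scaling_factor(tr3, pk2, "center_resize"),
               scaling_factor(tr2, pk2, "center_resize") / 4)
})

test_that("flank-background scaling ignores the peak center", {
  # center value 10 within +-1.5 kb, flanks at 1
  ctr <- 10000
  tr <- make_track(c(1, ctr - 1500, ctr + 1501),
                   c(ctr - 1501, ctr + 1500, 20000),
                   c(1, 10, 1))
  pk <- make_peaks(ctr - 99, ctr + 100, 40)  # center exactly at ctr
  expect_equal(scaling_factor(tr, pk, "flank_background"), 1)
  tr0 <- make_track(1, 20000, 0)
  expect_error(scaling_factor(tr0, pk, "flank_background"), "zero")
})

test_that("profile matrices bin anchor windows and average per column", {
  tr <- make_track(1, 100000, 5)
  anchors <- make_peaks(c(20000, 50000, 80000), c(20200, 50200, 80200),
                        c(40, 40, 40))
  pm <- profile_matrix(tr, anchors, half_window = 2500, bin = 10)
  expect_equal(ncol(pm$matrix), 500)  # 5,000 / 10
  expect_equal(nrow(pm$matrix), 3)
  expect_true(all(pm$matrix == 5))
  expect_equal(unname(pm$mean_curve), rep(5, 500))

  # single anchor: mean curve equals its row
  pm1 <- profile_matrix(tr, anchors[1], half_window = 1000, bin = 10)
  expect_equal(unname(pm1$mean_curve), unname(pm1$matrix[1, ]))

  # anchors at the extent edge are dropped with a warning
  edge <- make_peaks(c(500, 50000), c(700, 50200), c(40, 40))
  expect_warning(pme <- profile_matrix(tr, edge, 2500, 10), "dropped")
  expect_equal(nrow(pme$matrix), 1)
  expect_error(suppressWarnings(
    profile_matrix(tr, edge[1], 2500, 10)), "outside")

  # summit-centered when summits exist: a signal block placed at the
  # summit lands in the bin just right of center, not at the peak midpoint
  tr2 <- make_track(c(1, 30005, 30015), c(30004, 30014, 100000), c(0, 9, 0))
  pk2 <- make_peaks(29000, 31000, 40, summit = 30005)
  pm2 <- profile_matrix(tr2, pk2, half_window = 500, bin = 10)
  expect_equal(unname(which.max(pm2$matrix[1, ])), 51)
  expect_equal(ncol(pm2$matrix), 100)
})

test_that("differential FLAG labels follow the lfc and signal-floor rule", {
  counts <- rbind(worked = c(47, 49, 11),
                  lowcov = c(18, 22, 1),
                  flat = c(30, 30, 30))
  res <- differential_flag_peaks(counts, on_samples = 1:2, off_samples = 3)
  # ON average 48, lfc = log2(49/12) ~ 2.03 > 1 and 48 > 2^4.5
  expect_equal(res["worked", "lfc"], log2(49 / 12))
  expect_true(res["worked", "differential"])
  # large fold change but ON average 20 < 2^4.5: not differential
  expect_false(res["lowcov", "differential"])
  expect_gt(res["lowcov", "lfc"], 1)
  # ON == OFF -> lfc 0
  expect_equal(res["flat", "lfc"], 0)
  expect_false(res["flat", "differential"])

  # monotone in ON counts: raising an ON replicate never turns a
  # differential peak into a non-differential one
  up <- counts
  up["worked", 1] <- up["worked", 1] + 100
  res_up <- differential_flag_peaks(up, 1:2, 3)
  expect_true(res_up["worked", "differential"])
  expect_error(differential_flag_peaks(counts, 1:2, 3,
                                       size_factors = c(1, 1)), "per sample")
})

test_that("TetO enrichment is coverage over mean input, control-normalizable", {
  expect_equal(teto_enrichment(100, c(8, 12)), 10)
  expect_equal(teto_enrichment(100, c(8, 12), control_ratio = 2), 5)
  expect_equal(teto_enrichment(10, c(10, 10)), 1)
  expect_error(teto_enrichment(10, numeric(0)), "non-empty")
  expect_error(teto_enrichment(10, c(0, 0)), "positive")
})

test_that("consensus peaks require 50% coverage by both replicates", {
  pooled <- make_peaks(c(1000, 5000, 9000), c(1999, 5999, 9999),
                       c(40, 40, 40), chrom = "chr1")
  # first pooled peak 60% covered by each replicate, second only 40% by rep1
  rep1 <- gr1("chr1", c(1000, 5600, 9000), c(1599, 5999, 9999))
  rep2 <- gr1("chr1", c(1400, 5000, 9000), c(1999, 5599, 9999))
  out <- consensus_peaks(pooled, rep1, rep2)
  expect_equal(GenomicRanges::start(out), c(1000, 9000))

  # blacklist removes, non-canonical chromosomes removed
  bl <- gr1("chr1", 9500, 9600)
  expect_equal(GenomicRanges::start(consensus_peaks(pooled, rep1, rep2,
                                                    blacklist = bl)), 1000)
  odd <- make_peaks(100, 400, 40, chrom = "chrUn_gl000220")
  expect_length(consensus_peaks(odd, gr1("chrUn_gl000220", 100, 400),
                                gr1("chrUn_gl000220", 100, 400)), 0)
  # output is always a subset of the pooled set
  expect_true(all(GenomicRanges::start(out) %in% GenomicRanges::start(pooled)))
})
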