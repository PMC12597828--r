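test_that("binarization is strict at the threshold and drops missing fragments", {
  b <- binarize(c(25.0, 25.01, -10, NA, 30), threshold = 25)
  expect_equal(b$obs, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(b$index, c(1L, 2L, 3L, 5L))
  expect_error(binarize(numeric(0)), "empty")
  expect_error(binarize(c(NA_real_, NA_real_)), "observed")
})

test_that("Viterbi matches the brute-force path oracle on random sequences", {
  set.seed(21)
  for (n in c(1, 2, 5, 8, 12)) {
    for (rep in 1:10) {
      obs <- runif(n) < 0.4
      bf <- brute_force_decode(matrix(obs, nrow = 1))
      vit <- decode_states(obs) == "domain"
      expect_identical(unname(vit), unname(bf$best_path[1, ]))
    }
  }
  # alternative parameters change the decision boundary consistently too
  pars <- hmm_params(transition_prob = 0.05, p_emit_pos_given_domain = 0.7,
                     p_emit_neg_given_nochange = 0.9)
  for (rep in 1:20) {
    obs <- runif(10) < 0.5
    bf <- brute_force_decode(matrix(obs, nrow = 1), pars)
    expect_identical(unname(decode_states(obs, pars) == "domain"),
                     unname(bf$best_path[1, ]))
  }
})

test_that("persistence dominates isolated evidence", {
  expect_true(all(decode_states(rep(FALSE, 50)) == "no_change"))
  # one positive amid 20 negatives each side: switching twice costs more
  one <- c(rep(FALSE, 20), TRUE, rep(FALSE, 20))
  expect_true(all(decode_states(one) == "no_change"))
  # a sustained run of 30 positives is decoded as domain, flanks stay clean
  run <- c(rep(FALSE, 30), rep(TRUE, 30), rep(FALSE, 30))
  st <- decode_states(run)
  expect_equal(st, rep(c("no_change", "domain", "no_change"), each = 30))
})

test_that("the minimal detectable isolated run under default parameters is 9", {
  flanked <- function(k) c(rep(FALSE, 30), rep(TRUE, k), rep(FALSE, 30))
  expect_equal(sum(decode_states(flanked(9)) == "domain"), 9)
  expect_equal(sum(decode_states(flanked(8)) == "domain"), 0)
  # log-odds oracle for the same fact: a run of k positives flips iff its
  # cumulative emission log-ratio beats two transitions
  lo <- log(0.6 / 0.02); cost <- 2 * log(1e6)
  expect_true(9 * lo > cost && 8 * lo < cost)
})

test_that("run filtering keeps runs of at least min_run fragments", {
  st <- function(lens, vals) rep(c("no_change", "domain")[vals + 1], lens)
  r <- filter_runs(st(c(5, 21, 3), c(0, 1, 0)), 21)
  expect_equal(nrow(r), 1)
  expect_equal(r$n_fragments, 21)
  expect_equal(nrow(filter_runs(st(c(5, 20, 3), c(0, 1, 0)), 21)), 0)
  r2 <- filter_runs(st(c(2, 21, 4, 5, 1), c(0, 1, 0, 1, 0)), 21)
  expect_equal(nrow(r2), 1)  # the 5-run is dropped
  # idempotence: re-filtering a pure retained run changes nothing
  r3 <- filter_runs(rep("domain", 40), 21)
  expect_equal(r3$n_fragments, 40)
})

test_that("merge/draft stages respect their distance and count thresholds", {
  runs <- function(n) data.frame(first = NA, last = NA, n_fragments = n)
  # two 21-fragment runs 90 kb apart merge into one 42-fragment region
  # that survives the count filter; at 110 kb they stay separate and both
  # fall below it
  m90 <- merge_and_draft(runs(c(21, 21)), c(1e6, 1.19e6),
                         c(1.1e6, 1.29e6), filter_params("main"))
  expect_equal(nrow(m90), 1)
  expect_equal(m90$n_positive, 42)
  m110 <- merge_and_draft(runs(c(21, 21)), c(1e6, 1.21e6),
                          c(1.1e6, 1.31e6), filter_params("main"))
  expect_equal(nrow(m110), 0)
  # regions with 39 positive fragments are dropped, 40 kept
  expect_equal(nrow(merge_and_draft(runs(39), 1e6, 1.2e6,
                                    filter_params("main"))), 0)
  expect_equal(nrow(merge_and_draft(runs(40), 1e6, 1.2e6,
                                    filter_params("main"))), 1)
  # draft merge at 1.4 vs 1.6 Mb gaps
  d14 <- merge_and_draft(runs(c(40, 40)), c(1e6, 2.9e6), c(1.5e6, 3.4e6),
                         filter_params("main"))
  expect_equal(nrow(d14), 1)
  d16 <- merge_and_draft(runs(c(40, 40)), c(1e6, 3.1e6), c(1.5e6, 3.6e6),
                         filter_params("main"))
  expect_equal(nrow(d16), 2)
})

test_that("degron preset widens both merge distances", {
  runs <- function(n) data.frame(first = NA, last = NA, n_fragments = n)
  # 2.4 Mb gap drafts into one domain under degron, 2.6 Mb stays split
  d24 <- merge_and_draft(runs(c(40, 40)), c(1e6, 3.9e6), c(1.5e6, 4.4e6),
                         filter_params("degron"))
  expect_equal(nrow(d24), 1)
  d26 <- merge_and_draft(runs(c(40, 40)), c(1e6, 4.1e6), c(1.5e6, 4.6e6),
                         filter_params("degron"))
  expect_equal(nrow(d26), 2)
  # 150 kb run gap merges under degron (200 kb) but not under main (100 kb)
  g15 <- function(p) merge_and_draft(runs(c(30, 30)), c(1e6, 1.25e6),
                                     c(1.1e6, 1.35e6), filter_params(p))
  expect_equal(nrow(g15("degron")), 1)  # merged 60 >= 40 kept
  expect_equal(nrow(g15("main")), 0)    # separate 30s both dropped
  expect_error(filter_params("main", merge_gap = 2e6), "exceed")
})

test_that("merge_and_draft is idempotent on its own output", {
  runs <- data.frame(first = NA, last = NA,
                     n_fragments = c(25, 30, 45, 60))
  starts <- c(1e6, 1.15e6, 2.2e6, 4.1e6)
  ends <- c(1.05e6, 1.4e6, 2.6e6, 4.5e6)
  d1 <- merge_and_draft(runs, starts, ends, filter_params("main"))
  d2 <- merge_and_draft(
    data.frame(first = NA, last = NA, n_fragments = d1$n_positive),
    d1$start, d1$end, filter_params("main"))
  expect_equal(d2$start, d1$start)
  expect_equal(d2$end, d1$end)
  expect_equal(d2$n_positive, d1$n_positive)
})

test_that("TetO rescue joins segments across the integration site", {
  drafted <- data.frame(start = c(3e6, 5.2e6), end = c(4.5e6, 6e6),
                        n_positive = c(100, 50))
  # TetO inside the first draft: identity
  r <- rescue_teto(drafted, 3.5e6)
  expect_equal(c(r$start, r$end), c(3e6, 4.5e6))
  expect_false(r$rescued)
  # TetO between drafts: union of nearest segments on both sides
  r2 <- rescue_teto(drafted, 5.0e6)
  expect_equal(c(r2$start, r2$end), c(3e6, 6e6))
  expect_true(r2$rescued)
  expect_equal(r2$n_positive, 150)
  # no segment on the opposite side: extend to TetO with a warning
  expect_warning(r3 <- rescue_teto(drafted[1, ], 5.0e6), "opposite")
  expect_equal(c(r3$start, r3$end), c(3e6, 5e6))
  expect_error(rescue_teto(drafted[0, ], 1e6), "no draft")
})

test_that("call_domains recovers a planted domain and is silent on the null", {
  L <- 2e7; teto <- L / 2
  map <- simulate_fragment_map(L, 256, 0.05, seed = 31)
  spec <- domain_spec(teto, teto - 1e6, teto + 1e6, enrichment = 10)
  sim <- simulate_4c_pair(map, spec, seed = 32)
  fit <- call_domains(fragment_profile(map, sim$on, teto),
                      fragment_profile(map, sim$control, teto))
  expect_s3_class(fit, "tacl_domains")
  expect_equal(nrow(fit$domain), 1)
  expect_lt(abs(fit$domain$start - spec$domain_start), 3 * 256)
  expect_lt(abs(fit$domain$end - spec$domain_end), 3 * 256)
  expect_true(fit$domain$start <= teto && fit$domain$end >= teto)
  s <- summary(fit)
  expect_true(s$called)
  expect_equal(round(s$size_mb), 2)
  expect_length(domain_granges(fit), 1)

  null_sim <- simulate_4c_pair(map, domain_spec(teto, teto - 1e6, teto + 1e6,
                                                enrichment = 1), seed = 33)
  fit0 <- call_domains(fragment_profile(map, null_sim$on, teto),
                       fragment_profile(map, null_sim$control, teto))
  expect_equal(nrow(fit0$domain), 0)
  expect_equal(nrow(fit0$drafted), 0)
  expect_length(domain_granges(fit0), 0)
})

test_that("adding positive fragments never shrinks a drafted domain", {
  # monotonicity at the filter-cascade level: append one more retained run
  runs <- data.frame(first = NA, last = NA, n_fragments = c(45, 50))
  base <- merge_and_draft(runs, c(1e6, 2e6), c(1.4e6, 2.5e6),
                          filter_params("main"))
  more <- merge_and_draft(rbind(runs, data.frame(first = NA, last = NA,
                                                 n_fragments = 41)),
                          c(1e6, 2e6, 3.2e6), c(1.4e6, 2.5e6, 3.5e6),
                          filter_params("main"))
  expect_true(all(more$end[1] >= base$end[1]))
  expect_true(sum(more$n_positive) >= sum(base$n_positive))
})
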